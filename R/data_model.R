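## ---------------------------------------------------------------------------
## Data model: canonical CSV readers, schema validation, and the inclusion /
## quality filters applied before fitting.  Exclusions are flags with reason
## strings, never deletions, so reports can list excluded series.
## ---------------------------------------------------------------------------

obs_schema <- c("country_id", "series_id", "source_type", "indicator",
                "ref_year", "value", "se")

check_columns <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  stop_if(length(miss) > 0,
          sprintf("parse error in %s: missing column(s) %s", file,
                  paste(miss, collapse = ", ")))
}

check_rows <- function(ok, file, column, what) {
  if (!all(ok)) {
    bad <- which(!ok)
    stop(sprintf("parse error in %s: %s in column '%s' at row(s) %s", file,
                 what, column, paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
}

#' Read a mortality dataset from CSV files
#'
#' Reads the observation, births, crises, series and region files written by
#' [write_dataset()] (or assembled by hand in the same schemas) into one
#' typed in-memory dataset.  Malformed rows raise errors naming the file,
#' column and row.
#'
#' @param path directory containing `observations.csv`, `births.csv`,
#'   `series.csv` and optionally `crises.csv`, `regions.csv`, `hiv.csv`.
#' @return object of class `mortality_dataset`: a list of data frames
#'   (`observations` gains logical `included` and character
#'   `exclusion_reason` columns, initialised to include everything).
#' @export
read_dataset <- function(path) {
  stop_if(!dir.exists(path), "dataset directory not found: ", path)
  rd <- function(f) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) return(NULL)
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  obs <- rd("observations.csv")
  stop_if(is.null(obs), "observations.csv not found in ", path)
  check_columns(obs, obs_schema, "observations.csv")
  if (nrow(obs) > 0) {
    check_rows(is.finite(obs$value) & obs$value > 0, "observations.csv",
               "value", "non-positive or missing rate")
    check_rows(is.finite(obs$se) & obs$se >= 0, "observations.csv", "se",
               "negative or missing standard error")
    check_rows(obs$ref_year >= 1900 &
                 obs$ref_year <= as.integer(format(Sys.Date(), "%Y")) + 1,
               "observations.csv", "ref_year", "implausible reference year")
    check_rows(obs$indicator %in% c("U5MR", "IMR", "NMR"),
               "observations.csv", "indicator", "unknown indicator")
  }
  births <- rd("births.csv")
  stop_if(is.null(births), "births.csv not found in ", path)
  check_columns(births, c("country_id", "year", "births"), "births.csv")
  if (nrow(births) > 0) {
    check_rows(is.finite(births$births) & births$births > 0, "births.csv",
               "births", "non-positive births")
  }
  series <- rd("series.csv")
  stop_if(is.null(series), "series.csv not found in ", path)
  check_columns(series, c("series_id", "country_id", "source_type"),
                "series.csv")
  if (!"vr_coverage" %in% names(series)) series$vr_coverage <- NA_real_
  if (!"quality_flags" %in% names(series)) series$quality_flags <- ""
  series$quality_flags[is.na(series$quality_flags)] <- ""
  orphan <- setdiff(obs$series_id, series$series_id)
  stop_if(length(orphan) > 0, "observations reference unknown series: ",
          paste(utils::head(orphan, 5), collapse = ", "))
  crises <- rd("crises.csv") %||%
    data.frame(country_id = character(), year = integer(),
               excess_deaths_total = numeric(), frac_neonatal = numeric(),
               frac_postneonatal = numeric(), frac_child = numeric(),
               stringsAsFactors = FALSE)
  regions <- rd("regions.csv") %||%
    data.frame(country_id = unique(obs$country_id), region_id = "R1",
               stringsAsFactors = FALSE)
  hiv <- rd("hiv.csv") %||%
    data.frame(country_id = character(), year = integer(),
               u5mr_add = numeric(), nmr_add = numeric(),
               stringsAsFactors = FALSE)
  obs$included <- TRUE
  obs$exclusion_reason <- NA_character_
  structure(list(observations = obs, births = births, series = series,
                 crises = crises, region_map = regions, hiv = hiv),
            class = "mortality_dataset")
}

#' @export
print.mortality_dataset <- function(x, ...) {
  cat(sprintf(paste0("<mortality_dataset> %d observations (%d included), ",
                     "%d series, %d countries\n"),
              nrow(x$observations), sum(x$observations$included),
              nrow(x$series), length(unique(x$births$country_id))))
  invisible(x)
}

#' Inclusion rules for observation series
#'
#' @param min_vr_coverage minimum vital-registration population coverage;
#'   the boundary is inclusive (coverage of exactly the minimum is kept).
#' @param exclude_flags quality flags whose presence excludes a series
#'   (for example documented fieldwork disruption during a crisis).
#' @param known_flags the vocabulary of recognised flags; an `exclude_flags`
#'   entry outside it is a configuration error.
#' @return object of class `inclusion_rules`.
#' @export
inclusion_rules <- function(min_vr_coverage = 0.80,
                            exclude_flags = c("fieldwork_disrupted",
                                              "quality_concern"),
                            known_flags = c("fieldwork_disrupted",
                                            "quality_concern",
                                            "incomplete_coverage")) {
  unknown <- setdiff(exclude_flags, known_flags)
  stop_if(length(unknown) > 0, "unknown quality flag(s) in rules: ",
          paste(unknown, collapse = ", "))
  structure(list(min_vr_coverage = min_vr_coverage,
                 exclude_flags = exclude_flags, known_flags = known_flags),
            class = "inclusion_rules")
}

#' Read inclusion rules from a YAML file
#'
#' @param path YAML file with optional keys `min_vr_coverage` and
#'   `exclude_flags`.
#' @return an [inclusion_rules()] object.
#' @export
read_inclusion_rules <- function(path) {
  y <- yaml::read_yaml(path)
  inclusion_rules(
    min_vr_coverage = y$min_vr_coverage %||% 0.80,
    exclude_flags = unlist(y$exclude_flags) %||%
      c("fieldwork_disrupted", "quality_concern"))
}

#' Apply inclusion rules to a dataset
#'
#' Flags (never deletes) observations from series failing the rules: vital
#' registration series with population coverage below the minimum (strictly
#' below — coverage of exactly the minimum is included), and series carrying
#' any excluded quality flag.  Re-application is idempotent.
#'
#' @param dataset a [read_dataset()] result.
#' @param rules an [inclusion_rules()] object.
#' @return the dataset with `included` / `exclusion_reason` set.
#' @export
apply_inclusion_rules <- function(dataset, rules = inclusion_rules()) {
  stop_if(!inherits(dataset, "mortality_dataset"), "not a mortality_dataset")
  stop_if(!inherits(rules, "inclusion_rules"), "not inclusion_rules")
  ser <- dataset$series
  reason <- rep(NA_character_, nrow(ser))
  is_vr <- ser$source_type == "VR" & !is.na(ser$vr_coverage)
  low_cov <- is_vr & ser$vr_coverage < rules$min_vr_coverage
  reason[low_cov] <- "vr_coverage"
  flags <- strsplit(ser$quality_flags, "[;,|] *")
  flagged <- vapply(flags, function(f)
    length(intersect(f, rules$exclude_flags)) > 0, TRUE)
  reason[flagged & is.na(reason)] <-
    vapply(which(flagged & is.na(reason)), function(i)
      paste(intersect(flags[[i]], rules$exclude_flags), collapse = ";"), "")
  m <- match(dataset$observations$series_id, ser$series_id)
  dataset$observations$included <- is.na(reason[m])
  dataset$observations$exclusion_reason <- reason[m]
  dataset
}

#' Most recent included data year per country
#'
#' @param dataset a flagged dataset.
#' @param indicator one of `"U5MR"`, `"IMR"`, `"NMR"`.
#' @return named numeric vector (decimal year) per country; `NA` where no
#'   included observation of that indicator exists.
#' @export
last_included_year <- function(dataset, indicator = "U5MR") {
  obs <- dataset$observations
  ids <- sort(unique(obs$country_id))
  out <- vapply(ids, function(cid) {
    sel <- obs$country_id == cid & obs$indicator == indicator & obs$included
    if (!any(sel)) NA_real_ else max(obs$ref_year[sel])
  }, 0)
  names(out) <- ids
  out
}

#' Observations of one country and indicator
#'
#' @param dataset a [read_dataset()] result.
#' @param country_id,indicator selection.
#' @param included_only drop flagged-out observations (default).
#' @return data frame of observations.
#' @export
country_observations <- function(dataset, country_id, indicator,
                                 included_only = TRUE) {
  obs <- dataset$observations
  sel <- obs$country_id == country_id & obs$indicator == indicator
  if (included_only) sel <- sel & obs$included
  obs[sel, , drop = FALSE]
}
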