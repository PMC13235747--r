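## ---------------------------------------------------------------------------
## Post-fit adjustments: crisis excess mortality and HIV/AIDS mortality are
## added to the crisis-free fitted trajectories as additive per-1000 rates
## (crisis deaths / live births x 1000), allocated across age groups by the
## event's age pattern.  Fits use crisis-free data; the adjustment is
## invertible given the event table.
## ---------------------------------------------------------------------------

#' Crisis event record
#'
#' @param country_id country identifier.
#' @param years calendar year(s) of the event.
#' @param total_deaths total excess deaths across all ages (count, >= 0);
#'   scalar (split equally over years) or one value per year.
#' @param age_pattern named fractions allocating total deaths to
#'   `neonatal` (0-27 days), `postneonatal` (28 days-11 months), `child`
#'   (1-4 years), `older` (5+); must be non-negative and sum to 1.
#' @param vr_counts optional named vector of directly observed age-specific
#'   under-5 crisis deaths per year (`neonatal`, `postneonatal`, `child`);
#'   when present these are used verbatim instead of the pattern.
#' @param meets_criteria whether the event meets the inclusion criteria.
#' @return object of class `crisis_event`.
#' @export
crisis_event <- function(country_id, years, total_deaths,
                         age_pattern = c(neonatal = 0.1, postneonatal = 0.2,
                                         child = 0.2, older = 0.5),
                         vr_counts = NULL, meets_criteria = TRUE) {
  stop_if(any(total_deaths < 0), "total deaths must be >= 0")
  stop_if(any(age_pattern < 0), "age-pattern fractions must be >= 0")
  stop_if(abs(sum(age_pattern) - 1) > 1e-8,
          "age-pattern fractions must sum to 1")
  need <- c("neonatal", "postneonatal", "child")
  stop_if(!all(need %in% names(age_pattern)),
          "age_pattern needs named neonatal/postneonatal/child entries")
  total_deaths <- rep_len(total_deaths / ifelse(length(total_deaths) == 1,
                                                length(years), 1),
                          length(years))
  structure(list(country_id = country_id, years = as.integer(years),
                 total_deaths = total_deaths, age_pattern = age_pattern,
                 vr_counts = vr_counts, meets_criteria = meets_criteria),
            class = "crisis_event")
}

#' Allocate a crisis event's deaths to under-5 age groups
#'
#' Counts are `total x fraction` per age group; when the event carries
#' direct vital-registration age-specific counts those are used verbatim.
#'
#' @param event a [crisis_event()].
#' @return data frame with one row per event year and columns `year`,
#'   `neonatal`, `postneonatal`, `child`, `under5`.
#' @export
allocate_crisis_deaths <- function(event) {
  stop_if(!inherits(event, "crisis_event"), "not a crisis_event")
  if (!is.null(event$vr_counts)) {
    vc <- event$vr_counts
    out <- data.frame(year = event$years,
                      neonatal = rep_len(vc[["neonatal"]], length(event$years)),
                      postneonatal = rep_len(vc[["postneonatal"]],
                                             length(event$years)),
                      child = rep_len(vc[["child"]], length(event$years)))
  } else {
    p <- event$age_pattern
    out <- data.frame(year = event$years,
                      neonatal = event$total_deaths * p[["neonatal"]],
                      postneonatal = event$total_deaths * p[["postneonatal"]],
                      child = event$total_deaths * p[["child"]])
  }
  out$under5 <- out$neonatal + out$postneonatal + out$child
  out
}

#' Filter crisis events by inclusion criteria
#'
#' The production criteria live in configuration: an event qualifies when
#' its total excess deaths reach `min_deaths` and its under-5 deaths reach
#' `min_share` of the country's expected (crisis-free) under-5 deaths that
#' year.
#'
#' @param events list of [crisis_event()].
#' @param expected_u5_deaths optional named-by-year expected baseline under-5
#'   deaths used for the share criterion (skipped when `NULL`).
#' @param min_deaths,min_share thresholds.
#' @return the events that qualify (with `meets_criteria` set).
#' @export
filter_crisis_events <- function(events, expected_u5_deaths = NULL,
                                 min_deaths = 100, min_share = 0.025) {
  keep <- vapply(events, function(e) {
    alloc <- allocate_crisis_deaths(e)
    ok <- sum(e$total_deaths) >= min_deaths
    if (ok && !is.null(expected_u5_deaths)) {
      base <- expected_u5_deaths[as.character(e$years)]
      ok <- any(alloc$under5 >= min_share * base, na.rm = TRUE)
    }
    ok
  }, TRUE)
  lapply(events[keep], function(e) { e$meets_criteria <- TRUE; e })
}

## additive per-1000 rate adjustments per indicator implied by events
crisis_rate_additions <- function(events, births, years) {
  add <- matrix(0, 3, length(years),
                dimnames = list(c("NMR", "IMR", "U5MR"), years))
  for (e in events) {
    if (!isTRUE(e$meets_criteria)) next
    alloc <- allocate_crisis_deaths(e)
    for (r in seq_len(nrow(alloc))) {
      yr <- alloc$year[r]
      j <- match(yr, years)
      if (is.na(j)) next
      b <- births$births[match(yr, births$year)]
      stop_if(is.na(b), "missing births for crisis year ", yr)
      add["NMR", j] <- add["NMR", j] + alloc$neonatal[r] / b * 1000
      add["IMR", j] <- add["IMR", j] +
        (alloc$neonatal[r] + alloc$postneonatal[r]) / b * 1000
      add["U5MR", j] <- add["U5MR", j] + alloc$under5[r] / b * 1000
    }
  }
  add
}

#' Add crisis mortality to fitted crisis-free trajectories
#'
#' For each qualifying event-year the under-5 crisis deaths are converted to
#' an additive rate (deaths / births x 1000), allocated consistently across
#' NMR/IMR/U5MR by the event's age pattern, and added to every posterior
#' draw; non-event years are unchanged.  Since the additions are nested
#' (neonatal <= infant <= under-5), the rate ordering is preserved.
#'
#' @param trajectories named list with elements `nmr`, `imr`, `u5mr`, each a
#'   [new_trajectories()] on a common grid.
#' @param events list of [crisis_event()] (only those with
#'   `meets_criteria = TRUE` are applied).
#' @param births data frame (`year`, `births`).
#' @return the list of trajectories, adjusted, with attribute
#'   `crisis_adjusted = TRUE`.
#' @export
apply_crisis_adjustment <- function(trajectories, events, births) {
  years <- trajectories$u5mr$years
  add <- crisis_rate_additions(events, births, years)
  for (ind in c("nmr", "imr", "u5mr")) {
    key <- toupper(ind)
    tr <- trajectories[[ind]]
    if (is.null(tr)) next
    stop_if(!identical(tr$years, years), "trajectory grids differ")
    tr$draws <- sweep(tr$draws, 2, add[key, ], `+`)
    attr(tr, "crisis_adjusted") <- TRUE
    trajectories[[ind]] <- tr
  }
  attr(trajectories, "crisis_adjusted") <- TRUE
  trajectories
}

#' Add HIV/AIDS mortality to fitted trajectories
#'
#' Additive per-1000 adjustment analogous to the crisis adjustment; an
#' empty table is the identity.
#'
#' @param trajectories named list with elements `nmr`, `imr`, `u5mr`.
#' @param hiv_table data frame with `year`, `u5mr_add`, and optionally
#'   `imr_add`, `nmr_add` (per 1000, all >= 0).
#' @return adjusted trajectories.
#' @export
apply_hiv_adjustment <- function(trajectories, hiv_table) {
  if (is.null(hiv_table) || nrow(hiv_table) == 0) return(trajectories)
  years <- trajectories$u5mr$years
  bad <- setdiff(hiv_table$year, years)
  stop_if(length(bad) > 0, "HIV table years outside trajectory span: ",
          paste(bad, collapse = ", "))
  cols <- c(nmr = "nmr_add", imr = "imr_add", u5mr = "u5mr_add")
  for (ind in names(cols)) {
    if (!cols[ind] %in% names(hiv_table)) next
    v <- hiv_table[[cols[ind]]]
    stop_if(any(v < 0), "negative HIV adjustment")
    tr <- trajectories[[ind]]
    if (is.null(tr)) next
    add <- numeric(length(years))
    add[match(hiv_table$year, years)] <- v
    tr$draws <- sweep(tr$draws, 2, add, `+`)
    trajectories[[ind]] <- tr
  }
  trajectories
}
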