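## ---------------------------------------------------------------------------
## Synthetic-data generator: fake "countries" with smooth declining true
## mortality trajectories, multi-series noisy observations with source-type
## biases, live births, and crisis spikes.  The generator reproduces the
## statistical structure the estimation model assumes (multiplicative
## log-scale errors around an unobserved true rate), so every downstream
## stage is testable without any external database.
## ---------------------------------------------------------------------------

#' Source-type error hierarchy defaults
#'
#' Default log-scale bias magnitudes and error standard deviations per data
#' source type.  Vital registration (VR) is least biased with the lowest
#' variance; summary birth histories (SBH) are most error-prone.  The
#' magnitudes are placeholders spanning a realistic range, not estimates of
#' any real survey programme.
#'
#' @return data frame with one row per source type.
#' @export
source_type_defaults <- function() {
  data.frame(
    source_type    = c("VR", "SVR", "census", "survey_FBH", "survey_SBH"),
    bias_mean      = c(0, 0, 0, 0, 0),
    bias_sd        = c(0, 0.02, 0.05, 0.05, 0.10),
    sampling_sd    = c(0.01, 0.02, 0.04, 0.06, 0.08),
    nonsampling_sd = c(0.01, 0.03, 0.05, 0.06, 0.12),
    covers_nmr     = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines the study conditions of a synthetic world: how many countries,
#' the year range, baseline mortality and pace-of-decline distributions, the
#' per-source-type series counts and error hyperparameters, crisis frequency
#' and size, and the births process.  A fixed `seed` fully determines the
#' generated world.
#'
#' @param n_countries number of countries to generate.
#' @param years integer vector of calendar years covered by the truth.
#' @param u5mr_1990_meanlog,u5mr_1990_sdlog log-normal parameters of the
#'   baseline U5MR (per 1000) at the first year.
#' @param arr_mean,arr_sd per-country mean annual rate of reduction of U5MR
#'   (fraction per year) and its between-country SD.
#' @param slope_rw_sd innovation SD of the random walk on the yearly
#'   log-decline (0 gives exactly log-linear trajectories).
#' @param imr_share mean of the ratio (IMR-NMR)/(U5MR-NMR) used to place IMR
#'   between NMR and U5MR.
#' @param series_mean mean number of observation series per country
#'   (Poisson, at least one).
#' @param obs_prob probability a series observes any given year in its
#'   active window.
#' @param source_types data frame as [source_type_defaults()].
#' @param crisis_prob probability a country experiences one crisis event.
#' @param crisis_size_meanlog,crisis_size_sdlog log-normal parameters of
#'   the crisis spike added to U5MR (per 1000).
#' @param births_meanlog,births_sdlog log-normal parameters of the initial
#'   annual births level.
#' @param births_growth_mean,births_growth_sd per-country annual births
#'   growth rate distribution.
#' @param seed master RNG seed (integer).
#'
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_countries = 10,
                       years = 1985:2024,
                       u5mr_1990_meanlog = log(60), u5mr_1990_sdlog = 0.8,
                       arr_mean = 0.03, arr_sd = 0.012,
                       slope_rw_sd = 0.004,
                       imr_share = 0.60,
                       series_mean = 4,
                       obs_prob = 0.55,
                       source_types = source_type_defaults(),
                       crisis_prob = 0.15,
                       crisis_size_meanlog = log(5), crisis_size_sdlog = 0.5,
                       births_meanlog = log(2e5), births_sdlog = 1,
                       births_growth_mean = 0.01, births_growth_sd = 0.01,
                       seed = 20240601L) {
  cfg <- list(n_countries = as.integer(n_countries), years = as.integer(years),
              u5mr_1990_meanlog = u5mr_1990_meanlog,
              u5mr_1990_sdlog = u5mr_1990_sdlog,
              arr_mean = arr_mean, arr_sd = arr_sd, slope_rw_sd = slope_rw_sd,
              imr_share = imr_share, series_mean = series_mean,
              obs_prob = obs_prob, source_types = source_types,
              crisis_prob = crisis_prob,
              crisis_size_meanlog = crisis_size_meanlog,
              crisis_size_sdlog = crisis_size_sdlog,
              births_meanlog = births_meanlog, births_sdlog = births_sdlog,
              births_growth_mean = births_growth_mean,
              births_growth_sd = births_growth_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_if(cfg$n_countries < 0, "invalid config: n_countries must be >= 0")
  stop_if(length(cfg$years) < 2, "invalid config: need at least two years")
  num <- c(cfg$u5mr_1990_sdlog, cfg$arr_sd, cfg$slope_rw_sd, cfg$series_mean,
           cfg$obs_prob, cfg$crisis_prob, cfg$births_growth_sd)
  stop_if(any(!is.finite(num)) || any(num < 0),
          "invalid config: dispersion/probability parameters must be finite and >= 0")
  stop_if(cfg$imr_share <= 0 || cfg$imr_share >= 1,
          "invalid config: imr_share must lie in (0, 1)")
  stop_if(any(cfg$source_types$sampling_sd < 0) ||
          any(cfg$source_types$nonsampling_sd < 0),
          "invalid config: source-type error SDs must be >= 0")
  invisible(cfg)
}

#' Generate one country's true mortality trajectory
#'
#' The true log U5MR follows a piecewise log-linear path whose yearly decline
#' drifts as a random walk (innovation SD `slope_rw_sd`); NMR is placed via
#' the expected-ratio curve with a country multiplier and IMR lies between
#' NMR and U5MR, so the ordering NMR <= IMR <= U5MR holds by construction.
#' An optional crisis adds a one-or-two-year additive spike (per 1000) on
#' top of the crisis-free rates, recorded in `crisis_additions`.
#'
#' @param config a [sim_config()].
#' @param country_index integer country index (seeds a private RNG stream).
#' @return object of class `true_trajectory` with elements `country_id`,
#'   `years`, `u5mr`, `imr`, `nmr` (crisis-free, per 1000),
#'   `crisis_additions` (per 1000 added to U5MR), and `crisis_pattern`.
#' @export
generate_true_trajectory <- function(config, country_index) {
  validate_sim_config(config)
  ny <- length(config$years)
  with_seed(sub_seed(config$seed, country_index * 4L + 1L), {
    u5_0 <- stats::rlnorm(1, config$u5mr_1990_meanlog, config$u5mr_1990_sdlog)
    arr <- stats::rnorm(1, config$arr_mean, config$arr_sd)
    slopes <- arr + cumsum(stats::rnorm(ny - 1, 0, config$slope_rw_sd))
    log_u5 <- log(u5_0) - c(0, cumsum(slopes))
    u5mr <- exp(log_u5)
    mult <- exp(stats::rnorm(1, 0, 0.15))
    er <- expected_ratio(u5mr) * mult
    nmr <- u5mr * er / (1 + er)
    share <- min(max(stats::rnorm(1, config$imr_share, 0.05), 0.3), 0.9)
    imr <- nmr + (u5mr - nmr) * share
    crisis_additions <- numeric(ny)
    crisis_pattern <- NULL
    if (stats::runif(1) < config$crisis_prob) {
      yr_i <- sample(seq_len(ny - 1), 1)
      dur <- sample(1:2, 1)
      size <- stats::rlnorm(1, config$crisis_size_meanlog,
                            config$crisis_size_sdlog)
      idx <- yr_i:min(yr_i + dur - 1L, ny)
      crisis_additions[idx] <- size / length(idx)
      crisis_pattern <- c(neonatal = 0.1, postneonatal = 0.3, child = 0.6)
    }
    structure(
      list(country_id = sprintf("C%03d", country_index),
           years = config$years, u5mr = u5mr, imr = imr, nmr = nmr,
           crisis_additions = crisis_additions,
           crisis_pattern = crisis_pattern),
      class = "true_trajectory")
  })
}

#' Observation-series specification
#'
#' @param series_id series identifier.
#' @param source_type one of `"VR"`, `"SVR"`, `"census"`, `"survey_FBH"`,
#'   `"survey_SBH"`.
#' @param bias log-scale systematic offset of the series.
#' @param sampling_sd,nonsampling_sd log-scale error SDs (both >= 0).
#' @param obs_years years with observations.
#' @param indicators_covered subset of `c("U5MR", "IMR", "NMR")`; SBH series
#'   can never cover NMR (neonatal rates cannot be estimated from summary
#'   birth histories).
#' @return object of class `series_spec`.
#' @export
series_spec <- function(series_id, source_type, bias = 0,
                        sampling_sd = 0.05, nonsampling_sd = 0.05,
                        obs_years = integer(),
                        indicators_covered = c("U5MR", "IMR", "NMR")) {
  stop_if(sampling_sd < 0 || nonsampling_sd < 0,
          "error SDs must be non-negative")
  if (identical(source_type, "survey_SBH")) {
    indicators_covered <- setdiff(indicators_covered, "NMR")
  }
  structure(list(series_id = series_id, source_type = source_type,
                 bias = bias, sampling_sd = sampling_sd,
                 nonsampling_sd = nonsampling_sd,
                 obs_years = as.integer(obs_years),
                 indicators_covered = indicators_covered),
            class = "series_spec")
}

#' Generate noisy observations from a true trajectory
#'
#' Implements the multiplicative error model: for each observation year and
#' indicator covered by the series, `observed = true * exp(bias + e)` with
#' `e ~ Normal(0, sampling_sd^2 + nonsampling_sd^2)`.  Each observation
#' carries a rate-scale standard error derived from the sampling SD.
#'
#' @param truth a [generate_true_trajectory()] result.
#' @param spec a [series_spec()].
#' @param seed RNG seed for this series.
#' @return data frame of observations (one row per year x indicator).
#' @export
generate_observations <- function(truth, spec, seed = 1L) {
  bad <- setdiff(spec$obs_years, truth$years)
  stop_if(length(bad) > 0, "observation years outside truth range: ",
          paste(bad, collapse = ", "))
  rows <- expand.grid(ref_year = spec$obs_years,
                      indicator = spec$indicators_covered,
                      stringsAsFactors = FALSE)
  if (nrow(rows) == 0) {
    return(data.frame(country_id = character(), series_id = character(),
                      source_type = character(), indicator = character(),
                      ref_year = numeric(), value = numeric(),
                      se = numeric(), stringsAsFactors = FALSE))
  }
  with_seed(seed, {
    idx <- match(rows$ref_year, truth$years)
    true_val <- ifelse(rows$indicator == "U5MR", truth$u5mr[idx],
                ifelse(rows$indicator == "IMR", truth$imr[idx],
                       truth$nmr[idx]))
    total_sd <- sqrt(spec$sampling_sd^2 + spec$nonsampling_sd^2)
    e <- stats::rnorm(nrow(rows), 0, total_sd)
    value <- true_val * exp(spec$bias + e)
    ## reference point is the midpoint of the observation year (mid-year = x.5),
    ## matching the recall-window-midpoint convention for surveys
    ref <- rows$ref_year + 0.5
    data.frame(country_id = truth$country_id, series_id = spec$series_id,
               source_type = spec$source_type, indicator = rows$indicator,
               ref_year = ref, value = value,
               se = value * spec$sampling_sd, stringsAsFactors = FALSE)
  })
}

#' Generate annual live births for one country
#'
#' Deterministic geometric-growth births series given the seed: a log-normal
#' initial level and a country growth rate, rounded to whole births.
#'
#' @param config a [sim_config()].
#' @param country_index integer country index.
#' @return data frame with columns `country_id`, `year`, `births`.
#' @export
generate_births <- function(config, country_index) {
  validate_sim_config(config)
  with_seed(sub_seed(config$seed, country_index * 4L + 2L), {
    b0 <- stats::rlnorm(1, config$births_meanlog, config$births_sdlog)
    g <- stats::rnorm(1, config$births_growth_mean, config$births_growth_sd)
    ny <- length(config$years)
    births <- pmax(1, round(b0 * (1 + g)^(seq_len(ny) - 1)))
    data.frame(country_id = sprintf("C%03d", country_index),
               year = config$years, births = births,
               stringsAsFactors = FALSE)
  })
}

## draw the set of series specs for one country
generate_series_specs <- function(config, country_index) {
  st <- config$source_types
  with_seed(sub_seed(config$seed, country_index * 4L + 3L), {
    n_series <- max(1L, stats::rpois(1, config$series_mean))
    ## ensure at least one reference-quality VR series so biases are
    ## identified in the fitted model
    types <- c("VR", sample(st$source_type, n_series - 1L, replace = TRUE,
                            prob = c(2, 1, 1, 2, 1)))
    specs <- vector("list", n_series)
    ny <- length(config$years)
    for (k in seq_len(n_series)) {
      row <- st[st$source_type == types[k], ]
      span <- sort(sample(seq_len(ny), 2))
      if (types[k] %in% c("census", "survey_SBH")) {
        yrs <- sample(config$years[span[1]:span[2]],
                      min(3L, span[2] - span[1] + 1L))
      } else {
        win <- config$years[span[1]:span[2]]
        yrs <- win[stats::runif(length(win)) < config$obs_prob]
      }
      if (length(yrs) == 0) yrs <- sample(config$years, 1)
      bias <- if (types[k] == "VR") 0 else
        stats::rnorm(1, row$bias_mean, row$bias_sd)
      specs[[k]] <- series_spec(
        series_id = sprintf("C%03d_S%02d", country_index, k),
        source_type = types[k], bias = bias,
        sampling_sd = row$sampling_sd, nonsampling_sd = row$nonsampling_sd,
        obs_years = sort(unique(yrs)))
    }
    specs
  })
}

#' Generate one complete synthetic country
#'
#' Combines truth, series specifications, observations, births, crisis
#' events and VR metadata into one country record.
#'
#' @inheritParams generate_births
#' @return list with elements `truth`, `series` (list of [series_spec()]),
#'   `observations`, `births`, `crises`, `series_meta`.
#' @export
generate_country <- function(config, country_index) {
  truth <- generate_true_trajectory(config, country_index)
  specs <- generate_series_specs(config, country_index)
  obs <- do.call(rbind, lapply(seq_along(specs), function(k) {
    generate_observations(truth, specs[[k]],
                          seed = sub_seed(config$seed,
                                          country_index * 1000L + k))
  }))
  births <- generate_births(config, country_index)
  crises <- data.frame(country_id = character(), year = integer(),
                       excess_deaths_total = numeric(),
                       frac_neonatal = numeric(), frac_postneonatal = numeric(),
                       frac_child = numeric(), stringsAsFactors = FALSE)
  if (any(truth$crisis_additions > 0)) {
    yrs <- truth$years[truth$crisis_additions > 0]
    b <- births$births[match(yrs, births$year)]
    add <- truth$crisis_additions[truth$crisis_additions > 0]
    p <- truth$crisis_pattern
    u5_share <- sum(p)
    crises <- data.frame(
      country_id = truth$country_id, year = yrs,
      excess_deaths_total = add / 1000 * b / u5_share,
      frac_neonatal = p[["neonatal"]],
      frac_postneonatal = p[["postneonatal"]],
      frac_child = p[["child"]], stringsAsFactors = FALSE)
  }
  series_meta <- data.frame(
    series_id = vapply(specs, function(s) s$series_id, ""),
    country_id = truth$country_id,
    source_type = vapply(specs, function(s) s$source_type, ""),
    vr_coverage = vapply(specs, function(s)
      if (s$source_type == "VR") 1.0 else NA_real_, 0),
    quality_flags = "", stringsAsFactors = FALSE)
  list(truth = truth, series = specs, observations = obs, births = births,
       crises = crises, series_meta = series_meta)
}

#' Generate a full synthetic world
#'
#' @param config a [sim_config()].
#' @param n_regions number of regions countries are assigned to.
#' @return list of countries plus a `region_map` data frame.
#' @export
generate_world <- function(config, n_regions = 3) {
  countries <- lapply(seq_len(config$n_countries),
                      function(i) generate_country(config, i))
  ids <- vapply(countries, function(cc) cc$truth$country_id, "")
  region_map <- data.frame(
    country_id = ids,
    region_id = sprintf("R%d", ((seq_along(ids) - 1L) %% n_regions) + 1L),
    stringsAsFactors = FALSE)
  structure(list(countries = countries, region_map = region_map,
                 config = config), class = "synthetic_world")
}

#' Write a synthetic dataset to CSV files
#'
#' Writes `observations.csv`, `births.csv`, `crises.csv`, `series.csv`,
#' `regions.csv` and (for testing only) `truth.csv` in the schemas read by
#' [read_dataset()].
#'
#' @param world a [generate_world()] result.
#' @param path output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(world, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    stop_if(!ok && !dir.exists(path), "cannot create output directory: ", path)
  }
  cs <- world$countries
  bind <- function(get, proto) {
    parts <- lapply(cs, get)
    parts <- parts[vapply(parts, nrow, 0L) > 0]
    if (length(parts) == 0) proto else do.call(rbind, parts)
  }
  obs <- bind(function(x) x$observations,
              data.frame(country_id = character(), series_id = character(),
                         source_type = character(), indicator = character(),
                         ref_year = numeric(), value = numeric(),
                         se = numeric()))
  births <- bind(function(x) x$births,
                 data.frame(country_id = character(), year = integer(),
                            births = numeric()))
  crises <- bind(function(x) x$crises,
                 data.frame(country_id = character(), year = integer(),
                            excess_deaths_total = numeric(),
                            frac_neonatal = numeric(),
                            frac_postneonatal = numeric(),
                            frac_child = numeric()))
  series <- bind(function(x) x$series_meta,
                 data.frame(series_id = character(), country_id = character(),
                            source_type = character(), vr_coverage = numeric(),
                            quality_flags = character()))
  truth <- bind(function(x) {
    tr <- x$truth
    data.frame(country_id = tr$country_id, year = tr$years, u5mr = tr$u5mr,
               imr = tr$imr, nmr = tr$nmr,
               crisis_addition = tr$crisis_additions)
  }, data.frame(country_id = character(), year = integer(), u5mr = numeric(),
                imr = numeric(), nmr = numeric(), crisis_addition = numeric()))
  files <- c(observations = "observations.csv", births = "births.csv",
             crises = "crises.csv", series = "series.csv",
             regions = "regions.csv", truth = "truth.csv")
  utils::write.csv(obs, file.path(path, files["observations"]),
                   row.names = FALSE)
  utils::write.csv(births, file.path(path, files["births"]), row.names = FALSE)
  utils::write.csv(crises, file.path(path, files["crises"]), row.names = FALSE)
  utils::write.csv(series, file.path(path, files["series"]), row.names = FALSE)
  utils::write.csv(world$region_map, file.path(path, files["regions"]),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(path, files["truth"]), row.names = FALSE)
  invisible(file.path(path, files))
}
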