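## ---------------------------------------------------------------------------
## Aggregation to regions and the world, and report tables.  Percentiles
## are always taken on aggregated draws, never on summed percentiles (the
## sum of medians is not the median of sums).
## ---------------------------------------------------------------------------

#' Aggregate country death draws to regions and the world
#'
#' Sums country-level death-draw arrays within regions per draw; the world
#' is the sum over all countries.  Uncertainty intervals must then be taken
#' from the aggregated draws with [deaths_uncertainty()].
#'
#' @param country_deaths named list (by country id) of
#'   [compute_deaths_draws()] arrays with common years and draw counts.
#' @param region_map data frame (`country_id`, `region_id`); every country
#'   must be mapped.
#' @return named list of arrays: one per region plus `"world"`.
#' @export
aggregate_deaths <- function(country_deaths, region_map) {
  ids <- names(country_deaths)
  m <- match(ids, region_map$country_id)
  stop_if(anyNA(m), "unmapped country id(s): ",
          paste(ids[is.na(m)], collapse = ", "))
  regions <- region_map$region_id[m]
  dims <- dim(country_deaths[[1]])
  out <- list()
  for (r in unique(regions)) {
    arrs <- country_deaths[regions == r]
    acc <- array(0, dims, dimnames = dimnames(country_deaths[[1]]))
    for (a in arrs) {
      stop_if(!identical(dim(a), dims), "death arrays differ in shape")
      acc <- acc + a
    }
    out[[r]] <- acc
  }
  world <- array(0, dims, dimnames = dimnames(country_deaths[[1]]))
  for (a in country_deaths) world <- world + a
  out[["world"]] <- world
  out
}

#' Aggregate country rate trajectories to regions and the world
#'
#' Regional rate per draw-year is the birth-weighted mean of the member
#' countries' rates.
#'
#' @param traj_list named list (by country id) of [new_trajectories()] on a
#'   common grid with equal draw counts.
#' @param births_list named list of births data frames matching
#'   `traj_list`.
#' @param region_map data frame (`country_id`, `region_id`).
#' @return named list of [new_trajectories()]: one per region plus
#'   `"world"`.
#' @export
aggregate_rates <- function(traj_list, births_list, region_map) {
  ids <- names(traj_list)
  m <- match(ids, region_map$country_id)
  stop_if(anyNA(m), "unmapped country id(s): ",
          paste(ids[is.na(m)], collapse = ", "))
  regions <- region_map$region_id[m]
  ## align on the years every country covers
  years <- Reduce(intersect, lapply(traj_list, `[[`, "years"))
  stop_if(length(years) < 1, "no common span across countries")
  indicator <- traj_list[[1]]$indicator
  wts <- vapply(ids, function(id) {
    b <- births_list[[id]]
    w <- b$births[match(years, b$year)]
    stop_if(anyNA(w), "births missing for country ", id)
    w
  }, numeric(length(years)))
  wts <- matrix(wts, nrow = length(years))
  weighted <- function(sel) {
    tot <- rowSums(wts[, sel, drop = FALSE])
    stop_if(any(tot <= 0), "zero total births in aggregate")
    acc <- 0
    for (k in which(sel)) {
      dr <- traj_list[[k]]$draws[, match(years, traj_list[[k]]$years),
                                 drop = FALSE]
      acc <- acc + sweep(dr, 2, wts[, k], `*`)
    }
    sweep(acc, 2, tot, `/`)
  }
  out <- list()
  for (r in unique(regions)) {
    out[[r]] <- new_trajectories(r, indicator, years, weighted(regions == r))
  }
  out[["world"]] <- new_trajectories("world", indicator, years,
                                    weighted(rep(TRUE, length(ids))))
  out
}

#' Render report tables
#'
#' Produces the standard reporting tables from pipeline outputs: rates with
#' 90% intervals by region for selected years, deaths likewise, annual
#' rates of reduction by period, and an optional scenario summary.
#' Intervals render as `"median (lo to hi)"`.
#'
#' @param rate_aggregates named list of regional/world
#'   [new_trajectories()] (one indicator), as from [aggregate_rates()].
#' @param death_aggregates optional named list from [aggregate_deaths()].
#' @param years report years (default `c(1990, 2000, 2015, 2024)` clipped
#'   to the available span).
#' @param arr_periods list of `c(t1, t2)` periods for the ARR table.
#' @param scenario_summary optional data frame passed through (scenario,
#'   region, cumulative deaths).
#' @return list of data frames: `rates`, `deaths`, `arr`, `scenarios`.
#' @export
render_report <- function(rate_aggregates, death_aggregates = NULL,
                          years = c(1990, 2000, 2015, 2024),
                          arr_periods = list(c(1990, 2000), c(2000, 2015),
                                             c(2015, 2024)),
                          scenario_summary = NULL) {
  empty <- data.frame(region = character(), year = integer(),
                      estimate = character(), stringsAsFactors = FALSE)
  if (length(rate_aggregates) == 0) {
    return(list(rates = empty, deaths = empty,
                arr = data.frame(region = character(), period = character(),
                                 estimate = character()),
                scenarios = scenario_summary))
  }
  span <- rate_aggregates[[1]]$years
  years <- years[years %in% span]
  rates <- do.call(rbind, lapply(names(rate_aggregates), function(r) {
    q <- traj_quantiles(rate_aggregates[[r]])
    q <- q[q$year %in% years, ]
    data.frame(region = r, year = q$year,
               estimate = format_ui(q$median, q$lower, q$upper, 1),
               median = q$median, lower = q$lower, upper = q$upper,
               stringsAsFactors = FALSE)
  }))
  arr_tab <- do.call(rbind, lapply(names(rate_aggregates), function(r) {
    do.call(rbind, lapply(arr_periods, function(p) {
      if (!all(p %in% span)) return(NULL)
      a <- arr_with_ui(rate_aggregates[[r]], p[1], p[2])
      data.frame(region = r, period = paste(p, collapse = "-"),
                 estimate = format_ui(100 * a$median, 100 * a$lower,
                                      100 * a$upper, 1),
                 arr_median = a$median, stringsAsFactors = FALSE)
    }))
  }))
  deaths_tab <- NULL
  if (!is.null(death_aggregates)) {
    deaths_tab <- do.call(rbind, lapply(names(death_aggregates), function(r) {
      u <- deaths_uncertainty(death_aggregates[[r]])
      u <- u[u$year %in% years & u$age_group %in% c("under5", "neonatal"), ]
      data.frame(region = r, year = u$year, age_group = u$age_group,
                 estimate = format_ui(u$median, u$lower, u$upper, 0),
                 median = u$median, stringsAsFactors = FALSE)
    }))
  }
  list(rates = rates, deaths = deaths_tab, arr = arr_tab,
       scenarios = scenario_summary)
}
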