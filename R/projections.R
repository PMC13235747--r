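## ---------------------------------------------------------------------------
## Scenario projections 2025-2030.  To keep NMR/IMR/U5MR internally
## consistent, the estimated rates are first decomposed into component
## conditional probabilities — neonatal q(0-28d), post-neonatal q(28d-1y),
## child q(1-5y) — which are projected per scenario and recombined.
## ---------------------------------------------------------------------------

#' Decompose NMR/IMR/U5MR into component conditional probabilities
#'
#' @param nmr,imr,u5mr cumulative probabilities (not per 1000), with
#'   `nmr <= imr <= u5mr`.
#' @return list with `nmr`, `pnmr` (= 1 - (1-imr)/(1-nmr)) and `cmr`
#'   (= 1 - (1-u5mr)/(1-imr)), all probabilities.
#' @export
decompose_rates <- function(nmr, imr, u5mr) {
  stop_if(any(nmr > imr + 1e-12) || any(imr > u5mr + 1e-12),
          "ordering violated: need nmr <= imr <= u5mr")
  stop_if(any(u5mr >= 1), "rates must be probabilities below 1")
  list(nmr = nmr,
       pnmr = 1 - (1 - imr) / (1 - nmr),
       cmr = 1 - (1 - u5mr) / (1 - imr))
}

#' Recombine component probabilities into NMR/IMR/U5MR
#'
#' Inverse of [decompose_rates()]: `imr = 1 - (1-nmr)(1-pnmr)` and
#' `u5mr = 1 - (1-nmr)(1-pnmr)(1-cmr)`; the ordering is guaranteed by
#' construction.
#'
#' @param components list with `nmr`, `pnmr`, `cmr` probabilities.
#' @return list with `nmr`, `imr`, `u5mr` probabilities.
#' @export
recombine_rates <- function(components) {
  s1 <- 1 - components$nmr
  s2 <- 1 - components$pnmr
  s3 <- 1 - components$cmr
  list(nmr = components$nmr, imr = 1 - s1 * s2, u5mr = 1 - s1 * s2 * s3)
}

#' Scenario specification
#'
#' @param kind one of `"constant"`, `"current_trends"`,
#'   `"current_trends_lower"`, `"current_trends_upper"`, `"sdg_target"`,
#'   `"high_income"`.
#' @param arr_period period over which the crisis-free annual rates of
#'   reduction are measured (default 2015-2024).
#' @param floors per-1000 component floors: the lowest 2024 neonatal (0.7),
#'   post-neonatal (0.1) and child (0.3) rates observed among countries
#'   with at least `floor_min_births` live births; floors apply to all
#'   countries.
#' @param floor_min_births births threshold defining the floor reference set.
#' @param sdg_thresholds per-1000 targets: U5MR 25, NMR 12, to be reached by
#'   the horizon year.
#' @param hic_thresholds per-1000 high-income averages: U5MR 5.1, NMR 2.8.
#' @param horizon final projection year (2030).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("current_trends", "constant",
                                   "current_trends_lower",
                                   "current_trends_upper",
                                   "sdg_target", "high_income"),
                          arr_period = c(2015, 2024),
                          floors = c(nmr = 0.7, pnmr = 0.1, cmr = 0.3),
                          floor_min_births = 10000,
                          sdg_thresholds = c(u5mr = 25, nmr = 12),
                          hic_thresholds = c(u5mr = 5.1, nmr = 2.8),
                          horizon = 2030) {
  kind <- match.arg(kind)
  stop_if(any(floors <= 0), "floors must be positive")
  stop_if(sdg_thresholds[["u5mr"]] <= floors[["nmr"]] ||
            hic_thresholds[["u5mr"]] <= 0,
          "thresholds must exceed floors")
  structure(list(kind = kind, arr_period = arr_period, floors = floors,
                 floor_min_births = floor_min_births,
                 sdg_thresholds = sdg_thresholds,
                 hic_thresholds = hic_thresholds, horizon = horizon),
            class = "scenario_spec")
}

#' Component floors from a synthetic world
#'
#' Implements the floor rule on generated data: the lowest 2024 component
#' rates among countries with at least the births threshold.
#'
#' @param rates_2024 data frame with per-country `nmr`, `imr`, `u5mr`
#'   (per 1000) and `births` for 2024.
#' @param min_births births threshold.
#' @return named per-1000 floor vector (`nmr`, `pnmr`, `cmr`).
#' @export
compute_floors <- function(rates_2024, min_births = 10000) {
  el <- rates_2024[rates_2024$births >= min_births, , drop = FALSE]
  stop_if(nrow(el) == 0, "no country meets the births threshold")
  comp <- decompose_rates(el$nmr / 1000, el$imr / 1000, el$u5mr / 1000)
  c(nmr = min(comp$nmr) * 1000, pnmr = min(comp$pnmr) * 1000,
    cmr = min(comp$cmr) * 1000)
}

#' Crisis-free component annual rates of reduction with uncertainty
#'
#' Computes the ARR of each component conditional probability over the
#' scenario period per posterior draw, and returns the median and the 90%
#' interval bounds.  Negative ARRs (rising mortality) are clamped to zero:
#' rates are then held at their final-year level.
#'
#' @param trajectories named list with `nmr`, `imr`, `u5mr`
#'   crisis-free [new_trajectories()].
#' @param spec a [scenario_spec()].
#' @return list per component (`nmr`, `pnmr`, `cmr`) with `median`,
#'   `lower`, `upper` (fractions per year, >= 0).
#' @export
scenario_arr <- function(trajectories, spec = scenario_spec()) {
  t1 <- spec$arr_period[1]; t2 <- spec$arr_period[2]
  get <- function(ind, year) traj_window(trajectories[[ind]], year)[, 1] / 1000
  comp1 <- decompose_rates(get("nmr", t1), get("imr", t1), get("u5mr", t1))
  comp2 <- decompose_rates(get("nmr", t2), get("imr", t2), get("u5mr", t2))
  lapply(stats::setNames(nm = c("nmr", "pnmr", "cmr")), function(cm) {
    a <- arr(pmax(comp1[[cm]], 1e-9), pmax(comp2[[cm]], 1e-9), t1, t2)
    q <- stats::quantile(a, c(0.05, 0.5, 0.95), names = FALSE)
    list(lower = max(q[1], 0), median = max(q[2], 0), upper = max(q[3], 0))
  })
}

## log-linear component path with an absorbing floor, never raised to the
## floor if already below it
component_path <- function(q0, arr, years, t0, floor_q) {
  eff_floor <- min(floor_q, q0)
  pmax(q0 * exp(-arr * (years - t0)), eff_floor)
}

## log-linear path from q0 at t0 to target at horizon
target_path <- function(q0, target, years, t0, horizon) {
  a <- log(q0 / target) / (horizon - t0)
  q0 * exp(-a * (years - t0))
}

#' Project component rates under a scenario
#'
#' Projects the 2024 component rates year by year to the horizon:
#' `constant` freezes rates; the `current_trends` family declines each
#' component log-linearly at its (median, lower- or upper-bound) ARR,
#' clamped at the component floors, which are absorbing; `sdg_target`
#' replaces the paths of countries whose current-trends 2030 U5MR/NMR
#' exceed 25/12 per 1000 with log-linear paths hitting the targets exactly
#' in 2030 (the U5MR target is met by fixing the NMR path first and scaling
#' the post-neonatal and child components proportionally on the
#' log-survival scale); `high_income` does the same with the 5.1/2.8
#' thresholds for every country above them.
#'
#' @param rates_2024 named vector, per-1000 `nmr`, `imr`, `u5mr` in the
#'   jump-off year.
#' @param arrs result of [scenario_arr()] for this country.
#' @param spec a [scenario_spec()].
#' @param t0 jump-off year (default 2024).
#' @return data frame `year` (t0..horizon), components (`nmr_q`, `pnmr_q`,
#'   `cmr_q`, probabilities) and recombined `nmr`, `imr`, `u5mr` per 1000.
#' @export
project_rates <- function(rates_2024, arrs, spec = scenario_spec(),
                          t0 = 2024) {
  years <- t0:spec$horizon
  comp0 <- decompose_rates(rates_2024[["nmr"]] / 1000,
                           rates_2024[["imr"]] / 1000,
                           rates_2024[["u5mr"]] / 1000)
  fl <- spec$floors / 1000
  pick <- switch(spec$kind,
                 current_trends_lower = "lower",
                 current_trends_upper = "upper",
                 "median")
  a <- vapply(c("nmr", "pnmr", "cmr"), function(cm) arrs[[cm]][[pick]], 0)
  if (spec$kind == "constant") a[] <- 0
  ct <- list(
    nmr = component_path(comp0$nmr, a[["nmr"]], years, t0, fl[["nmr"]]),
    pnmr = component_path(comp0$pnmr, a[["pnmr"]], years, t0, fl[["pnmr"]]),
    cmr = component_path(comp0$cmr, a[["cmr"]], years, t0, fl[["cmr"]]))
  comp <- ct
  if (spec$kind %in% c("sdg_target", "high_income")) {
    th <- if (spec$kind == "sdg_target") spec$sdg_thresholds
          else spec$hic_thresholds
    rec_ct <- recombine_rates(ct)
    n <- length(years)
    ## "on track" if already reaching the threshold under current trends;
    ## for the high-income scenario only countries already below keep
    ## current trends
    if (spec$kind == "sdg_target") {
      nmr_off <- ct$nmr[n] > th[["nmr"]] / 1000
      u5_off <- rec_ct$u5mr[n] > th[["u5mr"]] / 1000
    } else {
      nmr_off <- comp0$nmr > th[["nmr"]] / 1000
      u5_off <- recombine_rates(comp0)$u5mr > th[["u5mr"]] / 1000
    }
    if (nmr_off) {
      comp$nmr <- target_path(comp0$nmr, th[["nmr"]] / 1000, years, t0,
                              spec$horizon)
    }
    if (u5_off) {
      u5_tgt <- target_path(recombine_rates(comp0)$u5mr, th[["u5mr"]] / 1000,
                            years, t0, spec$horizon)
      s23_needed <- (1 - u5_tgt) / (1 - comp$nmr)
      s23_ct <- (1 - ct$pnmr) * (1 - ct$cmr)
      lam <- ifelse(abs(log(s23_ct)) < 1e-14, 1,
                    pmax(log(s23_needed) / log(s23_ct), 0))
      comp$pnmr <- 1 - (1 - ct$pnmr)^lam
      comp$cmr <- 1 - (1 - ct$cmr)^lam
    }
  }
  rec <- recombine_rates(comp)
  data.frame(year = years, nmr_q = comp$nmr, pnmr_q = comp$pnmr,
             cmr_q = comp$cmr, nmr = rec$nmr * 1000, imr = rec$imr * 1000,
             u5mr = rec$u5mr * 1000)
}

#' Deaths implied by projected rates
#'
#' Delegates to the deaths engine: rates (estimates for the years before
#' the jump-off plus the scenario path) are converted to hazards and every
#' birth cohort alive during the accounting period is exposed.  Hazards
#' beyond the last projected year are held at their final values, which
#' does not affect deaths allocated inside the period.
#'
#' @param rates data frame `year`, `nmr`, `imr`, `u5mr` (per 1000) covering
#'   at least `period[1] - 5` through `period[2]`.
#' @param births data frame (`year`, `births`) covering the same years.
#' @param period accounting window, default `c(2025, 2030)`.
#' @return list with `by_year` (deaths table restricted to the period) and
#'   `cumulative` (named totals: `under5`, `neonatal`, `d1to59m`).
#' @export
projected_deaths <- function(rates, births, period = c(2025, 2030)) {
  need <- (period[1] - 5L):period[2]
  stop_if(!all(need %in% rates$year), "rates must cover ",
          period[1] - 5L, "-", period[2])
  bsel <- births[births$year %in% need, , drop = FALSE]
  stop_if(!all(need %in% bsel$year), "births must cover ",
          period[1] - 5L, "-", period[2])
  ## pad hazards after the horizon (exposure of the youngest cohorts only)
  pad_years <- (max(rates$year) + 1L):(max(need) + 5L)
  last <- rates[rates$year == max(rates$year), ]
  pad <- last[rep(1, length(pad_years)), ]
  pad$year <- pad_years
  rr <- rbind(rates[rates$year %in% need, ], pad)
  hz <- rates_to_hazards(rr$nmr, rr$imr, rr$u5mr, rr$year)
  dd <- compute_deaths(bsel, hz$h)
  in_period <- dd$year >= period[1] & dd$year <= period[2]
  by_year <- dd[in_period, , drop = FALSE]
  list(by_year = by_year,
       cumulative = c(under5 = sum(by_year$under5),
                      neonatal = sum(by_year$neonatal),
                      d1to59m = sum(by_year$d1to59m)))
}

#' Deaths averted between two scenarios
#'
#' @param scenario_a,scenario_b [projected_deaths()] results; averted =
#'   A minus B (positive when scenario B saves lives relative to A).
#' @return named numeric vector of averted deaths by age group.
#' @export
averted_deaths <- function(scenario_a, scenario_b) {
  scenario_a$cumulative - scenario_b$cumulative
}
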