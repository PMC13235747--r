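## ---------------------------------------------------------------------------
## Pace-of-change and share metrics with posterior uncertainty.
## ---------------------------------------------------------------------------

#' Annual rate of reduction
#'
#' ARR over a period is `log(rate_t1 / rate_t2) / (t2 - t1)`, positive when
#' mortality declines.  Satisfies duration-weighted additivity over
#' subperiods.
#'
#' @param rate_t1,rate_t2 rates at the start and end of the period (> 0).
#' @param t1,t2 calendar years, `t1 < t2`.
#' @return ARR as a fraction per year.
#' @export
arr <- function(rate_t1, rate_t2, t1, t2) {
  stop_if(any(rate_t1 <= 0) || any(rate_t2 <= 0),
          "rates must be positive")
  stop_if(any(t1 >= t2), "need t1 < t2")
  log(rate_t1 / rate_t2) / (t2 - t1)
}

#' Annual rate of reduction with posterior uncertainty
#'
#' ARR is computed per posterior trajectory draw; the median and the 5th and
#' 95th percentiles across draws give the point estimate and 90% interval.
#'
#' @param traj a [new_trajectories()] object covering both years.
#' @param t1,t2 period endpoints (years in the trajectory span).
#' @return list with `median`, `lower`, `upper`, `draws`, and the period.
#' @export
arr_with_ui <- function(traj, t1, t2) {
  stop_if(!(t1 %in% traj$years) || !(t2 %in% traj$years),
          "period endpoints outside trajectory span")
  r1 <- traj$draws[, match(t1, traj$years)]
  r2 <- traj$draws[, match(t2, traj$years)]
  a <- arr(r1, r2, t1, t2)
  q <- stats::quantile(a, c(0.05, 0.5, 0.95), names = FALSE)
  list(median = q[2], lower = q[1], upper = q[3], draws = a,
       t1 = t1, t2 = t2, indicator = traj$indicator)
}

#' Percent decline between two rates
#'
#' @param rate_a earlier rate (> 0).
#' @param rate_b later rate.
#' @return `1 - rate_b / rate_a` (fraction).
#' @export
percent_decline <- function(rate_a, rate_b) {
  stop_if(any(rate_a <= 0), "baseline rate must be positive")
  1 - rate_b / rate_a
}

#' Neonatal share of under-5 mortality
#'
#' @param nmr,u5mr rates with `0 < nmr <= u5mr`.
#' @return `nmr / u5mr`.
#' @export
nmr_share <- function(nmr, u5mr) {
  stop_if(any(nmr <= 0) || any(nmr > u5mr + 1e-12),
          "ordering violated: need 0 < nmr <= u5mr")
  nmr / u5mr
}

#' Share of deaths contributed by a part
#'
#' @param part,total death counts with `0 <= part <= total`, `total > 0`.
#' @return `part / total`.
#' @export
deaths_share <- function(part, total) {
  stop_if(any(total <= 0), "total deaths must be positive")
  stop_if(any(part < 0) || any(part > total + 1e-9),
          "part must lie in [0, total]")
  part / total
}
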