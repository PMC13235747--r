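## ---------------------------------------------------------------------------
## Neonatal mortality via the ratio model.
##
## The modelled quantity is R(t) = NMR / (U5MR - NMR), estimated as the
## product of an expected ratio — a deterministic global relation between
## the ratio and U5MR — and a country-specific multiplier m(t) whose log
## follows a first-order random walk centred at zero, fitted to the
## country's neonatal observations.  NMR = U5MR * R / (1 + R) guarantees
## 0 < NMR < U5MR for every posterior draw.
## ---------------------------------------------------------------------------

#' Expected-ratio curve configuration
#'
#' The global relation is log R = intercept + slope * log(U5MR) for U5MR
#' above a low-mortality plateau threshold, constant below it.  Default
#' parameters are calibrated so the curve passes through the published
#' global (U5MR, NMR) pairs for 1990 and 2024.
#'
#' @param intercept,slope parameters of the log-log relation (slope <= 0 so
#'   the ratio is non-increasing in U5MR).
#' @param plateau_u5mr U5MR (per 1000) below which the ratio is held at its
#'   plateau value (> 0).
#' @param innovation_a,innovation_b inverse-gamma prior on the multiplier
#'   random-walk innovation variance.
#' @param level_sd prior SD centring log m(t) at zero.
#' @param iter,warmup Gibbs settings for the multiplier.
#' @param seed RNG seed.
#' @return object of class `ratio_config`.
#' @export
ratio_config <- function(intercept = 0.947, slope = -0.306,
                         plateau_u5mr = 10,
                         innovation_a = 1, innovation_b = 0.005,
                         level_sd = 1,
                         iter = 1500, warmup = 500, seed = 1L) {
  stop_if(plateau_u5mr <= 0, "plateau threshold must be positive")
  stop_if(slope > 0, "slope must be non-positive (ratio non-increasing)")
  structure(list(intercept = intercept, slope = slope,
                 plateau_u5mr = plateau_u5mr,
                 innovation_a = innovation_a, innovation_b = innovation_b,
                 level_sd = level_sd, iter = iter, warmup = warmup,
                 seed = as.integer(seed)),
            class = "ratio_config")
}

#' Expected NMR/(U5MR - NMR) ratio at a given U5MR
#'
#' @param u5mr under-5 mortality rate, deaths per 1000 live births (> 0).
#' @param config a [ratio_config()].
#' @return dimensionless expected ratio, monotone non-increasing in U5MR
#'   above the plateau threshold and constant below it.
#' @export
expected_ratio <- function(u5mr, config = ratio_config()) {
  stop_if(any(!is.finite(u5mr)) || any(u5mr <= 0),
          "u5mr must be positive")
  x <- pmax(u5mr, config$plateau_u5mr)
  exp(config$intercept + config$slope * log(x))
}

#' Calibrate the expected-ratio curve to (U5MR, ratio) pairs
#'
#' Least-squares fit of the log-log relation above the plateau threshold;
#' points at or below the threshold are excluded from the regression.
#'
#' @param u5mr,ratio observed pairs (per 1000 / dimensionless).
#' @param plateau_u5mr plateau threshold to retain.
#' @return a [ratio_config()] with fitted intercept and slope.
#' @export
fit_expected_ratio <- function(u5mr, ratio, plateau_u5mr = 10) {
  keep <- u5mr > plateau_u5mr
  stop_if(sum(keep) < 2, "need at least two pairs above the plateau")
  fit <- stats::lm(log(ratio[keep]) ~ log(u5mr[keep]))
  ratio_config(intercept = unname(stats::coef(fit)[1]),
               slope = min(0, unname(stats::coef(fit)[2])),
               plateau_u5mr = plateau_u5mr)
}

#' Fit the country-specific ratio multiplier
#'
#' Fits log m(t), a first-order random walk centred at zero, to a country's
#' neonatal observations expressed as log-ratio residuals from the expected
#' ratio evaluated at the posterior-median U5MR.  With no usable neonatal
#' observations the multiplier is identically one and the ratio reduces to
#' the expected-ratio curve.  Observations implying NMR >= U5MR are dropped
#' with a warning.
#'
#' @param nmr_observations data frame with `ref_year`, `value` (NMR per
#'   1000), `se`; may have zero rows.
#' @param u5mr_traj [new_trajectories()] for U5MR.
#' @param config a [ratio_config()].
#' @return object of class `nmr_fit` holding multiplier draws per year.
#' @export
nmr_fit <- function(nmr_observations, u5mr_traj, config = ratio_config()) {
  years <- u5mr_traj$years
  ny <- length(years)
  u5_med <- apply(u5mr_traj$draws, 2, stats::median)
  obs <- as.data.frame(nmr_observations)
  n_draws <- nrow(u5mr_traj$draws)

  if (nrow(obs) > 0) {
    yr <- pmin(pmax(floor(obs$ref_year), min(years)), max(years))
    u5_at <- u5_med[match(yr, years)]
    bad <- obs$value >= u5_at
    if (any(bad)) {
      warning(sum(bad), " neonatal observation(s) implying NMR >= U5MR ",
              "excluded", call. = FALSE)
      obs <- obs[!bad, , drop = FALSE]
      yr <- yr[!bad]; u5_at <- u5_at[!bad]
    }
  }

  if (nrow(obs) == 0) {
    g_draws <- matrix(0, n_draws, ny)    # m(t) == 1 exactly
    sd_draws <- numeric(0)
  } else {
    r_obs <- obs$value / (u5_at - obs$value)
    z <- log(r_obs) - log(expected_ratio(u5_at, config))
    ## delta-method variance of log r from the rate-scale SE
    w <- (obs$se * (1 / obs$value + 1 / (u5_at - obs$value)))^2
    w <- pmax(w, 1e-8)
    gs <- multiplier_gibbs(z, match(yr, years), w, ny, config)
    keep <- (config$warmup + 1L):config$iter
    g_kept <- gs$g[keep, , drop = FALSE]
    idx <- rep_len(seq_len(nrow(g_kept)), n_draws)
    g_draws <- g_kept[idx, , drop = FALSE]
    sd_draws <- gs$sd[keep]
  }
  structure(list(years = years, g_draws = g_draws,
                 innovation_sd = sd_draws, u5_median = u5_med,
                 n_obs = nrow(obs), config = config,
                 country_id = u5mr_traj$country_id),
            class = "nmr_fit")
}

## Gibbs for the multiplier: z_i = g(t_i) + e_i, e_i ~ N(0, w_i);
## RW1 prior on g with innovation variance s2, weak zero-centring.
multiplier_gibbs <- function(z, t_idx, w, ny, config) {
  D <- difference_matrix(ny, 1)
  L <- crossprod(D)
  A_prec <- numeric(ny); A_mean <- numeric(ny)
  for (i in seq_along(z)) {
    A_prec[t_idx[i]] <- A_prec[t_idx[i]] + 1 / w[i]
    A_mean[t_idx[i]] <- A_mean[t_idx[i]] + z[i] / w[i]
  }
  s2 <- 0.01
  iter <- config$iter
  g_draws <- matrix(NA_real_, iter, ny)
  sd_draws <- numeric(iter)
  level_prec <- 1 / config$level_sd^2
  with_seed(config$seed, {
    for (it in seq_len(iter)) {
      Q <- L / s2 + diag(A_prec + level_prec, ny)
      U <- chol(Q)
      mu <- backsolve(U, forwardsolve(t(U), A_mean))
      g <- as.vector(mu + backsolve(U, stats::rnorm(ny)))
      ss <- sum(diff(g)^2)
      s2 <- 1 / stats::rgamma(1, config$innovation_a + (ny - 1) / 2,
                              config$innovation_b + ss / 2)
      s2 <- min(max(s2, 1e-10), 100)
      g_draws[it, ] <- g
      sd_draws[it] <- sqrt(s2)
    }
  })
  list(g = g_draws, sd = sd_draws)
}

#' @export
print.nmr_fit <- function(x, ...) {
  cat(sprintf("Neonatal ratio-model fit: %s, %d obs, %d-%d\n",
              x$country_id %||% "country", x$n_obs, min(x$years),
              max(x$years)))
  m_med <- apply(exp(x$g_draws), 2, stats::median)
  cat(sprintf("  multiplier median range: %.3f to %.3f\n",
              min(m_med), max(m_med)))
  invisible(x)
}

#' Ratio trajectories implied by a multiplier fit
#'
#' @param fit an [nmr_fit()].
#' @param u5mr_traj U5MR trajectories (same grid and draw count used in the
#'   fit).
#' @return list with `years` and `draws` of R(t) (dimensionless, > 0).
#' @export
ratio_trajectory <- function(fit, u5mr_traj) {
  stop_if(!identical(fit$years, u5mr_traj$years),
          "year grids differ between fit and trajectories")
  er <- expected_ratio(u5mr_traj$draws, fit$config)
  m <- exp(fit$g_draws)
  stop_if(nrow(m) != nrow(u5mr_traj$draws),
          "draw counts differ between fit and trajectories")
  list(years = fit$years, draws = er * m)
}

#' Derive NMR trajectories from U5MR and ratio trajectories
#'
#' Per draw-year, NMR = U5MR * R / (1 + R), which guarantees
#' 0 < NMR < U5MR.
#'
#' @param u5mr_traj [new_trajectories()] for U5MR.
#' @param ratio [ratio_trajectory()] result (matched dimensions).
#' @return [new_trajectories()] for NMR.
#' @export
derive_nmr <- function(u5mr_traj, ratio) {
  stop_if(!identical(dim(u5mr_traj$draws), dim(ratio$draws)) ||
            !identical(u5mr_traj$years, ratio$years),
          "mismatched dimensions between U5MR and ratio trajectories")
  nmr <- u5mr_traj$draws * ratio$draws / (1 + ratio$draws)
  new_trajectories(u5mr_traj$country_id, "NMR", u5mr_traj$years, nmr,
                   fitted = u5mr_traj$fitted)
}
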