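## ---------------------------------------------------------------------------
## Bias-adjusted Bayesian penalized B-spline model for U5MR / IMR.
##
## Observation model (log scale, rates per 1000):
##   log(obs_i) = f(t_i) + b_{source(i)} + eps_i,
##   eps_i ~ N(0, v_i + sigma^2_{source(i)}),
## where v_i is the observation's sampling variance on the log scale
## (delta method from its rate-scale SE), b_s is the average systematic
## bias of source type s (reference type fixed at 0 for identification),
## and sigma^2_s its non-sampling variance.
##
## Trend model: f(t) = sum_j alpha_j B_j(t), cubic B-splines with equally
## spaced knots and a second-order difference (random-walk) penalty on the
## coefficients with smoothing variance tau^2.  No covariates enter the
## mean.
##
## Posterior sampling: blocked Gibbs — alpha is multivariate-normal
## conditionally; biases b_s are normal conditionally; tau^2 is conjugate
## inverse-gamma; the non-sampling SDs are updated with a random-walk
## Metropolis step on log(sigma_s).
## ---------------------------------------------------------------------------

#' Configuration for the penalized-spline mortality model
#'
#' @param knot_spacing knot spacing in years (default 2.5).
#' @param degree spline degree (default cubic).
#' @param penalty_order order of the difference penalty (default 2).
#' @param bias_prior_sd prior SD of source-type log-scale biases.
#' @param sigma_prior_scale half-normal prior scale for the non-sampling SDs.
#' @param tau_a,tau_b inverse-gamma prior on the smoothing variance tau^2.
#' @param chains,iter,warmup MCMC settings; `iter` is the total number of
#'   iterations per chain, draws kept after `warmup`.
#' @param reference_source source type whose bias is fixed at zero to
#'   identify the bias parameters (high-coverage vital registration); if no
#'   series of that type is present, the least-biased available type in the
#'   order VR, SVR, census, survey_FBH, survey_SBH takes its place.
#' @param trailing_window years used for "recent country trend" in
#'   extrapolation (default 10).
#' @param reference_year common reference year trajectories extend to.
#' @param rhat_threshold convergence gate on the split-chain potential scale
#'   reduction factor.
#' @param fix_bias,fix_sigma,fix_tau optionally pin bias (to 0), non-sampling
#'   SDs, or tau at fixed values instead of sampling them (used for
#'   degenerate-limit checks and analytic cross-validation).
#' @param seed RNG seed for the sampler.
#' @return object of class `b3_config`.
#' @export
b3_config <- function(knot_spacing = 2.5, degree = 3, penalty_order = 2,
                      bias_prior_sd = 0.2, sigma_prior_scale = 0.1,
                      tau_a = 1, tau_b = 0.01,
                      chains = 2, iter = 1500, warmup = 500,
                      reference_source = "VR",
                      trailing_window = 10, reference_year = 2024,
                      rhat_threshold = 1.05,
                      fix_bias = FALSE, fix_sigma = NULL, fix_tau = NULL,
                      seed = 1L) {
  stop_if(knot_spacing <= 0 || degree < 1 || penalty_order < 1,
          "spline settings must be positive")
  stop_if(chains < 1 || iter <= warmup || iter - warmup < 1,
          "need at least one post-warmup draw")
  structure(list(knot_spacing = knot_spacing, degree = degree,
                 penalty_order = penalty_order,
                 bias_prior_sd = bias_prior_sd,
                 sigma_prior_scale = sigma_prior_scale,
                 tau_a = tau_a, tau_b = tau_b, chains = chains, iter = iter,
                 warmup = warmup, reference_source = reference_source,
                 trailing_window = trailing_window,
                 reference_year = reference_year,
                 rhat_threshold = rhat_threshold,
                 fix_bias = fix_bias, fix_sigma = fix_sigma, fix_tau = fix_tau,
                 seed = as.integer(seed)),
            class = "b3_config")
}

source_preference <- c("VR", "SVR", "census", "survey_FBH", "survey_SBH")

#' Fit the bias-adjusted penalized-spline mortality model
#'
#' Fits the log-scale spline trend with source-type bias and non-sampling
#' variance parameters to one country's included observations of a single
#' indicator, by blocked Gibbs sampling, and returns the posterior together
#' with convergence diagnostics.
#'
#' @param observations data frame with columns `ref_year`, `value` (rate per
#'   1000), `se` (rate-scale standard error), `source_type`, `series_id`;
#'   typically the included rows of one country/indicator from
#'   [read_dataset()].
#' @param config a [b3_config()].
#' @param years integer grid of years the trajectory is evaluated on;
#'   default `floor(min(ref_year))` through `config$reference_year`.
#' @return object of class `b3_fit` with posterior draws of the trajectory
#'   (per 1000), biases, non-sampling SDs and smoothing SD, plus split-chain
#'   R-hat diagnostics (`$rhat`, and `$converged` per the configured gate).
#' @export
b3_fit <- function(observations, config = b3_config(), years = NULL) {
  stop_if(!inherits(config, "b3_config"), "config must be a b3_config")
  obs <- as.data.frame(observations)
  stop_if(nrow(obs) < 1,
          paste("zero included observations: no likelihood to fit;",
                "use the extrapolation-only path instead"))
  need <- c("ref_year", "value", "se", "source_type")
  miss <- setdiff(need, names(obs))
  stop_if(length(miss) > 0, "observations missing column(s): ",
          paste(miss, collapse = ", "))
  stop_if(any(obs$value <= 0), "observed rates must be positive")

  if (is.null(years)) {
    years <- seq(floor(min(obs$ref_year)),
                 max(config$reference_year, ceiling(max(obs$ref_year))))
  }
  years <- as.integer(years)
  ## annual estimates refer to mid-year (t + 0.5), matching the decimal
  ## reference-year convention of the observations; the basis span covers
  ## both the observation times and the mid-year grid
  basis <- build_basis(seq(min(years), max(years) + 1L),
                       config$knot_spacing, config$degree)
  X <- eval_basis(basis, obs$ref_year)
  k <- ncol(basis$B)
  D <- difference_matrix(k, config$penalty_order)
  DtD <- crossprod(D)

  y <- log(obs$value)
  v <- (obs$se / obs$value)^2            # delta-method log-scale variance
  v <- pmax(v, 1e-8)
  types <- unique(obs$source_type)
  ref <- if (config$reference_source %in% types) config$reference_source
         else intersect(source_preference, types)[1] %||% types[1]
  src <- match(obs$source_type, types)

  chains <- lapply(seq_len(config$chains), function(ch) {
    with_seed(sub_seed(config$seed, ch), {
      b3_gibbs(y, X, v, src, types, ref, DtD, config)
    })
  })

  ## assemble post-warmup draws across chains
  keep <- (config$warmup + 1L):config$iter
  alpha <- do.call(rbind, lapply(chains, function(c) c$alpha[keep, , drop = FALSE]))
  bias <- do.call(rbind, lapply(chains, function(c) c$bias[keep, , drop = FALSE]))
  sigma <- do.call(rbind, lapply(chains, function(c) c$sigma[keep, , drop = FALSE]))
  tau <- unlist(lapply(chains, function(c) c$tau[keep]))
  B_grid <- eval_basis(basis, years + 0.5)
  logf <- alpha %*% t(B_grid)            # n_draws x n_years (mid-year)

  ## convergence: split R-hat on log f at a spread of years, plus log tau
  mon_idx <- unique(round(seq(1, length(years), length.out = 5)))
  rhat <- c(
    vapply(mon_idx, function(j) {
      split_rhat(lapply(chains, function(c)
        as.vector(c$alpha[keep, , drop = FALSE] %*% B_grid[j, ])))
    }, 0),
    tau = split_rhat(lapply(chains, function(c) log(c$tau[keep]))))
  names(rhat)[seq_along(mon_idx)] <- paste0("logf_", years[mon_idx])
  converged <- all(rhat < config$rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warning("convergence gate failed: max split R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)
  }

  fit <- structure(
    list(years = years, draws = exp(logf), alpha = alpha, bias = bias,
         sigma = sigma, tau = tau, bias_types = types,
         reference_source = ref, basis = basis, observations = obs,
         config = config, rhat = rhat, converged = converged,
         last_data_year = max(obs$ref_year), seed = config$seed),
    class = "b3_fit")
  fit
}

## one Gibbs chain; returns matrices of iter x dim draws
b3_gibbs <- function(y, X, v, src, types, ref, DtD, config) {
  n <- length(y); k <- ncol(X); S <- length(types)
  ref_i <- match(ref, types)
  iter <- config$iter
  ridge <- diag(1e-6, k)

  ## state
  sigma2 <- rep((config$sigma_prior_scale / 2)^2, S)
  if (!is.null(config$fix_sigma)) sigma2 <- rep(config$fix_sigma^2, S)
  b <- rep(0, S)
  tau2 <- if (is.null(config$fix_tau)) 0.01 else config$fix_tau^2

  alpha_draws <- matrix(NA_real_, iter, k)
  bias_draws <- matrix(NA_real_, iter, S,
                       dimnames = list(NULL, types))
  sigma_draws <- matrix(NA_real_, iter, S,
                        dimnames = list(NULL, types))
  tau_draws <- numeric(iter)
  Xt <- t(X)
  src_rows <- lapply(seq_len(S), function(s) which(src == s))
  n_s <- lengths(src_rows)
  prior_b_prec <- 1 / config$bias_prior_sd^2
  mh_sd <- 0.4
  alpha <- rep(mean(y), k)

  for (it in seq_len(iter)) {
    w <- 1 / (v + sigma2[src])
    ## alpha | rest
    Q <- Xt %*% (w * X) + DtD / tau2 + ridge
    r <- Xt %*% (w * (y - b[src]))
    U <- chol(Q)
    mu <- backsolve(U, forwardsolve(t(U), r))
    alpha <- as.vector(mu + backsolve(U, stats::rnorm(k)))
    f_obs <- as.vector(X %*% alpha)

    ## biases | rest (reference fixed at 0)
    if (!config$fix_bias) {
      for (s in seq_len(S)) {
        if (s == ref_i || n_s[s] == 0) { b[s] <- 0; next }
        rows <- src_rows[[s]]
        prec <- sum(w[rows]) + prior_b_prec
        mean_s <- sum(w[rows] * (y[rows] - f_obs[rows])) / prec
        b[s] <- stats::rnorm(1, mean_s, sqrt(1 / prec))
      }
    }

    ## tau^2 | alpha (conjugate inverse-gamma)
    if (is.null(config$fix_tau)) {
      pen <- DtD %*% alpha
      ss <- sum(alpha * pen)
      m <- nrow(DtD) - config$penalty_order   # rank of D'D
      tau2 <- 1 / stats::rgamma(1, config$tau_a + m / 2,
                                config$tau_b + ss / 2)
      tau2 <- min(max(tau2, 1e-8), 1e4)
    }

    ## sigma_s | rest via random-walk Metropolis on log sigma
    if (is.null(config$fix_sigma)) {
      for (s in seq_len(S)) {
        if (n_s[s] == 0) next
        rows <- src_rows[[s]]
        res <- y[rows] - f_obs[rows] - b[s]
        cur <- sqrt(sigma2[s])
        prop <- exp(log(cur + 1e-12) + stats::rnorm(1, 0, mh_sd))
        ll <- function(sg) {
          sum(stats::dnorm(res, 0, sqrt(v[rows] + sg^2), log = TRUE)) +
            stats::dnorm(sg, 0, config$sigma_prior_scale, log = TRUE) +
            log(sg)   # Jacobian of the log transform
        }
        if (log(stats::runif(1)) < ll(prop) - ll(cur + 1e-12)) {
          sigma2[s] <- prop^2
        }
      }
    }

    alpha_draws[it, ] <- alpha
    bias_draws[it, ] <- b
    sigma_draws[it, ] <- sqrt(sigma2)
    tau_draws[it] <- sqrt(tau2)
  }
  list(alpha = alpha_draws, bias = bias_draws, sigma = sigma_draws,
       tau = tau_draws)
}

#' @export
print.b3_fit <- function(x, ...) {
  cat(sprintf("Penalized-spline mortality fit: %d obs (%d series), %d-%d\n",
              nrow(x$observations), length(unique(x$observations$series_id)),
              min(x$years), max(x$years)))
  cat(sprintf("  draws: %d  |  reference source: %s  |  max R-hat: %.3f%s\n",
              nrow(x$draws), x$reference_source, max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.b3_fit <- function(object, ...) {
  q <- traj_quantiles(as_trajectories(object))
  bias <- apply(object$bias, 2, stats::quantile, c(0.05, 0.5, 0.95))
  sigma <- apply(object$sigma, 2, stats::quantile, c(0.05, 0.5, 0.95))
  out <- list(trajectory = q, bias = t(bias), sigma = t(sigma),
              tau = stats::quantile(object$tau, c(0.05, 0.5, 0.95)),
              rhat = object$rhat, converged = object$converged)
  class(out) <- "summary.b3_fit"
  out
}

#' @export
print.summary.b3_fit <- function(x, ...) {
  cat("Source-type log-scale biases (5%, 50%, 95%):\n")
  print(round(x$bias, 4))
  cat("Source-type non-sampling SDs (5%, 50%, 95%):\n")
  print(round(x$sigma, 4))
  cat("Smoothing SD tau:", paste(round(x$tau, 4), collapse = " / "), "\n")
  cat("Max split R-hat:", round(max(x$rhat, na.rm = TRUE), 3), "\n")
  yrs <- x$trajectory$year
  show <- x$trajectory[yrs %in% round(seq(min(yrs), max(yrs), length.out = 5)), ]
  print(show, row.names = FALSE)
  invisible(x)
}

#' @export
coef.b3_fit <- function(object, ...) {
  c(stats::setNames(apply(object$bias, 2, stats::median),
                    paste0("bias_", object$bias_types)),
    stats::setNames(apply(object$sigma, 2, stats::median),
                    paste0("sigma_", object$bias_types)),
    tau = stats::median(object$tau))
}

#' Posterior trajectory summaries or draws from a fitted model
#'
#' @param object a [b3_fit()].
#' @param years years to evaluate (defaults to the fit grid).
#' @param type `"summary"` for median and 90% interval, `"draws"` for the
#'   full draw matrix.
#' @param midyear if `TRUE` (default), `years` are calendar years and the
#'   trajectory is evaluated at their mid-points (t + 0.5), the reference
#'   time of an annual estimate; set `FALSE` to evaluate at the exact
#'   decimal times given.
#' @param ... unused.
#' @return data frame or draw matrix of rates per 1000.
#' @export
predict.b3_fit <- function(object, years = object$years,
                           type = c("summary", "draws"), midyear = TRUE,
                           ...) {
  type <- match.arg(type)
  Bn <- eval_basis(object$basis, if (midyear) years + 0.5 else years)
  dr <- exp(object$alpha %*% t(Bn))
  if (type == "draws") return(dr)
  q <- apply(dr, 2, stats::quantile, c(0.05, 0.5, 0.95), names = FALSE)
  data.frame(year = years, lower = q[1, ], median = q[2, ], upper = q[3, ])
}

#' @export
fitted.b3_fit <- function(object, ...) {
  pr <- predict(object, years = object$observations$ref_year,
                midyear = FALSE)
  pr$median
}

#' @export
residuals.b3_fit <- function(object, ...) {
  log(object$observations$value) - log(fitted(object))
}

#' Posterior-predictive observation draws
#'
#' Simulates replicate observations at the fitted data points from the
#' posterior predictive distribution (trajectory draw + source bias +
#' sampling and non-sampling noise).
#'
#' @param object a [b3_fit()].
#' @param nsim number of replicate datasets.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated rates per 1000.
#' @export
simulate.b3_fit <- function(object, nsim = 1, seed = NULL, ...) {
  obs <- object$observations
  X <- eval_basis(object$basis, obs$ref_year)
  src <- match(obs$source_type, object$bias_types)
  v <- pmax((obs$se / obs$value)^2, 1e-8)
  with_seed(seed, {
    idx <- sample(nrow(object$alpha), nsim, replace = nsim > nrow(object$alpha))
    sims <- vapply(idx, function(d) {
      mu <- as.vector(X %*% object$alpha[d, ]) + object$bias[d, src]
      sd <- sqrt(v + object$sigma[d, src]^2)
      exp(stats::rnorm(nrow(obs), mu, sd))
    }, numeric(nrow(obs)))
    as.data.frame(sims)
  })
}

#' @export
plot.b3_fit <- function(x, ...) {
  q <- predict(x)
  obs <- x$observations
  ylim <- range(q$lower, q$upper, obs$value)
  graphics::plot(q$year, q$median, type = "n", ylim = ylim, log = "y",
                 xlab = "year", ylab = "rate per 1000 live births", ...)
  graphics::polygon(c(q$year, rev(q$year)), c(q$lower, rev(q$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(q$year, q$median, col = "steelblue4", lwd = 2)
  pch <- as.integer(factor(obs$source_type))
  graphics::points(obs$ref_year, obs$value, pch = pch)
  graphics::legend("topright", legend = levels(factor(obs$source_type)),
                   pch = seq_along(unique(obs$source_type)), bty = "n")
  invisible(x)
}

#' Extract posterior trajectories from a fit
#'
#' @param fit a [b3_fit()].
#' @param country_id,indicator labels attached to the trajectories.
#' @return a [new_trajectories()] object; years beyond the last data point
#'   are flagged as extrapolated.
#' @export
as_trajectories <- function(fit, country_id = "country", indicator = "U5MR") {
  new_trajectories(country_id, indicator, fit$years, fit$draws,
                   fitted = fit$years <= ceiling(fit$last_data_year))
}

#' Extend trajectories to the reference year by blended trends
#'
#' Beyond the last observed data year, each posterior draw declines
#' log-linearly at an equally weighted combination of that draw's own recent
#' annual rate of reduction (over the trailing window) and the global annual
#' rate of reduction.  If the last data year already reaches the reference
#' year the input is returned unchanged.
#'
#' @param traj a [new_trajectories()] object covering the reference year.
#' @param last_data_year last included observation year for this country.
#' @param global_arr global annual rate of reduction (fraction per year).
#' @param config a [b3_config()] (trailing window, reference year).
#' @return trajectories with post-data years replaced by the blended-trend
#'   path and flagged as extrapolated.
#' @export
extrapolate_trajectories <- function(traj, last_data_year, global_arr,
                                     config = b3_config()) {
  stop_if(is.null(global_arr) || !is.finite(global_arr),
          "missing global trend")
  L <- floor(last_data_year)
  if (L >= config$reference_year) return(traj)
  yrs <- traj$years
  stop_if(!(L %in% yrs), "last data year outside trajectory span")
  j_L <- match(L, yrs)
  w <- min(config$trailing_window, L - min(yrs))
  stop_if(w < 1, "trajectory too short for a trailing trend")
  j_0 <- match(L - w, yrs)
  country_arr <- log(traj$draws[, j_0] / traj$draws[, j_L]) / w
  slope <- 0.5 * country_arr + 0.5 * global_arr
  future <- which(yrs > L)
  for (j in future) {
    traj$draws[, j] <- traj$draws[, j_L] * exp(-slope * (yrs[j] - L))
  }
  traj$fitted[future] <- FALSE
  traj
}

#' Global trend from country trajectories
#'
#' Birth-weighted global rate series (from country posterior medians) and
#' its annual rate of reduction over the trailing window ending at the last
#' common year.
#'
#' @param traj_list list of [new_trajectories()] with identical years.
#' @param births_list list of data frames (`year`, `births`) matching
#'   `traj_list`.
#' @param config a [b3_config()].
#' @return list with `years`, `rates` (global per-1000 series) and `arr`.
#' @export
compute_global_trend <- function(traj_list, births_list,
                                 config = b3_config()) {
  stop_if(length(traj_list) < 1, "need at least one country")
  ## align on the years every country covers
  years <- Reduce(intersect, lapply(traj_list, `[[`, "years"))
  stop_if(length(years) < 2, "no common span across countries")
  med <- vapply(traj_list, function(tr) {
    apply(tr$draws[, match(years, tr$years), drop = FALSE], 2,
          stats::median)
  }, numeric(length(years)))
  wts <- vapply(births_list, function(b) {
    b$births[match(years, b$year)]
  }, numeric(length(years)))
  stop_if(anyNA(wts), "births missing for some trajectory years")
  global <- rowSums(med * wts) / rowSums(wts)
  w <- min(config$trailing_window, length(years) - 1)
  t2 <- max(years); t1 <- t2 - w
  list(years = years, rates = global,
       arr = arr(global[match(t1, years)], global[match(t2, years)], t1, t2))
}

#' Enforce per-draw ordering between two indicators
#'
#' Caps each draw of the smaller indicator at the matched draw of the larger
#' one (truncation, no swapping), e.g. IMR <= U5MR.
#'
#' @param smaller,larger [new_trajectories()] objects on the same grid with
#'   the same number of draws.
#' @return the `smaller` trajectories, truncated.
#' @export
enforce_ordering <- function(smaller, larger) {
  stop_if(!identical(smaller$years, larger$years) ||
            nrow(smaller$draws) != nrow(larger$draws),
          "trajectories must share years and draw count")
  smaller$draws <- pmin(smaller$draws, larger$draws)
  smaller
}
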