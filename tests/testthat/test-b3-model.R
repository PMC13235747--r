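fast_cfg <- function(...) {
  args <- utils::modifyList(list(chains = 2, iter = 900, warmup = 300,
                                 seed = 42), list(...))
  do.call(b3_config, args)
}

test_that("noise-free single-series fit recovers a log-linear truth", {
  obs <- loglinear_obs(u5_0 = 120, arr = 0.035, years = 2000:2023)
  fit <- b3_fit(obs, fast_cfg(fix_bias = TRUE, reference_year = 2024))
  pr <- predict(fit, years = 2000:2023)
  truth <- loglinear_truth(120, 0.035, 2000)(2000:2023 + 0.5)
  expect_lt(max(abs(pr$median / truth - 1)), 0.02)
  expect_true(all(fit$draws > 0))
  expect_true(all(is.finite(log(fit$draws))))
})

test_that("sampler agrees with the analytic conjugate posterior when
           variances are fixed", {
  obs <- loglinear_obs(u5_0 = 80, arr = 0.02, years = 2005:2020)
  sig <- 0.04; tau <- 0.05
  fit <- b3_fit(obs, fast_cfg(fix_bias = TRUE, fix_sigma = sig,
                              fix_tau = tau, iter = 2500, warmup = 500,
                              reference_year = 2021))
  ## independent oracle: Gaussian linear model posterior mean of log f
  bs <- fit$basis
  X <- eval_basis(bs, obs$ref_year)
  v <- (obs$se / obs$value)^2
  W <- diag(1 / (v + sig^2))
  D <- diff(diag(ncol(X)), differences = 2)
  Q <- t(X) %*% W %*% X + crossprod(D) / tau^2 + diag(1e-6, ncol(X))
  mu <- solve(Q, t(X) %*% W %*% log(obs$value))
  logf_mean_oracle <- as.vector(eval_basis(bs, obs$ref_year) %*% mu)
  logf_mean_mcmc <- colMeans(log(predict(fit, obs$ref_year,
                                         type = "draws",
                                         midyear = FALSE)))
  expect_lt(max(abs(logf_mean_mcmc - logf_mean_oracle)), 0.01)
})

test_that("source-type bias is identified against an unbiased VR anchor", {
  set.seed(8)
  years <- 2000:2022
  vr <- loglinear_obs(u5_0 = 90, arr = 0.03, years = years)
  svy <- loglinear_obs(u5_0 = 90, arr = 0.03, years = years,
                       source_type = "survey_FBH", bias = 0.12, sd = 0.02)
  fit <- b3_fit(rbind(vr, svy), fast_cfg(reference_year = 2023))
  b_med <- median(fit$bias[, "survey_FBH"])
  b_lo <- quantile(fit$bias[, "survey_FBH"], 0.05)
  b_hi <- quantile(fit$bias[, "survey_FBH"], 0.95)
  expect_equal(median(fit$bias[, "VR"]), 0)     # reference fixed at zero
  expect_lt(abs(b_med - 0.12), 0.05)
  expect_true(b_lo <= 0.12 && 0.12 <= b_hi)
})

test_that("convergence diagnostics are attached and gated", {
  obs <- loglinear_obs(years = 2010:2020)
  fit <- b3_fit(obs, fast_cfg(reference_year = 2021))
  expect_true(all(is.finite(fit$rhat)))
  expect_type(fit$converged, "logical")
  expect_error(b3_fit(obs[0, ], fast_cfg()), "extrapolation")
})

test_that("fit methods are coherent", {
  obs <- loglinear_obs(years = 2005:2020)
  fit <- b3_fit(obs, fast_cfg(reference_year = 2021))
  expect_output(print(fit), "Penalized-spline")
  s <- summary(fit)
  expect_s3_class(s, "summary.b3_fit")
  cf <- coef(fit)
  expect_true(all(c("bias_VR", "sigma_VR", "tau") %in% names(cf)))
  expect_equal(length(residuals(fit)), nrow(obs))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(obs), 3L))
  expect_true(all(sim > 0))
  f <- withr::local_tempfile(fileext = ".png")
  png(f); plot(fit); dev.off()
  expect_true(file.exists(f))
})

test_that("extrapolation blends country and global trends equally", {
  years <- 2000:2024
  n_draws <- 50
  ## every draw declines at exactly 4%/yr through 2014, data end there
  draws <- outer(rep(100, n_draws), exp(-0.04 * (years - 2000)))
  tr <- new_trajectories("X", "U5MR", years, draws)
  cfg <- b3_config(trailing_window = 10, reference_year = 2024)
  ex <- extrapolate_trajectories(tr, last_data_year = 2014,
                                 global_arr = 0.02, config = cfg)
  ## applied slope must be 0.5*4% + 0.5*2% = 3%
  slope <- log(ex$draws[1, ex$years == 2014] /
                 ex$draws[1, ex$years == 2024]) / 10
  expect_equal(slope, 0.03, tolerance = 1e-12)
  expect_true(all(!ex$fitted[ex$years > 2014]))
  ## country trend equal to global leaves the slope unchanged
  ex2 <- extrapolate_trajectories(tr, 2014, 0.04, cfg)
  slope2 <- log(ex2$draws[1, ex2$years == 2014] /
                  ex2$draws[1, ex2$years == 2024]) / 10
  expect_equal(slope2, 0.04, tolerance = 1e-12)
  ## data reaching the reference year: identity
  ex3 <- extrapolate_trajectories(tr, 2024, 0.02, cfg)
  expect_identical(ex3$draws, tr$draws)
  expect_error(extrapolate_trajectories(tr, 2014, NA_real_, cfg),
               "global trend")
})

test_that("global trend is birth-weighted and bracketed by member ARRs", {
  years <- 2000:2024
  mk <- function(arr) new_trajectories("X", "U5MR", years,
    outer(rep(100, 20), exp(-arr * (years - 2000))))
  b <- data.frame(year = years, births = 1000)
  cfg <- b3_config(trailing_window = 10)
  ## identical countries: global ARR equals the common ARR
  gt <- compute_global_trend(list(mk(0.03), mk(0.03)), list(b, b), cfg)
  expect_equal(gt$arr, 0.03, tolerance = 1e-10)
  ## single country: equals that country's ARR
  gt1 <- compute_global_trend(list(mk(0.05)), list(b), cfg)
  expect_equal(gt1$arr, 0.05, tolerance = 1e-10)
  ## two equal-birth countries: between the two ARRs
  gt2 <- compute_global_trend(list(mk(0.02), mk(0.06)), list(b, b), cfg)
  expect_gt(gt2$arr, 0.02)
  expect_lt(gt2$arr, 0.06)
  ## weighting oracle on one year
  med1 <- 100 * exp(-0.02 * 24); med2 <- 100 * exp(-0.06 * 24)
  expect_equal(gt2$rates[length(years)], (med1 + med2) / 2,
               tolerance = 1e-8)
})

test_that("interval width grows with years since the last datum", {
  obs_recent <- loglinear_obs(u5_0 = 80, arr = 0.03, years = 2000:2022,
                              sd = 0.03)
  obs_old <- obs_recent[obs_recent$ref_year <= 2010, ]
  f1 <- b3_fit(obs_recent, fast_cfg(reference_year = 2024))
  f2 <- b3_fit(obs_old, fast_cfg(reference_year = 2024))
  w <- function(f) {
    p <- predict(f, 2024)
    log(p$upper / p$lower)
  }
  expect_gt(w(f2), w(f1))
})
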