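test_that("rate-to-hazard conversion satisfies its algebraic identities", {
  ## equal rates: no deaths after the neonatal period
  hz <- rates_to_hazards(15, 15, 15, 2000)
  expect_equal(unname(hz$q[2:3, 1]), c(0, 0))
  expect_equal(unname(hz$h[2:3, 1]), c(0, 0))
  ## survival product over segments reconstructs 1 - u5mr/1000 exactly
  hz2 <- rates_to_hazards(17.2, 27.7, 37.4, 2024)
  dts <- c(28 / 365.25, (365.25 - 28) / 365.25, 4)
  expect_equal(prod(exp(-hz2$h[, 1] * dts)), 1 - 37.4 / 1000,
               tolerance = 1e-12)
  ## conditional post-neonatal probability from published 2024 global rates
  expect_equal(unname(hz2$q[2, 1]), 1 - (1 - 0.0277) / (1 - 0.0172),
               tolerance = 1e-12)
  expect_equal(unname(hz2$q[2, 1]), 0.01068, tolerance = 1e-3)
  expect_error(rates_to_hazards(30, 20, 40, 2000), "ordering")
})

test_that("zero hazards give zero deaths and full survival", {
  b <- data.frame(year = 2000:2002, births = c(1000, 2000, 1500))
  hz <- matrix(0, 3, 8, dimnames = list(NULL, 2000:2007))
  dd <- compute_deaths(b, hz)
  expect_true(all(dd$under5 == 0))
  expect_equal(sum(dd$survivors5), 4500)
})

test_that("steady state reproduces births x U5MR/1000 and conserves cohorts", {
  b <- data.frame(year = 2000:2020, births = 250000)
  hz <- rates_to_hazards(rep(18, 26), rep(30, 26), rep(45, 26), 2000:2025)
  dd <- compute_deaths(b, hz$h)
  mid <- dd$year %in% 2006:2019   # years with full cohort coverage
  expect_lt(max(abs(dd$under5[mid] / (250000 * 45 / 1000) - 1)), 0.001)
  ## conservation: all births either die under 5 or reach age five
  expect_equal(sum(dd$under5) + sum(dd$survivors5), 21 * 250000,
               tolerance = 1e-9)
  ## age-group additivity
  expect_equal(dd$neonatal + dd$d1to59m, dd$under5, tolerance = 1e-12)
  expect_true(all(dd$neonatal <= dd$infant + 1e-12))
  expect_true(all(dd$infant <= dd$under5 + 1e-12))
})

test_that("engine agrees with a daily-resolution microsimulation", {
  set.seed(2)
  years <- 2000:2007
  nmr <- runif(8, 10, 20)
  imr <- nmr + runif(8, 2, 10)
  u5 <- imr + runif(8, 5, 20)
  hz <- rates_to_hazards(nmr, imr, u5, years)
  b <- c("2000" = 120000, "2001" = 100000, "2002" = 90000)
  dd <- compute_deaths(b, hz$h)
  oracle <- daily_microsim(b, hz$h)
  m <- match(oracle$year, dd$year)
  tot_pkg <- sum(dd$under5[m])
  expect_lt(abs(sum(dd$under5[m]) / sum(oracle$under5) - 1), 0.005)
  expect_lt(abs(sum(dd$neonatal[m]) / sum(oracle$neonatal) - 1), 0.005)
  yearly_rel <- abs(dd$under5[m] / oracle$under5 - 1)
  expect_lt(max(yearly_rel[oracle$under5 > 100]), 0.005)
})

test_that("raising a year's hazards never decreases that year's deaths", {
  b <- data.frame(year = 2000:2010, births = 50000)
  base <- rates_to_hazards(rep(12, 16), rep(20, 16), rep(30, 16),
                           2000:2015)$h
  dd0 <- compute_deaths(b, base)
  up <- base
  up[, "2005"] <- up[, "2005"] * 1.5
  dd1 <- compute_deaths(b, up)
  expect_gt(dd1$under5[dd1$year == 2005], dd0$under5[dd0$year == 2005])
  ## later years may see fewer deaths (cohorts depleted earlier), but the
  ## total across all years cannot fall below what the cohorts lose
  expect_gt(sum(dd1$under5), sum(dd0$under5))
})

test_that("a late-year cohort splits its neonatal deaths across the
           calendar boundary", {
  hz <- rates_to_hazards(c(20, 20), c(30, 30), c(40, 40), 2000:2001)
  hzm <- cbind(hz$h, matrix(rep(hz$h[, 2], 4), 3))
  colnames(hzm) <- 2000:2005
  dd <- compute_deaths(c("2000" = 10000), hzm)
  ## most neonatal deaths fall in the birth year, some spill into the next
  expect_gt(dd$neonatal[dd$year == 2000], dd$neonatal[dd$year == 2001])
  expect_gt(dd$neonatal[dd$year == 2001], 0)
  ## oracle agreement on the split itself (finer steps: the spilled amount
  ## is small, so boundary discretization matters)
  oracle <- daily_microsim(c("2000" = 10000), hzm, dt = 1 / (6 * 365.25))
  expect_lt(abs(dd$neonatal[dd$year == 2001] /
                  oracle$neonatal[oracle$year == 2001] - 1), 0.02)
})

test_that("missing hazard years are reported by name", {
  b <- data.frame(year = 2000:2001, births = 1000)
  hz <- matrix(0.01, 3, 3, dimnames = list(NULL, 2000:2002))
  expect_error(compute_deaths(b, hz), "2006")
})

test_that("death draws propagate rate uncertainty with fixed births", {
  years <- 2000:2010
  b <- data.frame(year = 2000:2005, births = 10000)
  n <- 40
  set.seed(9)
  mk <- function(base) new_trajectories("X", "U5MR", years,
    matrix(base * exp(rnorm(n, 0, 0.1)), n, length(years)))
  u5 <- mk(50); imr <- u5; imr$draws <- u5$draws * 0.7
  nmr <- u5; nmr$draws <- u5$draws * 0.4
  dd <- compute_deaths_draws(b, nmr, imr, u5, birth_years = 2000:2005)
  u <- deaths_uncertainty(dd)
  expect_true(all(u$lower <= u$median & u$median <= u$upper))
  ## identical draws collapse to a zero-width interval
  u5c <- const_traj("U5MR", 50, years, n); imc <- const_traj("IMR", 35, years, n)
  nmc <- const_traj("NMR", 20, years, n)
  ddc <- compute_deaths_draws(b, nmc, imc, u5c, birth_years = 2000:2005)
  uc <- deaths_uncertainty(ddc)
  expect_equal(uc$lower, uc$upper, tolerance = 1e-12)
  ## scaling equivariance of percentiles
  dd2 <- dd * 2
  u2 <- deaths_uncertainty(dd2)
  expect_equal(u2$median, 2 * u$median, tolerance = 1e-12)
  ## sort-based percentile oracle on one cell
  cell <- dd[3, "under5", ]
  s <- sort(cell)
  expect_equal(u$median[u$year == as.integer(dimnames(dd)[[1]][3]) &
                          u$age_group == "under5"],
               unname(quantile(s, 0.5)), tolerance = 1e-12)
})
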