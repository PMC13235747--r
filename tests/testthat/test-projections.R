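test_that("decompose/recombine are exact inverses and match the published
           2024 global components", {
  cmp <- decompose_rates(0.0172, 0.0277, 0.0374)
  expect_equal(cmp$pnmr, 0.01068, tolerance = 1e-3)
  expect_equal(cmp$cmr, 0.00998, tolerance = 1e-3)
  rec <- recombine_rates(cmp)
  expect_equal(rec$u5mr, 0.0374, tolerance = 1e-12)
  expect_equal(rec$imr, 0.0277, tolerance = 1e-12)
  ## imr = nmr gives zero post-neonatal component
  expect_equal(decompose_rates(0.02, 0.02, 0.03)$pnmr, 0)
  ## zero pnmr and cmr collapse all three rates
  rec0 <- recombine_rates(list(nmr = 0.01, pnmr = 0, cmr = 0))
  expect_equal(rec0$imr, 0.01)
  expect_equal(rec0$u5mr, 0.01)
  ## random round trips
  set.seed(31)
  for (i in 1:20) {
    n <- runif(1, 1e-4, 0.05); im <- n + runif(1, 0, 0.05)
    u <- im + runif(1, 0, 0.08)
    expect_equal(recombine_rates(decompose_rates(n, im, u))$u5mr, u,
                 tolerance = 1e-14)
  }
  expect_error(decompose_rates(0.05, 0.03, 0.06), "ordering")
})

mk_world_traj <- function(u5_2015, u5_2024, n = 100, years = 2010:2024,
                          seed = 1) {
  set.seed(seed)
  a <- log(u5_2015 / u5_2024) / 9
  path <- u5_2024 * exp(a * (2024 - years))
  noise <- exp(matrix(rnorm(n * length(years), 0, 0.03), n))
  u5 <- new_trajectories("X", "U5MR", years, outer(rep(1, n), path) * noise)
  imr <- u5; imr$draws <- u5$draws * 0.75
  nmr <- u5; nmr$draws <- u5$draws * 0.45
  list(nmr = nmr, imr = imr, u5mr = u5)
}

test_that("scenario ARRs clamp rising mortality at zero and order the
           interval bounds", {
  tra <- mk_world_traj(40, 55)   # mortality rising over 2015-24
  a <- scenario_arr(tra, scenario_spec("current_trends"))
  expect_equal(a$nmr$median, 0)
  expect_equal(a$pnmr$median, 0)
  tra2 <- mk_world_traj(60, 40)
  a2 <- scenario_arr(tra2, scenario_spec("current_trends"))
  expect_true(a2$nmr$lower <= a2$nmr$median)
  expect_true(a2$nmr$median <= a2$nmr$upper)
  expect_gt(a2$nmr$median, 0)
})

test_that("constant scenario freezes 2024 rates through 2030", {
  tra <- mk_world_traj(60, 40)
  arrs <- scenario_arr(tra, scenario_spec("constant"))
  r24 <- c(nmr = 18, imr = 30, u5mr = 40)
  p <- project_rates(r24, arrs, scenario_spec("constant"))
  expect_equal(p$u5mr, rep(40, 7), tolerance = 1e-12)
  expect_equal(p$nmr, rep(18, 7), tolerance = 1e-12)
})

test_that("current trends declines log-linearly with absorbing floors", {
  arrs <- list(nmr = list(median = 0.05, lower = 0.02, upper = 0.08),
               pnmr = list(median = 0.05, lower = 0.02, upper = 0.08),
               cmr = list(median = 0.05, lower = 0.02, upper = 0.08))
  sp <- scenario_spec("current_trends")
  r24 <- c(nmr = 20, imr = 32, u5mr = 45)
  p <- project_rates(r24, arrs, sp)
  cmp0 <- decompose_rates(0.020, 0.032, 0.045)
  expect_equal(p$nmr_q, cmp0$nmr * exp(-0.05 * (0:6)), tolerance = 1e-12)
  ## a country starting at the neonatal floor stays there
  r_floor <- c(nmr = 0.7, imr = 0.85, u5mr = 1.2)
  pf <- project_rates(r_floor, arrs, sp)
  expect_equal(pf$nmr_q, rep(0.0007, 7), tolerance = 1e-12)
  ## once a path hits the floor it never moves again (absorbing)
  arrs_fast <- lapply(arrs, function(x) list(median = 0.5, lower = 0.5,
                                             upper = 0.5))
  pfast <- project_rates(c(nmr = 1.0, imr = 1.3, u5mr = 1.8), arrs_fast, sp)
  at_floor <- which(abs(pfast$nmr_q - 0.0007) < 1e-12)
  expect_true(length(at_floor) >= 2)
  expect_true(all(diff(at_floor) == 1))
  expect_true(all(pfast$nmr_q >= 0.0007 - 1e-15))
  ## lower/upper ARR variants bracket the median path
  pl <- project_rates(r24, arrs, scenario_spec("current_trends_lower"))
  pu <- project_rates(r24, arrs, scenario_spec("current_trends_upper"))
  expect_true(all(pu$u5mr <= p$u5mr & p$u5mr <= pl$u5mr))
})

test_that("SDG and high-income scenarios hit their targets exactly in 2030
           for off-track countries", {
  arrs <- lapply(list(1, 2, 3), function(i)
    list(median = 0.01, lower = 0.0, upper = 0.02))
  names(arrs) <- c("nmr", "pnmr", "cmr")
  r24 <- c(nmr = 22, imr = 38, u5mr = 50)   # far off track
  p_sdg <- project_rates(r24, arrs, scenario_spec("sdg_target"))
  expect_equal(p_sdg$u5mr[p_sdg$year == 2030], 25, tolerance = 1e-9)
  expect_equal(p_sdg$nmr[p_sdg$year == 2030], 12, tolerance = 1e-9)
  p_hic <- project_rates(r24, arrs, scenario_spec("high_income"))
  expect_equal(p_hic$u5mr[p_hic$year == 2030], 5.1, tolerance = 1e-9)
  expect_equal(p_hic$nmr[p_hic$year == 2030], 2.8, tolerance = 1e-9)
  ## internal consistency along the target paths
  expect_true(all(p_sdg$nmr <= p_sdg$imr + 1e-12))
  expect_true(all(p_sdg$imr <= p_sdg$u5mr + 1e-12))
  ## on-track countries keep the current-trends projection
  r_low <- c(nmr = 2.0, imr = 3.0, u5mr = 4.5)
  p_ct <- project_rates(r_low, arrs, scenario_spec("current_trends"))
  p_sdg2 <- project_rates(r_low, arrs, scenario_spec("sdg_target"))
  p_hic2 <- project_rates(r_low, arrs, scenario_spec("high_income"))
  expect_equal(p_sdg2$u5mr, p_ct$u5mr, tolerance = 1e-12)
  expect_equal(p_hic2$u5mr, p_ct$u5mr, tolerance = 1e-12)
  expect_error(project_rates(r24, arrs, structure(list(kind = "bogus"),
                                                  class = "scenario_spec")))
})

test_that("floors derived from a synthetic world use only large countries", {
  r <- data.frame(country_id = c("A", "B", "C"),
                  nmr = c(1.0, 0.5, 3.0), imr = c(1.5, 0.8, 5.0),
                  u5mr = c(2.0, 1.0, 8.0),
                  births = c(50000, 5000, 200000))
  fl <- compute_floors(r, min_births = 10000)
  ## country B is below the threshold and cannot define the floor
  expect_equal(unname(fl["nmr"]), 1.0, tolerance = 1e-9)
  expect_error(compute_floors(r, min_births = 1e7), "threshold")
})

test_that("cumulative projected deaths respect the scenario ordering", {
  set.seed(77)
  for (rep in 1:3) {
    u5_24 <- runif(1, 20, 90)
    tra <- mk_world_traj(u5_24 * runif(1, 1.1, 1.6), u5_24, seed = rep)
    arrs <- scenario_arr(tra, scenario_spec("current_trends"))
    r24 <- c(nmr = u5_24 * 0.45, imr = u5_24 * 0.75, u5mr = u5_24)
    births <- data.frame(year = 2019:2030, births = 100000)
    est <- data.frame(year = 2019:2024, nmr = u5_24 * 0.45,
                      imr = u5_24 * 0.75, u5mr = u5_24)
    total <- sapply(c("high_income", "sdg_target", "current_trends",
                      "constant"), function(k) {
      p <- project_rates(r24, arrs, scenario_spec(k))
      rates <- rbind(est, p[p$year > 2024, c("year", "nmr", "imr", "u5mr")])
      projected_deaths(rates, births)$cumulative[["under5"]]
    })
    expect_true(all(diff(total) >= -1e-9))   # hic <= sdg <= ct <= constant
  }
})

test_that("projected deaths validate inputs and report averted deaths", {
  births <- data.frame(year = 2020:2030, births = 50000)
  rates <- data.frame(year = 2020:2030, nmr = 10, imr = 18, u5mr = 25)
  pd <- projected_deaths(rates, births)
  expect_equal(nrow(pd$by_year), 6)
  ## zero rates are impossible (hazard needs positive nmr) but tiny rates
  ## give tiny deaths
  rates0 <- data.frame(year = 2020:2030, nmr = 1e-6, imr = 2e-6,
                       u5mr = 3e-6)
  pd0 <- projected_deaths(rates0, births)
  expect_lt(pd0$cumulative[["under5"]], 1)
  av <- averted_deaths(pd, pd0)
  expect_true(av[["under5"]] > 0)
  expect_equal(av[["under5"]],
               pd$cumulative[["under5"]] - pd0$cumulative[["under5"]])
  expect_error(projected_deaths(rates[rates$year > 2022, ], births),
               "cover")
})
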