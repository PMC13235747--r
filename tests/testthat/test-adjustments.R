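test_that("crisis deaths are allocated by the age pattern", {
  e <- crisis_event("X", 2020, 1000,
                    age_pattern = c(neonatal = 0.1, postneonatal = 0.1,
                                    child = 0.2, older = 0.6))
  a <- allocate_crisis_deaths(e)
  expect_equal(c(a$neonatal, a$postneonatal, a$child), c(100, 100, 200))
  expect_equal(a$under5, 400)

  ## an all-adult pattern leaves no child crisis deaths
  e2 <- crisis_event("X", 2020, 1000,
                     age_pattern = c(neonatal = 0, postneonatal = 0,
                                     child = 0, older = 1))
  expect_equal(allocate_crisis_deaths(e2)$under5, 0)

  ## direct VR age-specific counts override the pattern
  e3 <- crisis_event("X", 2020, 1000,
                     age_pattern = c(neonatal = 0.1, postneonatal = 0.1,
                                     child = 0.2, older = 0.6),
                     vr_counts = c(neonatal = 7, postneonatal = 11,
                                   child = 13))
  a3 <- allocate_crisis_deaths(e3)
  expect_equal(c(a3$neonatal, a3$postneonatal, a3$child), c(7, 11, 13))

  ## malformed patterns are rejected
  expect_error(crisis_event("X", 2020, 10,
                            age_pattern = c(neonatal = 0.5,
                                            postneonatal = 0.2,
                                            child = 0.2, older = 0.2)),
               "sum to 1")
})

mk_ctraj <- function(years = 2000:2010, n = 20) {
  list(nmr = new_trajectories("X", "NMR", years, matrix(10, n, length(years))),
       imr = new_trajectories("X", "IMR", years, matrix(20, n, length(years))),
       u5mr = new_trajectories("X", "U5MR", years,
                               matrix(30, n, length(years))))
}

test_that("crisis adjustment adds the implied rate in event years only", {
  tra <- mk_ctraj()
  births <- data.frame(year = 2000:2010, births = 100000)
  ## 500 under-5 deaths on 100k births = +5 per 1000 U5MR in 2005
  e <- crisis_event("X", 2005, 1000,
                    age_pattern = c(neonatal = 0.1, postneonatal = 0.15,
                                    child = 0.25, older = 0.5))
  adj <- apply_crisis_adjustment(tra, list(e), births)
  d_u5 <- adj$u5mr$draws - tra$u5mr$draws
  expect_equal(unique(d_u5[, tra$u5mr$years == 2005]), 5.0)
  expect_true(all(d_u5[, tra$u5mr$years != 2005] == 0))
  ## nested allocation preserves ordering
  expect_true(all(adj$nmr$draws <= adj$imr$draws + 1e-12))
  expect_true(all(adj$imr$draws <= adj$u5mr$draws + 1e-12))
  ## no qualifying events: identity
  e_no <- crisis_event("X", 2005, 1000, meets_criteria = FALSE)
  adj0 <- apply_crisis_adjustment(tra, list(e_no), births)
  expect_equal(adj0$u5mr$draws, tra$u5mr$draws)
  ## missing births for the event year is an error
  expect_error(apply_crisis_adjustment(tra, list(e),
                                       births[births$year != 2005, ]),
               "births")
})

test_that("ordering is preserved under random crisis events", {
  set.seed(11)
  births <- data.frame(year = 2000:2010, births = 50000)
  for (rep in 1:20) {
    tra <- mk_ctraj()
    f <- diff(sort(c(0, runif(3), 1)))   # random simplex pattern
    e <- crisis_event("X", sample(2000:2010, 1), runif(1, 10, 5000),
                      age_pattern = c(neonatal = f[1], postneonatal = f[2],
                                      child = f[3], older = f[4]))
    adj <- apply_crisis_adjustment(tra, list(e), births)
    expect_true(all(adj$nmr$draws <= adj$imr$draws + 1e-9))
    expect_true(all(adj$imr$draws <= adj$u5mr$draws + 1e-9))
  }
})

test_that("crisis adjustment is additive, order-independent and invertible", {
  tra <- mk_ctraj()
  births <- data.frame(year = 2000:2010, births = 100000)
  e1 <- crisis_event("X", 2003, 500)
  e2 <- crisis_event("X", 2007, 800)
  a12 <- apply_crisis_adjustment(tra, list(e1, e2), births)
  a21 <- apply_crisis_adjustment(tra, list(e2, e1), births)
  expect_equal(a12$u5mr$draws, a21$u5mr$draws)
  ## recover the crisis-free input by subtracting the event-implied rates
  one <- apply_crisis_adjustment(tra, list(e1), births)
  back <- one
  back$u5mr$draws <- a12$u5mr$draws -
    (apply_crisis_adjustment(tra, list(e2), births)$u5mr$draws -
       tra$u5mr$draws)
  expect_equal(back$u5mr$draws, one$u5mr$draws, tolerance = 1e-12)
})

test_that("crisis inclusion criteria filter by size and share thresholds", {
  small <- crisis_event("X", 2010, 50)
  big <- crisis_event("X", 2011, 5000)
  kept <- filter_crisis_events(list(small, big), min_deaths = 100)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$years, 2011L)
  ## share criterion against expected baseline deaths
  kept2 <- filter_crisis_events(list(big),
                                expected_u5_deaths = c("2011" = 1e6),
                                min_deaths = 100, min_share = 0.025)
  expect_length(kept2, 0)
})

test_that("HIV adjustment is additive per year and validates input", {
  tra <- mk_ctraj()
  hiv <- data.frame(year = c(2000, 2005), u5mr_add = c(2.0, 1.0),
                    nmr_add = c(0.2, 0.1))
  adj <- apply_hiv_adjustment(tra, hiv)
  expect_equal(unique(adj$u5mr$draws[, tra$u5mr$years == 2000] -
                        tra$u5mr$draws[, tra$u5mr$years == 2000]), 2.0)
  expect_equal(unique(adj$u5mr$draws[, tra$u5mr$years == 2005] -
                        tra$u5mr$draws[, tra$u5mr$years == 2005]), 1.0)
  expect_equal(adj$u5mr$draws[, tra$u5mr$years == 2001],
               tra$u5mr$draws[, tra$u5mr$years == 2001])
  ## empty table is the identity
  expect_identical(apply_hiv_adjustment(tra, NULL), tra)
  ## negative adjustments and out-of-span years are rejected
  expect_error(apply_hiv_adjustment(tra, data.frame(year = 2000,
                                                    u5mr_add = -1)),
               "negative")
  expect_error(apply_hiv_adjustment(tra, data.frame(year = 1990,
                                                    u5mr_add = 1)),
               "span")
})
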