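# Independent oracles used across tests.  Each reimplements the quantity it
# checks from first principles, sharing no code with the package internals.

# textbook Cox-de-Boor recursion for a single B-spline basis function
cox_de_boor <- function(x, knots, i, p) {
  if (p == 0) {
    return(as.numeric(knots[i] <= x & x < knots[i + 1]))
  }
  d1 <- knots[i + p] - knots[i]
  d2 <- knots[i + p + 1] - knots[i + 1]
  a <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(x, knots, i, p - 1) else 0
  b <- if (d2 > 0) (knots[i + p + 1] - x) / d2 *
         cox_de_boor(x, knots, i + 1, p - 1) else 0
  a + b
}

cox_de_boor_basis <- function(x, knots, degree) {
  k <- length(knots) - degree - 1
  vapply(seq_len(k), function(i) cox_de_boor(x, knots, i, degree),
         numeric(length(x)))
}

# daily-resolution microsimulation of cohort survival: independent check of
# the 52-weekly-cohort deaths engine.  hz is the 3 x n_years hazard matrix
# (per person-year) with year colnames; births a named vector by birth year.
daily_microsim <- function(births, hz, dt = 1 / 365.25) {
  age_breaks <- c(0, 28 / 365.25, 1, 5)
  years <- as.integer(colnames(hz))
  out_years <- min(as.integer(names(births))):(max(as.integer(names(births))) + 5L)
  deaths <- matrix(0, length(out_years), 3, dimnames = list(out_years, NULL))
  for (by in as.integer(names(births))) {
    for (w in 1:52) {
      entry <- by + (w - 0.5) / 52
      n_steps <- ceiling(5 / dt)
      t_mid <- entry + (seq_len(n_steps) - 0.5) * dt
      age_mid <- t_mid - entry
      keep <- age_mid < 5
      t_mid <- t_mid[keep]; age_mid <- age_mid[keep]
      seg <- findInterval(age_mid, age_breaks)
      yr <- findInterval(t_mid, years)
      h <- hz[cbind(seg, yr)]
      step_dt <- rep(dt, length(t_mid))
      step_dt[length(step_dt)] <- 5 - age_mid[length(age_mid)] + dt / 2
      H <- h * step_dt
      S_entry <- exp(-c(0, cumsum(H)[-length(H)]))
      d <- (births[[as.character(by)]] / 52) * S_entry * (1 - exp(-H))
      for (s in 1:3) {
        agg <- rowsum(d[seg == s], floor(t_mid[seg == s]))
        i <- match(rownames(agg), rownames(deaths))
        deaths[i, s] <- deaths[i, s] + agg[, 1]
      }
    }
  }
  data.frame(year = out_years, neonatal = deaths[, 1],
             d1to59m = deaths[, 2] + deaths[, 3],
             under5 = rowSums(deaths))
}

# quick constant-rate trajectory container for engine tests
const_traj <- function(indicator, value, years, n_draws = 2) {
  new_trajectories("X", indicator, years,
                   matrix(value, n_draws, length(years)))
}

# small noise-free single-series dataset on a log-linear truth; annual
# observations are referenced to mid-year (t + 0.5), the package convention
loglinear_truth <- function(u5_0, arr, t0) function(t) u5_0 * exp(-arr * (t - t0))
loglinear_obs <- function(u5_0 = 100, arr = 0.03, years = 2000:2020,
                          source_type = "VR", bias = 0, sd = 0) {
  tf <- loglinear_truth(u5_0, arr, years[1])
  t_ref <- years + 0.5
  true <- tf(t_ref)
  value <- true * exp(bias + if (sd > 0) rnorm(length(years), 0, sd) else 0)
  data.frame(country_id = "X", series_id = paste0("S_", source_type),
             source_type = source_type, indicator = "U5MR",
             ref_year = t_ref,
             value = value, se = pmax(value * 0.015, 1e-6),
             stringsAsFactors = FALSE)
}
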