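## ---------------------------------------------------------------------------
## Deaths engine: converts annual NMR/IMR/U5MR trajectories and live births
## into death counts by age group and calendar year.  Each annual birth
## cohort is divided into 52 equal birth-week cohorts entering at week
## midpoints; each cohort is exposed over its first five years of life to
## piecewise-constant hazards on the age segments [0, 28d), [28d, 1y),
## [1y, 5y), switching to each new calendar year's hazards at the year
## boundary.  Deaths are allocated to the calendar year in which they occur
## and to the age group at death.
## ---------------------------------------------------------------------------

NEONATAL_BOUNDARY <- 28 / 365.25
AGE_BREAKS <- c(0, NEONATAL_BOUNDARY, 1, 5)

#' Convert annual rates to age-segment hazards
#'
#' The cumulative-probability rates are decomposed into conditional
#' probabilities per age segment, q1 = nmr/1000,
#' q2 = 1 - (1 - imr/1000) / (1 - nmr/1000),
#' q3 = 1 - (1 - u5mr/1000) / (1 - imr/1000), then each is converted to a
#' constant hazard on its segment, h = -log(1 - q) / dt with segment widths
#' 28/365.25, (365.25 - 28)/365.25, and 4 years.  The survival product over
#' the three segments reconstructs 1 - u5mr/1000 exactly.
#'
#' @param nmr,imr,u5mr rates per 1000 live births (vectors over years),
#'   with 0 < nmr <= imr <= u5mr < 1000.
#' @param years calendar years labelling the columns.
#' @return list with matrices `q` and `h` (3 x n_years, rows `neonatal`,
#'   `postneonatal`, `child`).
#' @export
rates_to_hazards <- function(nmr, imr, u5mr, years = seq_along(nmr)) {
  stop_if(any(nmr <= 0) || any(u5mr >= 1000),
          "rates must satisfy 0 < rate < 1000")
  stop_if(any(nmr > imr + 1e-12) || any(imr > u5mr + 1e-12),
          "ordering violated: need nmr <= imr <= u5mr")
  q1 <- nmr / 1000
  q2 <- 1 - (1 - imr / 1000) / (1 - q1)
  q3 <- 1 - (1 - u5mr / 1000) / (1 - imr / 1000)
  q <- rbind(neonatal = q1, postneonatal = pmax(q2, 0), child = pmax(q3, 0))
  dt <- diff(AGE_BREAKS)
  h <- -log(1 - q) / dt
  colnames(q) <- colnames(h) <- years
  list(q = q, h = h)
}

## Exposure intervals of a cohort entering at fractional year `frac` within
## its birth year: each interval lies inside one age segment and one
## calendar year.  Returns year_offset (0-based), segment index, duration.
cohort_interval_pattern <- function(frac) {
  breaks <- sort(unique(c(AGE_BREAKS,
                          seq(ceiling(frac), frac + 5) - frac)))
  breaks <- breaks[breaks >= 0 & breaks <= 5 + 1e-12]
  a0 <- breaks[-length(breaks)]
  a1 <- breaks[-1]
  mid <- (a0 + a1) / 2
  data.frame(year_offset = floor(frac + mid),
             seg = findInterval(mid, AGE_BREAKS),
             dt = a1 - a0)
}

## interval table for 52 weekly cohorts of a single birth year
weekly_interval_table <- function() {
  parts <- lapply(1:52, function(k) {
    p <- cohort_interval_pattern((k - 0.5) / 52)
    p$week <- k
    p
  })
  do.call(rbind, parts)
}

## Precompute the exposure structure for a set of birth years: per interval,
## the flat (segment, year) hazard index, duration, cohort grouping for the
## running survival product, and output aggregation keys.  Depends only on
## the birth years and hazard year grid, so it is reused across posterior
## draws.
build_cohort_exposure <- function(birth_years, hz_years) {
  need <- min(birth_years):(max(birth_years) + 5L)
  missing_y <- setdiff(need, hz_years)
  stop_if(length(missing_y) > 0, "missing hazard year(s): ",
          paste(missing_y, collapse = ", "))
  wt <- weekly_interval_table()
  nwt <- nrow(wt)
  nby <- length(birth_years)
  ## rows are already grouped by week within the weekly table; replicate
  ## across birth years keeping each cohort's intervals contiguous
  ord <- order(wt$week)
  wt <- wt[ord, ]
  tab_year <- rep(birth_years, each = nwt) + wt$year_offset
  tab_seg <- rep(wt$seg, nby)
  tab_dt <- rep(wt$dt, nby)
  cohort <- rep((seq_len(nby) - 1L) * 52L, each = nwt) + rep(wt$week, nby)
  o <- order(cohort)
  tab_year <- tab_year[o]; tab_seg <- tab_seg[o]; tab_dt <- tab_dt[o]
  cohort <- cohort[o]
  birth_of_row <- rep(birth_years, each = nwt)[o]
  grp_start <- which(!duplicated(cohort))
  grp_len <- diff(c(grp_start, length(cohort) + 1L))
  out_years <- sort(unique(tab_year))
  gid <- match(tab_year, out_years) + (tab_seg - 1L) * length(out_years)
  list(idx_flat = (match(tab_year, hz_years) - 1L) * 3L + tab_seg,
       dt = tab_dt, grp_start = grp_start, grp_len = grp_len,
       gid = gid, n_groups = 3L * length(out_years),
       out_years = out_years, birth_of_row = birth_of_row,
       last_row = c(grp_start[-1] - 1L, length(cohort)),
       hz_years = hz_years)
}

## running within-cohort cumulative sum (rows grouped contiguously)
grouped_cumsum <- function(x, exposure) {
  cs <- cumsum(x)
  base <- c(0, cs[exposure$grp_start[-1] - 1L])
  cs - rep(base, times = exposure$grp_len)
}

## deaths by (year, segment) for one hazard matrix (3 x n_years, flattened
## column-major) given a precomputed exposure structure and cohort sizes
deaths_one_draw <- function(hz_flat, exposure, size_of_row) {
  H <- hz_flat[exposure$idx_flat] * exposure$dt
  csum <- grouped_cumsum(H, exposure)
  deaths <- size_of_row * exp(-(csum - H)) * (1 - exp(-H))
  agg <- numeric(exposure$n_groups)
  sums <- rowsum(deaths, exposure$gid)
  agg[as.integer(rownames(sums))] <- sums[, 1]
  matrix(agg, ncol = 3, dimnames = list(exposure$out_years,
                                        c("neonatal", "postneonatal",
                                          "child")))
}

#' Compute death counts from births and hazards
#'
#' Implements the 52-weekly-birth-cohort calculation.  Hazards must cover
#' the first five years of life of every birth cohort (`max(birth years)+5`);
#' a missing hazard year is an error naming the year.
#'
#' @param births data frame (`year`, `births`) or named numeric vector.
#' @param hazards `h` matrix from [rates_to_hazards()] with year colnames
#'   covering every exposure year.
#' @return data frame per calendar year with death counts `neonatal`,
#'   `d1to59m` (28 days-4 years), `infant` (under 1), `under5`, plus
#'   `survivors5` — children reaching exact age five that year.
#' @export
compute_deaths <- function(births, hazards) {
  if (is.data.frame(births)) {
    b <- stats::setNames(births$births, births$year)
  } else b <- births
  birth_years <- as.integer(names(b))
  hz_years <- as.integer(colnames(hazards))
  ex <- build_cohort_exposure(birth_years, hz_years)
  size <- b[as.character(ex$birth_of_row)] / 52

  dmat <- deaths_one_draw(as.vector(hazards[, match(ex$hz_years, hz_years)]),
                          ex, size)

  ## survivors to exact age five, by the calendar year they turn five
  H <- as.vector(hazards)[ex$idx_flat] * ex$dt
  tot <- grouped_cumsum(H, ex)[ex$last_row]
  surv <- (b[as.character(ex$birth_of_row[ex$last_row])] / 52) * exp(-tot)
  surv_year <- ex$birth_of_row[ex$last_row] + 5L
  surv_by_year <- rowsum(surv, surv_year)

  res <- data.frame(year = ex$out_years,
                    neonatal = dmat[, "neonatal"],
                    d1to59m = dmat[, "postneonatal"] + dmat[, "child"],
                    infant = dmat[, "neonatal"] + dmat[, "postneonatal"],
                    under5 = rowSums(dmat))
  res$survivors5 <- 0
  m <- match(rownames(surv_by_year), as.character(res$year))
  res$survivors5[m] <- surv_by_year[, 1]
  rownames(res) <- NULL
  res
}

#' Deaths per posterior draw
#'
#' Runs [compute_deaths()] for each posterior draw of the rate trajectories.
#'
#' @param births data frame (`year`, `births`).
#' @param nmr_traj,imr_traj,u5mr_traj matched [new_trajectories()] covering
#'   every exposure year.
#' @param birth_years the cohort years to expose (default: trajectory years
#'   ending five years before the last trajectory year).
#' @return 3-d array `year x age_group x draw` of death counts.
#' @export
compute_deaths_draws <- function(births, nmr_traj, imr_traj, u5mr_traj,
                                 birth_years = NULL) {
  years <- u5mr_traj$years
  if (is.null(birth_years)) {
    birth_years <- years[years <= max(years) - 5L]
    stop_if(length(birth_years) == 0,
            "trajectory span too short to expose any cohort fully")
  }
  bsel <- births[births$year %in% birth_years, ]
  stop_if(!all(birth_years %in% bsel$year), "births missing for some ",
          "birth cohort years")
  b <- stats::setNames(bsel$births, bsel$year)
  n_draws <- nrow(u5mr_traj$draws)
  ex <- build_cohort_exposure(as.integer(names(b)), years)
  size <- b[as.character(ex$birth_of_row)] / 52
  ## per-draw hazards, vectorized over years (3 x n_years flattened)
  q1 <- nmr_traj$draws / 1000
  q2 <- 1 - (1 - imr_traj$draws / 1000) / (1 - q1)
  q3 <- 1 - (1 - u5mr_traj$draws / 1000) / (1 - imr_traj$draws / 1000)
  stop_if(any(q2 < -1e-9) || any(q3 < -1e-9),
          "ordering violated in trajectory draws")
  dts <- diff(AGE_BREAKS)
  out <- NULL
  for (d in seq_len(n_draws)) {
    hz_flat <- as.vector(rbind(-log(1 - q1[d, ]) / dts[1],
                               -log(1 - pmax(q2[d, ], 0)) / dts[2],
                               -log(1 - pmax(q3[d, ], 0)) / dts[3]))
    dmat <- deaths_one_draw(hz_flat, ex, size)
    if (is.null(out)) {
      out <- array(0, c(nrow(dmat), 4, n_draws),
                   dimnames = list(rownames(dmat),
                                   c("neonatal", "d1to59m", "infant",
                                     "under5"), NULL))
    }
    out[, , d] <- cbind(dmat[, 1], dmat[, 2] + dmat[, 3],
                        dmat[, 1] + dmat[, 2], rowSums(dmat))
  }
  out
}

#' Summarise death draws into medians and 90% intervals
#'
#' Percentiles are taken across draws per cell; live births are treated as
#' fixed, so the intervals reflect mortality-rate uncertainty only.
#'
#' @param death_draws array from [compute_deaths_draws()] (needs >= 2 draws
#'   for a non-degenerate interval).
#' @return data frame with `year`, `age_group`, `lower`, `median`, `upper`.
#' @export
deaths_uncertainty <- function(death_draws) {
  stop_if(length(dim(death_draws)) != 3, "expected a year x age x draw array")
  yrs <- dimnames(death_draws)[[1]]
  ages <- dimnames(death_draws)[[2]]
  rows <- expand.grid(year = as.integer(yrs), age_group = ages,
                      stringsAsFactors = FALSE)
  q <- apply(death_draws, c(1, 2), stats::quantile,
             probs = c(0.05, 0.5, 0.95), names = FALSE)
  rows$lower <- as.vector(q[1, , ])
  rows$median <- as.vector(q[2, , ])
  rows$upper <- as.vector(q[3, , ])
  rows
}
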