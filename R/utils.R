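#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## run expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483646L) + 1L)
  }
  force(expr)
}

## deterministic sub-seed for stream i of a master seed (kept < 2^31)
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483629)
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

#' Posterior rate trajectories
#'
#' Container for posterior draws of an annual mortality-rate trajectory for
#' one country and indicator.  This is the common currency passed between the
#' spline fit, the neonatal ratio model, the adjustment layer, the deaths
#' engine, the metrics, and the projections.
#'
#' @param country_id country identifier.
#' @param indicator one of `"U5MR"`, `"IMR"`, `"NMR"`.
#' @param years integer vector of contiguous calendar years.
#' @param draws numeric matrix, `n_draws x length(years)`, rates in deaths
#'   per 1000 live births; all entries must be strictly positive.
#' @param fitted logical vector per year: `TRUE` for years inside the
#'   observed period, `FALSE` for extrapolated years.
#'
#' @return an object of class `mortality_trajectories`.
#' @export
new_trajectories <- function(country_id, indicator, years, draws,
                             fitted = rep(TRUE, length(years))) {
  years <- as.integer(years)
  stop_if(length(years) < 1L, "need at least one year")
  stop_if(any(diff(years) != 1L), "years must be contiguous")
  draws <- as.matrix(draws)
  stop_if(ncol(draws) != length(years),
          "draws must have one column per year")
  stop_if(any(!is.finite(draws)) || any(draws <= 0),
          "trajectory draws must be finite and strictly positive")
  stop_if(length(fitted) != length(years), "fitted flag must match years")
  structure(
    list(country_id = country_id, indicator = indicator, years = years,
         draws = draws, fitted = as.logical(fitted)),
    class = "mortality_trajectories"
  )
}

#' @export
print.mortality_trajectories <- function(x, ...) {
  cat(sprintf("<mortality_trajectories> %s %s, %d-%d, %d draws\n",
              x$country_id, x$indicator, min(x$years), max(x$years),
              nrow(x$draws)))
  q <- traj_quantiles(x)
  show <- q[q$year %in% range(x$years), ]
  print(show, row.names = FALSE)
  invisible(x)
}

#' Posterior summaries of a trajectory
#'
#' @param traj a [new_trajectories()] object.
#' @param probs quantile probabilities; default gives the 90% interval
#'   bounds and the median.
#' @return data frame with columns `year`, `lower`, `median`, `upper` (for
#'   the default probs) or `year` plus one column per probability.
#' @export
traj_quantiles <- function(traj, probs = c(0.05, 0.5, 0.95)) {
  q <- apply(traj$draws, 2, stats::quantile, probs = probs, names = FALSE)
  q <- if (is.null(dim(q))) matrix(q, nrow = 1) else q
  out <- data.frame(year = traj$years, t(q))
  nm <- if (identical(probs, c(0.05, 0.5, 0.95))) c("lower", "median", "upper")
        else paste0("q", probs * 100)
  names(out)[-1] <- nm
  out
}

## extract the draw matrix restricted to a set of years
traj_window <- function(traj, years) {
  idx <- match(years, traj$years)
  stop_if(anyNA(idx), "requested years outside trajectory span: ",
          paste(years[is.na(idx)], collapse = ", "))
  traj$draws[, idx, drop = FALSE]
}

#' Format an estimate with its 90% uncertainty interval
#'
#' Renders `"median (lower to upper)"` in the conventional reporting style.
#'
#' @param med,lo,hi numeric vectors.
#' @param digits decimals to print.
#' @return character vector.
#' @export
format_ui <- function(med, lo, hi, digits = 1) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f to %.", digits, "f)"),
          med, lo, hi)
}

## split-chain potential scale reduction factor (two half-chains per chain)
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (d in draws_by_chain) {
    n <- length(d)
    h <- floor(n / 2)
    halves[[length(halves) + 1L]] <- d[seq_len(h)]
    halves[[length(halves) + 1L]] <- d[(n - h + 1L):n]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
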