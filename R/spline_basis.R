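#' Build an equally spaced B-spline basis
#'
#' Constructs a degree-`degree` B-spline basis with equally spaced interior
#' knots covering a year span.  Knots extend `degree` spacings beyond each
#' boundary so that the basis forms a partition of unity (rows sum to one)
#' over the whole span.
#'
#' @param years numeric grid (at least two points) the basis will be
#'   evaluated on; typically `min_year:reference_year`.
#' @param knot_spacing distance between adjacent knots, in years (> 0).
#' @param degree spline degree (3 = cubic).
#' @return object of class `spline_basis` with elements `years`, `knots`,
#'   `degree`, and the basis matrix `B` (`length(years) x n_basis`).
#' @export
build_basis <- function(years, knot_spacing = 2.5, degree = 3) {
  years <- as.numeric(years)
  stop_if(length(years) < 2, "need at least two grid years")
  stop_if(knot_spacing <= 0, "knot spacing must be positive")
  lo <- min(years); hi <- max(years)
  stop_if(hi <= lo, "degenerate year grid")
  n_int <- max(1L, ceiling((hi - lo) / knot_spacing))
  h <- (hi - lo) / n_int
  knots <- seq(lo - degree * h, hi + degree * h, by = h)
  B <- splines::splineDesign(knots, years, ord = degree + 1L)
  structure(list(years = years, knots = knots, degree = degree, B = B),
            class = "spline_basis")
}

#' Evaluate a spline basis at new points
#'
#' @param basis a [build_basis()] object.
#' @param x points inside the basis span.
#' @return matrix `length(x) x n_basis`.
#' @export
eval_basis <- function(basis, x) {
  lo <- min(basis$years); hi <- max(basis$years)
  stop_if(any(x < lo - 1e-9) || any(x > hi + 1e-9),
          "evaluation points outside basis span")
  splines::splineDesign(basis$knots, pmin(pmax(x, lo), hi),
                        ord = basis$degree + 1L)
}

## d-th order difference penalty matrix for k coefficients
difference_matrix <- function(k, order = 2) {
  stop_if(k <= order, "too few basis functions for the penalty order")
  diff(diag(k), differences = order)
}
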