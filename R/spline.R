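#' Quadratic B-spline specification for class mean trajectories
#'
#' The class mean trajectories are quadratic B-splines with (by default) one
#' internal knot; the basis spans constants, so the class coefficient vectors
#' absorb the trajectory level and no separate intercept is used. Boundary
#' knots are fixed at the analysis window so bases are comparable across fits.
#'
#' @param internal_knots numeric vector of internal knot locations (weeks).
#' @param boundary_knots length-2 numeric, the analysis window bounds.
#' @param degree spline degree (2 = quadratic).
#' @return An object of class `spline_spec` with basis dimension
#'   `p = degree + 1 + length(internal_knots)`.
#' @export
spline_spec <- function(internal_knots, boundary_knots = c(14, 37),
                        degree = 2) {
  .assert(length(boundary_knots) == 2 && boundary_knots[1] < boundary_knots[2],
          "boundary_knots must be increasing length-2")
  .assert(degree >= 1, "degree must be >= 1")
  internal_knots <- sort(as.numeric(internal_knots))
  if (length(internal_knots) &&
      (any(internal_knots <= boundary_knots[1]) ||
       any(internal_knots >= boundary_knots[2])))
    stop("internal knots must lie strictly inside the boundary knots",
         call. = FALSE)
  structure(list(degree = as.integer(degree),
                 internal_knots = internal_knots,
                 boundary_knots = as.numeric(boundary_knots),
                 p = as.integer(degree + 1 + length(internal_knots))),
            class = "spline_spec")
}

#' Place the internal knot at the pooled median scan age
#'
#' Single internal knot at the median of all pooled scan gestational ages
#' (even count: mean of the central pair, i.e. the usual sample median);
#' boundary knots at the analysis window bounds.
#'
#' @param all_scan_ga numeric vector of pooled gestational ages (weeks) across
#'   all retained scans.
#' @param boundary_knots analysis window bounds (weeks).
#' @param degree spline degree.
#' @return A [spline_spec()].
#' @export
place_knots <- function(all_scan_ga, boundary_knots = c(14, 37), degree = 2) {
  .assert(length(all_scan_ga) > 0, "no scan ages supplied")
  if (length(unique(all_scan_ga)) == 1)
    stop("all scan ages identical; knot placement is degenerate",
         call. = FALSE)
  k <- median(all_scan_ga)
  if (k <= boundary_knots[1] || k >= boundary_knots[2])
    stop("median scan age falls on or outside the analysis window",
         call. = FALSE)
  spline_spec(internal_knots = k, boundary_knots = boundary_knots,
              degree = degree)
}

# full (repeated-boundary) knot vector
.full_knots <- function(spec) {
  c(rep(spec$boundary_knots[1], spec$degree + 1), spec$internal_knots,
    rep(spec$boundary_knots[2], spec$degree + 1))
}

#' B-spline design matrix
#'
#' Rows hold the `p` B-spline basis values at each time; the basis is a
#' partition of unity (each row sums to 1). The right boundary is included:
#' the basis value at `ga_max` is the left limit, so no in-window scan is
#' unrepresentable.
#'
#' @param times numeric vector of gestational ages (weeks), all within the
#'   boundary knots.
#' @param spec a [spline_spec()].
#' @return numeric matrix, `length(times)` rows by `spec$p` columns.
#' @export
design_matrix <- function(times, spec) {
  .assert(inherits(spec, "spline_spec"), "spec must be a spline_spec")
  if (any(times < spec$boundary_knots[1] | times > spec$boundary_knots[2]))
    stop("times outside the boundary knots [", spec$boundary_knots[1], ", ",
         spec$boundary_knots[2], "]", call. = FALSE)
  splines::splineDesign(knots = .full_knots(spec), x = times,
                        ord = spec$degree + 1)
}

# Greville abscissae: quasi-interpolation sites, one per basis function
.greville <- function(spec) {
  kn <- .full_knots(spec)
  vapply(seq_len(spec$p),
         function(j) mean(kn[(j + 1):(j + spec$degree)]), numeric(1))
}
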