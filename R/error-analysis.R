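#' Three-point bend-curve benchmark configuration
#'
#' Builds the parametric plane curve used for approximation-error analysis
#' on a 2000 x 2000 px grid: `D0 = (1500, 500)`,
#' `D1 = (500, 500 + 1000 delta)`, `D2 = (1500 - 1000 delta, 1500)`,
#' traversed in the order `D1 -> D0 -> D2`. `delta` controls the angle
#' between the two curve legs and hence the maximum curvature at `D0`.
#' At `delta = 1` the formulas collapse `D1` and `D2` onto the same point
#' (a 180-degree hairpin of unbounded curvature), which is rejected.
#'
#' @param delta bend parameter in `[0, 1)`.
#' @return A [ControlPoints-class] with the three points in traversal order.
#' @examples
#' coords(buildBendCurve(0.5))  # (500,1000), (1500,500), (1000,1500)
#' @export
buildBendCurve <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0 || delta >= 1)
    stop("delta must lie in [0, 1): at delta = 1 the configuration is ",
         "degenerate (D1 and D2 coincide)")
  controlPoints(rbind(c(500, 500 + 1000 * delta),
                      c(1500, 500),
                      c(1500 - 1000 * delta, 1500)))
}

#' Evaluation points at a signed orthogonal offset from a curve
#'
#' Samples `count` base points `E0` at uniform parameter spacing, computes
#' unit normals from the analytic tangents, and offsets the base points by
#' the signed distance `i` along the normals. The chord lengths between
#' consecutive base points provide trapezoid quadrature weights for
#' integrating fields along the level set.
#'
#' @param curve a [BSplineCurve-class] (2D).
#' @param offset signed orthogonal distance `i` in px.
#' @param count number of evaluation points (>= 10).
#' @param tRange parameter interval to sample `E0` from (default the full
#'   domain `c(0, 1)`).
#' @return List with `points` (offset points), `base` (`E0`), `normals`,
#'   and `weights` (per-point chord-length quadrature weights of `E0`).
#' @export
levelSetPoints <- function(curve, offset, count = 500L, tRange = c(0, 1)) {
  stopifnot(is(curve, "BSplineCurve"), spatialDim(curve) == 2L)
  if (count < 10L) stop("count must be at least 10")
  t0 <- seq(tRange[1L], tRange[2L], length.out = count)
  E0 <- evalCurve(curve, t0)
  d1 <- evalCurve(curve, t0, 1L)
  sp <- sqrt(rowSums(d1^2))
  bad <- sp < 1e-12
  if (any(bad)) {
    warning(sum(bad), " evaluation point(s) dropped: undefined normal ",
            "(zero tangent)")
    E0 <- E0[!bad, , drop = FALSE]
    d1 <- d1[!bad, , drop = FALSE]
    sp <- sp[!bad]
  }
  tang <- d1 / sp
  normals <- cbind(-tang[, 2L], tang[, 1L])
  seg <- sqrt(rowSums((E0[-1L, , drop = FALSE] - E0[-nrow(E0), , drop = FALSE])^2))
  weights <- c(seg[1L] / 2, (seg[-length(seg)] + seg[-1L]) / 2,
               seg[length(seg)] / 2)
  list(points = E0 + offset * normals, base = E0, normals = normals,
       weights = weights)
}

#' Approximation error of the distance-based heatmap (bend-curve statistic)
#'
#' Accumulates, over a ladder of signed orthogonal offsets `i` spanning
#' `[-3 sigma, 3 sigma]`, the absolute difference between the level-set
#' integral of the numerically integrated convolution (the oracle) and the
#' same integral of the distance-based approximation `h*(f(e))`, weighted
#' by the chord lengths of the on-curve evaluation points:
#' `epsilon = int | int_{S_i} H ds - sum_e l_e h*(f(e)) | di`.
#' The kernel is profile-normalized (`pdf` mode, unit 1D integral) so the
#' accumulated signal per unit curve length is 1 and the normalized error
#' `epsilonHat = epsilon / L` is the fraction of the accumulated signal.
#'
#' @param curve a [BSplineCurve-class] (2D), typically a close fit of
#'   [buildBendCurve()].
#' @param sigma heatmap width in px.
#' @param reduction `"min"`, `"idw1"` or `"idw2"`.
#' @param family kernel family for both the approximation and the oracle
#'   filter (default `"gaussian"`, the convolution model of the benchmark).
#' @param m polyline sample count for the approximation (default 200).
#' @param levels number of offset levels (default 121).
#' @param count evaluation points per level (default 500).
#' @param nodes oracle quadrature nodes (default 2000; the oracle integrand
#'   is smooth at the benchmark widths so the midpoint rule converges fast).
#' @param trimEnds if `TRUE`, restrict the evaluation points to arc
#'   positions at least `3 sigma` away from the curve endpoints. The
#'   default `FALSE` accumulates over the whole curve; trimming isolates
#'   the curvature-induced representation error from the finite-end
#'   truncation (an infinite straight line is exact, a finite one decays
#'   differently at its tips than the distance-based approximation).
#' @return A one-row data.frame: `sigma`, `reduction`, `kappaMax`, `L`,
#'   `epsilon` (absolute error) and `epsilonHat` (fraction of accumulated
#'   signal, `epsilon / L` with `L` the arc length spanned by `E0`).
#' @export
approximationError <- function(curve, sigma, reduction = c("min", "idw1", "idw2"),
                               family = "gaussian", m = 200L, levels = 121L,
                               count = 500L, nodes = 2000L, trimEnds = FALSE) {
  reduction <- match.arg(reduction)
  stopifnot(is(curve, "BSplineCurve"))
  kern <- kernelSpec(family, sigma, mode = "pdf")
  poly <- samplePolyline(curve, m)
  L <- curveLength(curve)
  tRange <- c(0, 1)
  if (trimEnds) {
    if (L <= 6.5 * sigma)
      stop("curve too short to trim 3 sigma from both ends")
    dense <- evalCurve(curve, seq(0, 1, length.out = 20000L))
    cl <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
    tt <- seq(0, 1, length.out = 20000L)
    tRange <- stats::approx(cl, tt, xout = c(3 * sigma, cl[length(cl)] - 3 * sigma),
                            ties = "ordered")$y
    L <- L - 6 * sigma
  }
  base <- levelSetPoints(curve, 0, count, tRange = tRange)
  offs <- seq(-3 * sigma, 3 * sigma, length.out = levels)
  np <- nrow(base$base)
  # stack all level points for one vectorized field/oracle evaluation
  allpts <- do.call(rbind, lapply(offs, function(i) base$base + i * base$normals))
  approx_v <- evaluateHeatmapField(poly, kern, allpts, reduction)
  oracle_v <- convolveLineIntegral(curve, kern, allpts, nodes = nodes)
  lev_err <- vapply(seq_along(offs), function(k) {
    ii <- ((k - 1L) * np + 1L):(k * np)
    abs(sum(base$weights * oracle_v[ii]) - sum(base$weights * approx_v[ii]))
  }, 0)
  di <- offs[2L] - offs[1L]
  eps <- sum((lev_err[-1L] + lev_err[-levels]) / 2) * di   # trapezoid over i
  data.frame(sigma = sigma, reduction = reduction,
             kappaMax = maxCurvature(curve), L = L,
             epsilon = eps, epsilonHat = eps / L)
}

#' Approximation-error sweep over the bend-curve benchmark
#'
#' Runs [approximationError()] over a grid of bend parameters, heatmap
#' widths and reduction functions. The curve for each `delta` is the close
#' (`S = 0`) interpolating fit, so the sweep studies geometry rather than
#' smoothing. `kappaWindow` restricts the expensive error evaluation to
#' configurations whose maximum curvature falls inside the window (the
#' curvature itself is always reported).
#'
#' @param deltas bend parameters in `[0, 1)`.
#' @param sigmas heatmap widths in px.
#' @param reductions subset of `c("min", "idw1", "idw2")`.
#' @param kappaWindow optional `c(lo, hi)`: evaluate errors only where
#'   `kappaMax` lies in the window (rows outside carry `NA` errors).
#' @param ... further arguments passed to [approximationError()].
#' @return A data.frame with one row per configuration: `delta`, `sigma`,
#'   `reduction`, `kappaMax`, `L`, `epsilon`, `epsilonHat`.
#' @export
errorSweep <- function(deltas = seq(0, 0.9, by = 0.1), sigmas = c(34, 51),
                       reductions = "min", kappaWindow = NULL, ...) {
  rows <- list()
  for (d in deltas) {
    crv <- fitCurve(buildBendCurve(d), mode = "close")
    kap <- maxCurvature(crv)
    inside <- is.null(kappaWindow) ||
      (kap >= kappaWindow[1L] && kap <= kappaWindow[2L])
    for (s in sigmas) for (r in reductions) {
      if (inside) {
        rec <- approximationError(crv, s, r, ...)
      } else {
        rec <- data.frame(sigma = s, reduction = r, kappaMax = kap,
                          L = NA_real_, epsilon = NA_real_,
                          epsilonHat = NA_real_)
      }
      rows[[length(rows) + 1L]] <- cbind(delta = d, rec)
    }
  }
  do.call(rbind, rows)
}

#' Minimal sampling rate for a given curvature
#'
#' The printed sampling-rate bound `r > 4 pi kappa` derived from relating
#' the maximum curvature to the highest frequency component
#' `f_max = kappa / (2 pi)` via the sampling theorem. Note the printed
#' bound is a factor `2 pi^2` above `2 f_max`; it is returned as printed.
#'
#' @param kappa maximum curvature in 1/px (>= 0).
#' @return The bound `4 pi kappa`.
#' @seealso [maxFrequency()]
#' @export
nyquistRate <- function(kappa) {
  stopifnot(all(kappa >= 0))
  4 * pi * kappa
}

#' Highest frequency component associated with a curvature
#'
#' @param kappa maximum curvature in 1/px (>= 0).
#' @return `kappa / (2 pi)`.
#' @export
maxFrequency <- function(kappa) {
  stopifnot(all(kappa >= 0))
  kappa / (2 * pi)
}
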