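#' Chord-length parameter values
#'
#' Assigns each data point a parameter value in `[0, 1]` proportional to the
#' cumulative chord length along the point sequence, the standard
#' approximation of arc-length parameterization for curve fitting. The chord
#' polyline length `L_h` underestimates the true curve length `L` and
#' converges to it at second order in the sampling density.
#'
#' @param points a [ControlPoints-class] object or coordinate matrix.
#' @return Numeric vector of strictly increasing parameters with first
#'   element 0 and last element 1.
#' @examples
#' chordLengthParameters(rbind(c(0, 0), c(3, 4), c(3, 9)))  # 0, 0.5, 1
#' @export
chordLengthParameters <- function(points) {
  p <- coords(controlPoints(points))
  chords <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  c(0, cumsum(chords)) / sum(chords)
}

#' Automatic smoothing factor
#'
#' The smoothing budget `S = n - sqrt(2 n)` derived from the number of data
#' points `n`, bounding the residual sum of squares of the smoothing fit.
#' `close = TRUE` returns 0, requesting an interpolating fit.
#'
#' @param count number of data points (>= 2).
#' @param close logical; if `TRUE` return 0 (close interpolation).
#' @return Non-negative scalar `S`.
#' @examples
#' smoothingFactor(8)   # 4
#' smoothingFactor(2)   # 0
#' @export
smoothingFactor <- function(count, close = FALSE) {
  if (!is.numeric(count) || length(count) != 1L || count < 2)
    stop("count must be a single number >= 2")
  if (close) return(0)
  count - sqrt(2 * count)
}

spline_degree <- function(n) {
  # n data points: index K = n - 1; cubic for K > 2, quadratic K = 2, linear K = 1
  if (n >= 4L) 3L else n - 1L
}

interp_knots <- function(t, d) {
  n <- length(t)
  interior <- if (n - 1L - d >= 1L)
    vapply(seq_len(n - 1L - d), function(j) mean(t[(j + 1L):(j + d)]), 0)
  else numeric(0)
  c(rep(t[1L], d + 1L), interior, rep(t[n], d + 1L))
}

#' Fit a parametric B-spline to ordered data points
#'
#' Fits one B-spline per coordinate over the chord-length parameters.
#' In `close` mode the spline interpolates the data points exactly. In
#' `smooth` mode a second-difference roughness penalty on the control points
#' is applied, with the penalty weight chosen (by bisection) as large as
#' possible while keeping the residual sum of squares within the automatic
#' budget `S = n - sqrt(2 n)`, so the fit is as smooth as the budget allows.
#'
#' @param points a [ControlPoints-class] object or coordinate matrix.
#' @param mode `"smooth"` (residual budget `S`) or `"close"` (interpolation).
#' @return A [BSplineCurve-class].
#' @examples
#' crv <- fitCurve(rbind(c(0, 0), c(1, 2), c(3, 3), c(5, 1)), mode = "close")
#' evalCurve(crv, c(0, 0.5, 1))
#' @export
fitCurve <- function(points, mode = c("smooth", "close")) {
  mode <- match.arg(mode)
  pts <- controlPoints(points)
  p <- coords(pts)
  n <- nrow(p)
  t <- chordLengthParameters(pts)
  d <- spline_degree(n)
  knots <- interp_knots(t, d)
  A <- splines::splineDesign(knots, t, ord = d + 1L)
  S <- if (mode == "close") 0 else smoothingFactor(n)
  if (S <= 0 || nrow(A) < 3L) {
    cf <- tryCatch(solve(A, p), error = function(e)
      stop("B-spline interpolation system is singular: ", conditionMessage(e)))
    cf <- matrix(cf, ncol = ncol(p))
    rss <- sum((A %*% cf - p)^2)
    return(new("BSplineCurve", degree = d, knots = knots, coefs = cf,
               params = t, smoothing = S, residual = rss))
  }
  # penalized fit: largest penalty weight with RSS <= S
  nc <- ncol(A)
  AtA <- crossprod(A)
  Atp <- crossprod(A, p)
  P <- if (nc >= 3L) crossprod(diff(diag(nc), differences = 2L)) else diag(0, nc)
  fit_for <- function(lam) {
    cf <- solve(AtA + lam * P, Atp)
    list(coefs = cf, rss = sum((A %*% cf - p)^2))
  }
  lo <- 0; hi <- 1e-6
  while (fit_for(hi)$rss <= S && hi < 1e12) { lo <- hi; hi <- hi * 10 }
  if (fit_for(hi)$rss <= S) {
    lam <- hi
  } else {
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (fit_for(mid)$rss <= S) lo <- mid else hi <- mid
    }
    lam <- lo
  }
  f <- fit_for(lam)
  new("BSplineCurve", degree = d, knots = knots,
      coefs = matrix(f$coefs, ncol = ncol(p)), params = t,
      smoothing = S, residual = f$rss)
}

#' Evaluate a fitted curve (or its derivatives)
#'
#' @param curve a [BSplineCurve-class].
#' @param t parameter values in `[0, 1]`.
#' @param deriv derivative order (0, 1 or 2; must be below the degree + 1).
#' @return Matrix of coordinates (or derivative vectors), one row per `t`.
#' @export
evalCurve <- function(curve, t, deriv = 0L) {
  stopifnot(is(curve, "BSplineCurve"))
  hi <- curve@knots[length(curve@knots)]
  t <- pmin(pmax(t, curve@knots[1L]), hi)
  # derivative bases are left-discontinuous at the right boundary for low
  # degrees; evaluate the one-sided limit just inside the domain
  if (deriv > 0L) t <- pmin(t, hi - 1e-9)
  if (deriv > curve@degree)
    return(matrix(0, length(t), ncol(curve@coefs)))
  B <- splines::splineDesign(curve@knots, t, ord = curve@degree + 1L,
                             derivs = rep(as.integer(deriv), length(t)))
  B %*% curve@coefs
}

#' Sample a curve into a polyline at uniform arc length
#'
#' Pre-samples the spline densely (20 m parameter values), accumulates chord
#' length and inverts the arc-length map by linear interpolation, yielding
#' `m` samples whose spacing is uniform in arc length. The first and last
#' samples are the exact curve endpoints.
#'
#' @param curve a [BSplineCurve-class].
#' @param m number of samples (>= 2); the polyline has `m - 1` segments.
#' @param oversample dense pre-sampling factor (default 20).
#' @return A [Polyline-class].
#' @export
samplePolyline <- function(curve, m = 200L, oversample = 20L) {
  stopifnot(is(curve, "BSplineCurve"))
  if (!is.numeric(m) || length(m) != 1L || m < 2)
    stop("m must be a single integer >= 2")
  m <- as.integer(m)
  tt <- seq(0, 1, length.out = max(oversample * m, 200L))
  xy <- evalCurve(curve, tt)
  seg <- sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2))
  cl <- c(0, cumsum(seg))
  targets <- seq(0, cl[length(cl)], length.out = m)
  ts <- stats::approx(cl, tt, xout = targets, ties = "ordered")$y
  out <- evalCurve(curve, ts)
  out[1L, ] <- xy[1L, ]
  out[m, ] <- xy[nrow(xy), ]
  polyline(out)
}

#' Maximum absolute curvature of a fitted curve
#'
#' Evaluates the analytic spline derivatives on a dense parameter grid and
#' returns the maximum of `|x'y'' - y'x''| / (x'^2 + y'^2)^(3/2)` (2D) or
#' `|C' x C''| / |C'|^3` (3D). Linear curves return 0.
#'
#' @param curve a [BSplineCurve-class].
#' @param n number of grid points (default 2000).
#' @return Maximum curvature in 1/px.
#' @export
maxCurvature <- function(curve, n = 2000L) {
  stopifnot(is(curve, "BSplineCurve"))
  if (curve@degree < 2L) return(0)
  tt <- seq(0, 1, length.out = n)
  d1 <- evalCurve(curve, tt, 1L)
  d2 <- evalCurve(curve, tt, 2L)
  sp2 <- rowSums(d1^2)
  if (ncol(d1) == 2L) {
    num <- abs(d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L])
  } else {
    cx <- d1[, 2L] * d2[, 3L] - d1[, 3L] * d2[, 2L]
    cy <- d1[, 3L] * d2[, 1L] - d1[, 1L] * d2[, 3L]
    cz <- d1[, 1L] * d2[, 2L] - d1[, 2L] * d2[, 1L]
    num <- sqrt(cx^2 + cy^2 + cz^2)
  }
  kap <- num / pmax(sp2^1.5, .Machine$double.eps)
  max(kap[is.finite(kap)])
}

#' Arc length of a fitted curve
#'
#' Chord-length approximation on a dense parameter grid (second-order
#' accurate in the grid spacing).
#'
#' @param curve a [BSplineCurve-class].
#' @param n dense grid size (default 20000).
#' @return Curve length in px.
#' @export
curveLength <- function(curve, n = 20000L) {
  xy <- evalCurve(curve, seq(0, 1, length.out = n))
  sum(sqrt(rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)))
}
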