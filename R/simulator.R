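#' Simulation configuration for random-walk curve signals
#'
#' Parameters of the heuristic generation model for elongated-structure
#' signals on a square envelope: the number of data points is drawn from
#' the integer uniform `U[3, 10)`, the seed point uniformly from the inner
#' region `[10, 246)^2` (for the default 256 px envelope), and subsequent
#' points follow `D[i+1] = D[i] + (s cos(phi), s sin(phi))` with step
#' length `s ~ U[20, 60)` px and angle `phi ~ U[-90, 90)` degrees. A walk
#' leaving the region discards the whole point set and restarts.
#'
#' @param shape envelope dimensions `c(H, W)` (default `c(256, 256)`).
#' @param region inner region bounds `c(lo, hi)` (half-open; default
#'   `c(10, 246)`).
#' @param countRange point-count bounds `c(lo, hi)` (half-open integer
#'   uniform; default `c(3, 10)`).
#' @param stepRange step-length bounds in px (half-open; default `c(20, 60)`).
#' @param angleRange step-angle bounds in degrees (half-open; default
#'   `c(-90, 90)`).
#' @param a overlay strength factor (default 0.15).
#' @param sigmaZ multiplicative Gaussian noise standard deviation
#'   (default 0.1).
#' @param maxRetries restart budget for rejected walks (default 1000).
#' @return A plain list of class `"simulationConfig"`.
#' @export
simulationConfig <- function(shape = c(256L, 256L), region = c(10, 246),
                             countRange = c(3L, 10L), stepRange = c(20, 60),
                             angleRange = c(-90, 90), a = 0.15, sigmaZ = 0.1,
                             maxRetries = 1000L) {
  stopifnot(length(shape) == 2L, region[1L] < region[2L],
            countRange[1L] >= 2L, stepRange[1L] > 0, a >= 0, sigmaZ >= 0)
  structure(list(shape = shape, region = region, countRange = countRange,
                 stepRange = stepRange, angleRange = angleRange, a = a,
                 sigmaZ = sigmaZ, maxRetries = maxRetries),
            class = "simulationConfig")
}

#' Draw random-walk curve control points
#'
#' Samples one point set from the generation model of
#' [simulationConfig()]. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param cfg a [simulationConfig()] list.
#' @return A [ControlPoints-class] whose points all lie inside the region.
#' @export
sampleCurvePoints <- function(cfg = simulationConfig()) {
  lo <- cfg$region[1L]; hi <- cfg$region[2L]
  for (try in seq_len(cfg$maxRetries)) {
    n <- floor(stats::runif(1, cfg$countRange[1L], cfg$countRange[2L]))
    p <- matrix(NA_real_, n, 2L)
    p[1L, ] <- stats::runif(2, lo, hi)
    ok <- TRUE
    for (i in seq_len(n - 1L)) {
      s <- stats::runif(1, cfg$stepRange[1L], cfg$stepRange[2L])
      phi <- stats::runif(1, cfg$angleRange[1L], cfg$angleRange[2L]) * pi / 180
      p[i + 1L, ] <- p[i, ] + s * c(cos(phi), sin(phi))
      if (any(p[i + 1L, ] < lo) || any(p[i + 1L, ] >= hi)) { ok <- FALSE; break }
    }
    if (ok) return(controlPoints(p))
  }
  stop("curve generation failed: retry budget (", cfg$maxRetries,
       ") exhausted")
}

#' Smooth synthetic background image
#'
#' A seeded low-frequency random field in `[0, 1]`: a sum of a few random
#' plane cosine waves, rescaled to the unit interval. A stand-in for real
#' radiograph backgrounds so the pipeline runs without external data; it
#' reproduces only the smooth large-scale intensity variation of such
#' images, not their anatomy or noise statistics.
#'
#' @param shape image dimensions `c(H, W)`.
#' @param waves number of cosine components (default 6).
#' @param flat if `TRUE` return a constant-zero image (clean-signal tests).
#' @return Matrix of dimension `shape` with values in `[0, 1]`.
#' @export
syntheticBackground <- function(shape = c(256L, 256L), waves = 6L,
                                flat = FALSE) {
  if (flat) return(matrix(0, shape[1L], shape[2L]))
  ys <- seq_len(shape[1L]) - 1
  xs <- seq_len(shape[2L]) - 1
  img <- matrix(0, shape[1L], shape[2L])
  for (k in seq_len(waves)) {
    fr <- stats::runif(2, 0.5, 3) / max(shape)
    ph <- stats::runif(1, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    img <- img + amp * cos(2 * pi * (outer(ys * fr[1L], xs * fr[2L], "+")) + ph)
  }
  rng <- range(img)
  if (diff(rng) < 1e-12) return(matrix(0.5, shape[1L], shape[2L]))
  (img - rng[1L]) / diff(rng)
}

#' Compose a signal heatmap onto a background image
#'
#' Applies the overlay model `X_sim = X_img + a * H * (1 + Z)` elementwise,
#' with `Z ~ N(0, sigmaZ^2)` i.i.d. per pixel. The output is not clipped
#' and may exceed 1.
#'
#' @param background background image matrix.
#' @param heatmap signal heatmap ([Heatmap-class] or matrix) of the same
#'   dimension.
#' @param a overlay strength factor (>= 0).
#' @param sigmaZ noise standard deviation (>= 0).
#' @return The composite image matrix.
#' @export
composeImage <- function(background, heatmap, a = 0.15, sigmaZ = 0.1) {
  H <- if (is(heatmap, "Heatmap")) heatmapValues(heatmap) else as.matrix(heatmap)
  if (!identical(dim(background), dim(H)))
    stop("background and heatmap shapes differ: ",
         paste(dim(background), collapse = "x"), " vs ",
         paste(dim(H), collapse = "x"))
  if (a < 0) stop("overlay strength a must be non-negative")
  Z <- if (sigmaZ > 0) matrix(stats::rnorm(length(H), 0, sigmaZ), nrow(H)) else 0
  background + a * H * (1 + Z)
}

#' Generate one complete simulated sample
#'
#' Draws random-walk control points, fits and samples the curve, renders
#' the target heatmap, builds a background and composes the overlay image.
#'
#' @param cfg a [simulationConfig()] list.
#' @param kernel a [KernelSpec-class] (default peak Gaussian, sigma 3).
#' @param reduction reduction rule for rendering (default `"min"`).
#' @param m polyline sample count (default 200).
#' @param mode curve fitting mode (default `"smooth"`).
#' @param flatBackground if `TRUE` use a zero background.
#' @return A [SimulatedSample-class].
#' @export
simulateSample <- function(cfg = simulationConfig(),
                           kernel = kernelSpec("gaussian", 3),
                           reduction = "min", m = 200L, mode = "smooth",
                           flatBackground = FALSE) {
  pts <- sampleCurvePoints(cfg)
  crv <- fitCurve(pts, mode = mode)
  poly <- samplePolyline(crv, m)
  hm <- renderHeatmap(poly, kernel, reduction, shape = cfg$shape)
  bg <- syntheticBackground(cfg$shape, flat = flatBackground)
  comp <- composeImage(bg, hm, a = cfg$a, sigmaZ = cfg$sigmaZ)
  new("SimulatedSample", points = pts, heatmap = hm, background = bg,
      composite = comp)
}
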