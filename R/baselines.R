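#' Rasterize a polyline onto a binary grid
#'
#' Marks every cell whose center lies within `spacing` px of the polyline
#' (supercover-style discretization; the default 0.5 yields a connected
#' one-cell-wide trace).
#'
#' @param poly a [Polyline-class] (or coordinate matrix), 2D.
#' @param shape grid dimensions `c(H, W)`.
#' @param spacing marking radius in px (default 0.5).
#' @return Binary matrix of dimension `shape` (1 = curve cell).
#' @export
rasterizeCurve <- function(poly, shape, spacing = 0.5) {
  poly <- polyline(poly)
  stopifnot(spatialDim(poly) == 2L)
  p <- coords(poly)
  md <- array(Inf, dim = shape)
  hulls <- buildHulls(poly, w = 2 * spacing + 2, shape = shape)
  for (i in seq_len(nrow(hulls))) {
    bx <- hulls[i, ]
    cells <- box_cells_2d(bx)
    idx <- cbind(cells[, 2L] + 1L, cells[, 1L] + 1L)
    d <- pointSegmentDistance(cells, p[bx$segment, ], p[bx$segment + 1L, ])
    md[idx] <- pmin(md[idx], d)
  }
  out <- array(0, dim = shape)
  out[md <= spacing] <- 1
  out
}

gaussian_2d_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  off <- -r:r
  g2 <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  g2[sqrt(outer(off^2, off^2, "+")) > 3 * sigma] <- 0
  g2
}

# zero-padded 2D convolution (EBImage filter2 is circular, so pad first)
conv2_padded <- function(x, k) {
  r <- (dim(k) - 1L) %/% 2L
  xp <- matrix(0, nrow(x) + 2L * r[1L], ncol(x) + 2L * r[2L])
  xp[(r[1L] + 1L):(r[1L] + nrow(x)), (r[2L] + 1L):(r[2L] + ncol(x))] <- x
  yp <- EBImage::imageData(EBImage::filter2(EBImage::Image(xp), k))
  yp[(r[1L] + 1L):(r[1L] + nrow(x)), (r[2L] + 1L):(r[2L] + ncol(x))]
}

check_raster <- function(raster) {
  raster <- as.matrix(raster)
  if (!any(raster > 0)) stop("curve raster is empty (no on-curve cell)")
  (raster > 0) + 0
}

#' Gaussian-blur (MSE) curve representation
#'
#' Baseline representation: discrete 2D convolution of the rasterized curve
#' cells with a sampled radial Gaussian (support `3 sigma`), then
#' peak-normalized. Corresponds to treating each discrete curve point as an
#' independent squared-error source; superposition broadens the profile in
#' dense and curved regions.
#'
#' @param raster binary curve raster (matrix, 1 = curve cell).
#' @param sigma Gaussian width in px.
#' @return Matrix of the same dimension, maximum 1.
#' @export
mseBlurRepresentation <- function(raster, sigma) {
  raster <- check_raster(raster)
  out <- conv2_padded(raster, gaussian_2d_kernel(sigma))
  out <- pmax(out, 0)
  out / max(out)
}

#' Gaussian-weighted Euclidean distance transform representation
#'
#' Baseline representation: the exact Euclidean distance of every cell to
#' the nearest rasterized curve cell, evaluated through the peak-normalized
#' Gaussian profile. On-curve cells map to 1.
#'
#' @param raster binary curve raster (matrix, 1 = curve cell).
#' @param sigma Gaussian width in px.
#' @param pxsize physical size of one raster cell in px (use `1/k` for a
#'   raster built on a `k`-fold supersampled grid to obtain sub-cell
#'   discretization).
#' @return Matrix of the same dimension, values in `[0, 1]`.
#' @export
edtGaussianRepresentation <- function(raster, sigma, pxsize = 1) {
  raster <- check_raster(raster)
  dist <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - raster))) * pxsize
  g <- kernelSpec("gaussian", sigma, mode = "peak")
  out <- array(evaluateKernel(g, as.vector(dist)), dim = dim(raster))
  out
}

#' Gaussian-weighted binary cross-entropy response
#'
#' Baseline representation: discrete 2D convolution of the curve raster
#' with the impulse response of a Gaussian-weighted BCE term. The impulse
#' response at offset `r` is the Gaussian pdf at `||r||` multiplied by the
#' clamped BCE log term `min(||r||^2 / (2 sigma^2), -log(eps))` (the
#' negative log of the peak-normalized Gaussian response, clamped at
#' `eps`). The output is not normalized; it is compared against the 1D
#' impulse profile in representation-error analyses.
#'
#' @param raster binary curve raster (matrix, 1 = curve cell).
#' @param sigma Gaussian width in px.
#' @param eps clamping constant for the log term (default 1e-12).
#' @return Matrix of the same dimension.
#' @export
bceWeightedRepresentation <- function(raster, sigma, eps = 1e-12) {
  raster <- check_raster(raster)
  r <- ceiling(3 * sigma)
  off <- -r:r
  rad2 <- outer(off^2, off^2, "+")
  k <- exp(-rad2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
    pmin(rad2 / (2 * sigma^2), -log(eps))
  k[sqrt(rad2) > 3 * sigma] <- 0
  conv2_padded(raster, k)
}
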