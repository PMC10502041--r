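# points on a circular arc of given radius (0..angle radians)
arc_points <- function(n, radius = 1, angle = pi / 2, center = c(0, 0)) {
  th <- seq(0, angle, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

# a long horizontal 2-point polyline at an off-grid height
offgrid_line <- function(y = 10.3, x0 = -60, x1 = 160) {
  rbind(c(x0, y), c(x1, y))
}

all_kernel_families <- c("gaussian", "laplace", "triangular", "rectangular",
                         "cosine", "catheter")

# brute-force minimum distance from points to a densely sampled curve
dense_curve_distance <- function(curve, pts, n = 20000L) {
  samp <- evalCurve(curve, seq(0, 1, length.out = n))
  apply(as.matrix(pts), 1L, function(p)
    sqrt(min(colSums((t(samp) - p)^2))))
}

# rasterized 0-based points of a polyline on a grid
raster_points <- function(poly, shape) {
  r <- rasterizeCurve(poly, shape)
  ai <- which(r == 1, arr.ind = TRUE)
  cbind(ai[, 2L] - 1L, ai[, 1L] - 1L)
}
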