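test_that("chord-length parameters follow cumulative chord ratios", {
  expect_equal(chordLengthParameters(rbind(c(0, 0), c(3, 4), c(3, 9))),
               c(0, 0.5, 1))
  expect_equal(chordLengthParameters(rbind(c(0, 0), c(1, 0))), c(0, 1))
  expect_equal(chordLengthParameters(rbind(c(0, 0), c(1, 0), c(4, 0))),
               c(0, 0.25, 1))
  # strictly increasing for a generic 3D walk
  set.seed(7)
  p <- apply(matrix(rnorm(30), 10, 3), 2, cumsum)
  t <- chordLengthParameters(p)
  expect_true(all(diff(t) > 0))
  expect_equal(t[c(1, 10)], c(0, 1))
})

test_that("coincident consecutive points are rejected", {
  expect_error(controlPoints(rbind(c(0, 0), c(0, 0), c(1, 1))), "coincide")
  expect_error(chordLengthParameters(rbind(c(1, 2), c(1, 2))), "coincide")
})

test_that("parameterization is invariant under rigid motion", {
  set.seed(11)
  p <- apply(matrix(rnorm(16), 8, 2), 2, cumsum)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p2 <- sweep(p %*% Rm, 2, c(12.3, -4.5), "+")
  expect_equal(chordLengthParameters(p), chordLengthParameters(p2))
})

test_that("smoothing factor follows S = n - sqrt(2 n) with a close override", {
  expect_equal(smoothingFactor(8), 4)
  expect_equal(smoothingFactor(2), 0)
  expect_equal(smoothingFactor(50), 40)
  expect_equal(smoothingFactor(50, close = TRUE), 0)
  expect_error(smoothingFactor(1), ">= 2")
})

test_that("degree rule and interpolation condition hold in close mode", {
  # 2 points -> linear segment through both
  crv2 <- fitCurve(rbind(c(0, 0), c(4, 2)), mode = "close")
  expect_equal(crv2@degree, 1L)
  expect_equal(evalCurve(crv2, 0.5), matrix(c(2, 1), 1), tolerance = 1e-12)
  # 3 points -> quadratic
  expect_equal(fitCurve(rbind(c(0, 0), c(1, 2), c(3, 0)), mode = "close")@degree, 2L)
  # 4 non-collinear points, close mode: residuals below 1e-6 px
  pts <- rbind(c(0, 0), c(1, 2), c(3, 3), c(5, 1))
  crv <- fitCurve(pts, mode = "close")
  expect_equal(crv@degree, 3L)
  fitted <- evalCurve(crv, chordLengthParameters(pts))
  expect_lt(max(abs(fitted - pts)), 1e-6)
})

test_that("collinear points yield the straight line in both modes", {
  pts <- rbind(c(0, 0), c(1, 0.5), c(4, 2))
  for (mode in c("close", "smooth")) {
    crv <- fitCurve(pts, mode = mode)
    xy <- evalCurve(crv, seq(0, 1, length.out = 50))
    # line y = x/2
    expect_lt(max(abs(xy[, 2] - xy[, 1] / 2)), 1e-6)
  }
})

test_that("smooth mode keeps the residual sum within the budget S", {
  set.seed(3)
  pts <- cbind(seq(0, 10, length.out = 12),
               3 * sin(seq(0, 3, length.out = 12)) + rnorm(12, 0, 0.3))
  crv <- fitCurve(pts, mode = "smooth")
  expect_equal(crv@smoothing, smoothingFactor(12))
  expect_lte(crv@residual, crv@smoothing + 1e-9)
  # and actually smooths: residual exceeds the close fit's
  expect_gt(crv@residual, fitCurve(pts, mode = "close")@residual)
})

test_that("polyline sampling is uniform in arc length with exact endpoints", {
  crv <- fitCurve(arc_points(30, radius = 10), mode = "close")
  # straight segment of length 10, m = 11 -> unit spacing
  seg <- fitCurve(rbind(c(0, 0), c(10, 0)), mode = "close")
  pl <- samplePolyline(seg, 11)
  expect_equal(diff(pl@cumlen), rep(1, 10), tolerance = 1e-9)
  # m = 2 -> endpoints only
  pl2 <- samplePolyline(seg, 2)
  expect_equal(coords(pl2), rbind(c(0, 0), c(10, 0)))
  # curved case: spacing uniform within 1 percent relative deviation
  pl3 <- samplePolyline(crv, 50)
  sp <- diff(pl3@cumlen)
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.01)
  expect_equal(coords(pl3)[1, ], evalCurve(crv, 0)[1, ], tolerance = 1e-9)
  expect_error(samplePolyline(seg, 1), ">= 2")
})

test_that("polyline length underestimates the arc length at second order", {
  crv <- fitCurve(arc_points(40), mode = "close")  # unit quarter circle
  L <- pi / 2
  errs <- vapply(c(64L, 128L, 256L), function(m)
    L - totalLength(samplePolyline(crv, m)), 0)
  expect_true(all(errs > 0))                       # L_h <= L
  orders <- log2(errs[-3] / errs[-1])
  expect_true(all(abs(orders - 2) < 0.1))
})

test_that("maximum curvature matches analytic values and grid refinement", {
  seg <- fitCurve(rbind(c(0, 0), c(10, 3)), mode = "close")
  expect_equal(maxCurvature(seg), 0)
  for (R in c(2, 7)) {
    crv <- fitCurve(arc_points(60, radius = R), mode = "close")
    expect_equal(maxCurvature(crv), 1 / R, tolerance = 0.01)
  }
  bend <- fitCurve(buildBendCurve(0.8), mode = "close")
  expect_equal(maxCurvature(bend, 2000L), maxCurvature(bend, 20000L),
               tolerance = 0.01)
})

test_that("3D curves fit, sample and report curvature", {
  th <- seq(0, 2, length.out = 25)
  helix <- cbind(5 * cos(th), 5 * sin(th), 2 * th)
  crv <- fitCurve(helix, mode = "close")
  expect_equal(spatialDim(crv), 3L)
  fitted <- evalCurve(crv, chordLengthParameters(helix))
  expect_lt(max(abs(fitted - helix)), 1e-6)
  # helix curvature r / (r^2 + c^2) with r = 5, c = 2
  expect_equal(maxCurvature(crv), 5 / 29, tolerance = 0.01)
  pl <- samplePolyline(crv, 100)
  sp <- diff(pl@cumlen)
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.01)
})
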