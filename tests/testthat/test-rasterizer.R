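test_that("point-to-segment distance handles projection and clamping", {
  l1 <- c(0, 0); l2 <- c(2, 0)
  expect_equal(pointSegmentDistance(c(1, 1), l1, l2), 1)
  expect_equal(pointSegmentDistance(c(3, 0), l1, l2), 1)        # clamp to l2
  expect_equal(pointSegmentDistance(c(-1, 1), l1, l2), sqrt(2)) # clamp to l1
  # vectorized and 3D
  expect_equal(pointSegmentDistance(rbind(c(1, 1), c(3, 0)), l1, l2), c(1, 1))
  expect_equal(pointSegmentDistance(c(1, 0, 2), c(0, 0, 0), c(2, 0, 0)), 2)
  expect_error(pointSegmentDistance(c(1, 1), c(1, 2), c(1, 2)), "degenerate")
})

test_that("hull boxes dilate segments by w/2 with end caps, clipped to grid", {
  h <- buildHulls(rbind(c(10, 10), c(20, 10)), w = 6, shape = c(40, 40))
  segbox <- h[!h$cap, ]
  expect_equal(unlist(segbox[c("x0", "x1", "y0", "y1")], use.names = FALSE),
               c(7, 23, 7, 13))
  expect_equal(sum(h$cap), 2L)
  caps <- h[h$cap, ]
  expect_equal(caps$x1 - caps$x0, c(6, 6))   # side w
  # union of boxes covers exactly rows 7..13, cols 7..23
  expect_true(all(caps$y0 == 7 & caps$y1 == 13))
  # segment fully outside the grid -> nothing
  expect_equal(nrow(buildHulls(rbind(c(100, 100), c(120, 100)), 6, c(40, 40))), 0L)
  # diagonal segment: AABB of the endpoints dilated by w/2
  hd <- buildHulls(rbind(c(5, 5), c(15, 25)), w = 4, shape = c(40, 40))
  sb <- hd[!hd$cap, ]
  expect_equal(unlist(sb[c("x0", "x1", "y0", "y1")], use.names = FALSE),
               c(3, 17, 3, 27))
  expect_error(buildHulls(rbind(c(0, 0), c(1, 1)), w = 0, shape = c(10, 10)),
               "positive")
})

test_that("reduction rules reproduce hand-evaluated values", {
  g1 <- kernelSpec("gaussian", 1)
  expect_equal(reduceMin(c(3, 1, 2), g1), exp(-0.5))
  expect_equal(reduceMin(0, kernelSpec("catheter", 1, s = 0.5)),
               evaluateKernel(kernelSpec("catheter", 1, s = 0.5), 0))
  expect_equal(reduceMin(c(5, 7), g1), 0)   # beyond support
  expect_equal(reduceIdw(c(2, 2), g1, p = 1), evaluateKernel(g1, 2))
  expect_equal(reduceIdw(c(1, 2), g1, p = 2),
               (exp(-0.5) + 0.25 * exp(-2)) / 1.25)
  expect_equal(reduceIdw(c(0, 4), g1, p = 1), 1)  # zero-distance convention
  expect_error(reduceMin(numeric(0), g1), "estimates")
  expect_error(reduceIdw(numeric(0), g1), "estimates")
})

test_that("straight-line heatmap rows carry the exact kernel profile", {
  kern <- kernelSpec("gaussian", 3)
  hm <- renderHeatmap(offgrid_line(y = 10), kern, "min", shape = c(21, 100))
  v <- heatmapValues(hm)
  d <- abs(0:20 - 10)
  for (col in c(1, 50, 100))
    expect_equal(v[, col], evaluateKernel(kern, d), tolerance = 1e-6)
  # peak-mode values stay within [0, 1]
  expect_true(all(v >= 0 & v <= 1))
  # min and idw agree wherever a single box covers a cell (single estimate)
  vidw <- heatmapValues(renderHeatmap(offgrid_line(y = 10), kern, "idw2",
                                      shape = c(21, 100)))
  mid <- 30:70   # central columns: one segment, one box
  expect_lt(max(abs(v[, mid] - vidw[, mid])), 1e-9)
})

test_that("IDW never exceeds the min reduction for monotone kernels", {
  crv <- fitCurve(coords(buildBendCurve(0.85)) / 5, mode = "close")
  poly <- samplePolyline(crv, 80)
  kern <- kernelSpec("gaussian", 7)
  vmin <- heatmapValues(renderHeatmap(poly, kern, "min", c(400, 400)))
  for (red in c("idw1", "idw2")) {
    vi <- heatmapValues(renderHeatmap(poly, kern, red, c(400, 400)))
    expect_true(all(vi <= vmin + 1e-9), info = red)
  }
})

test_that("heatmap is translation-equivariant for integer shifts", {
  poly <- rbind(c(12.4, 15.7), c(30.2, 28.9), c(44.8, 20.1))
  kern <- kernelSpec("cosine", 2.5)
  v1 <- heatmapValues(renderHeatmap(poly, kern, "min", c(64, 64)))
  v2 <- heatmapValues(renderHeatmap(sweep(poly, 2, c(5, 7), "+"), kern,
                                    "min", c(64, 64)))
  # compare interior region away from the grid boundary
  expect_equal(v2[23:60, 21:60], v1[16:53, 16:55], tolerance = 1e-12)
})

test_that("covered-cell count scales with the support width", {
  poly <- rbind(c(20, 50), c(120, 50))
  n1 <- sum(heatmapValues(renderHeatmap(poly, kernelSpec("rectangular", 2),
                                        "min", c(101, 141))) > 0)
  n2 <- sum(heatmapValues(renderHeatmap(poly, kernelSpec("rectangular", 4),
                                        "min", c(101, 141))) > 0)
  expect_gt(n2 / n1, 1.8)
  expect_lt(n2 / n1, 2.4)
})

test_that("3D rendering matches the radial profile around a straight axis", {
  kern <- kernelSpec("gaussian", 2)
  poly <- rbind(c(-10, 8, 8), c(40, 8, 8))
  hm <- renderHeatmap(poly, kern, "min", shape = c(17, 30, 17))
  v <- heatmapValues(hm)
  expect_equal(dim(v), c(17L, 30L, 17L))
  # radial Gaussian in the (y, z) plane at a mid column
  for (yz in list(c(8, 8), c(10, 8), c(8, 12), c(11, 11))) {
    d <- sqrt(sum((yz - c(8, 8))^2))
    expect_equal(v[yz[1] + 1, 15, yz[2] + 1], evaluateKernel(kern, d),
                 tolerance = 1e-9)
  }
  expect_error(renderHeatmap(poly, kern, "min", shape = c(17, 30)),
               "dimensions")
})

test_that("field evaluation agrees with the rendered grid", {
  poly <- rbind(c(5.2, 9.1), c(35.4, 22.3), c(55.1, 12.2))
  kern <- kernelSpec("laplace", 2)
  for (red in c("min", "idw1")) {
    v <- heatmapValues(renderHeatmap(poly, kern, red, c(32, 64)))
    cells <- as.matrix(expand.grid(x = 0:63, y = 0:31))
    fv <- evaluateHeatmapField(poly, kern, cells, red)
    expect_equal(v[cbind(cells[, 2] + 1, cells[, 1] + 1)], fv,
                 tolerance = 1e-12, info = red)
  }
  # distanceEstimates feeds the standalone reductions consistently
  pts <- rbind(c(20, 15), c(3, 3), c(60, 30))
  est <- distanceEstimates(poly, pts, w = 2 * kernelSupport(kern))
  fv <- evaluateHeatmapField(poly, kern, pts, "min")
  for (i in seq_along(est)) {
    if (length(est[[i]]) > 0)
      expect_equal(reduceMin(est[[i]], kern), fv[i])
    else expect_equal(fv[i], 0)
  }
})
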