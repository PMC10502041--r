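test_that("assd matches hand values and is a symmetric pre-metric", {
  A <- cbind(0:9, rep(0, 10))
  expect_equal(assd(A, A), 0)
  B <- cbind(0:9, rep(3, 10))
  expect_equal(assd(A, B), 3)              # parallel lines 3 px apart
  expect_equal(assd(B, A), assd(A, B))
  # 3D voxel sets use the same formula
  A3 <- cbind(A, 0); B3 <- cbind(A, 4)
  expect_equal(assd(A3, B3), 4)
  expect_error(assd(A[0, ], B), "non-empty")
  # asymmetric sets: average of both directed sums
  C <- rbind(c(0, 0))
  D <- rbind(c(0, 1), c(0, 3))
  expect_equal(assd(C, D), (1 + 1 + 3) / 3)
})

test_that("Zhang-Suen thinning reduces bands to unit width and keeps 1-px input", {
  b <- matrix(0L, 20, 40)
  b[8:12, 5:35] <- 1L                      # 5-px-thick horizontal band
  sk <- thinBinary(b)
  expect_true(all(rowSums(sk)[c(1:7, 13:20)] == 0))
  byrow <- colSums(sk[, 10:30])
  expect_true(all(byrow == 1))             # unit width in the interior
  thin <- matrix(0L, 10, 10); thin[5, 2:9] <- 1L
  expect_equal(thinBinary(thin), thin)     # fixed point
})

test_that("centerline extraction recovers a rendered straight line", {
  poly <- rbind(c(-5, 10), c(45, 10))
  hm <- renderHeatmap(poly, kernelSpec("gaussian", 2), "min", c(21, 40))
  pts <- extractCenterline(hm)
  expect_true(all(abs(pts[, 2] - 10) <= 1))
  expect_gt(nrow(pts), 30)
  expect_error(extractCenterline(matrix(0.5, 10, 10)), "constant")
  # an isolated peak collapses to a point-like cluster
  spot <- matrix(0, 21, 21); spot[11, 11] <- 1
  spot <- mseBlurRepresentation(spot, 1.5)
  expect_lte(nrow(extractCenterline(spot)), 4)
})

test_that("3D thinning reduces a tube to a near-axial skeleton", {
  vol <- array(0L, c(15, 30, 15))
  vol[6:10, 4:27, 6:10] <- 1L              # square tube along x
  sk <- thinBinary3d(vol)
  pts <- which(sk == 1L, arr.ind = TRUE)
  expect_gt(nrow(pts), 10)
  expect_lt(nrow(pts), 60)                 # unit-width chain, not a slab
  expect_true(all(abs(pts[, 1] - 8) <= 2 & abs(pts[, 3] - 8) <= 2))
})

test_that("non-maximum suppression keeps ridge crests and constant maps", {
  kern <- kernelSpec("gaussian", 2)
  v <- heatmapValues(renderHeatmap(rbind(c(-5, 10), c(45, 10)), kern,
                                   "min", c(21, 40)))
  nm <- nmsHeatmap(v, 1)
  expect_true(all(nm[11, 5:35] > 0))       # crest row survives
  expect_true(all(nm[c(8, 9, 13, 14), 5:35] == 0))  # flanks suppressed
  cst <- matrix(0.4, 15, 15)
  expect_equal(nmsHeatmap(cst, 1), cst)    # no orthogonal dominance
})

test_that("F-measure counts one-to-one matches within the tolerance", {
  gt <- cbind(1:20, rep(5, 20))
  r <- fMeasure(gt, gt, dmax = 2)
  expect_equal(r$f, 1)
  far <- sweep(gt, 2, c(0, 50), "+")
  expect_equal(fMeasure(far, gt, dmax = 2)$f, 0)
  expect_equal(fMeasure(gt[0, ], gt, dmax = 2)$f, 0)
  expect_error(fMeasure(gt, gt[0, ], dmax = 2), "non-empty")
  expect_error(fMeasure(gt, gt, dmax = 0), "positive")
  # the benchmark tolerance: 0.0075 of a 256 x 256 diagonal
  expect_equal(0.0075 * sqrt(2 * 256^2), 2.715, tolerance = 1e-3)
  # one-to-one: two predictions cannot both claim one ground-truth point
  r2 <- fMeasure(rbind(c(5, 5), c(5.4, 5)), rbind(c(5, 5)), dmax = 2)
  expect_equal(r2$matched, 1L)
  expect_equal(r2$precision, 0.5)
  # adding a correctly matched point never lowers F
  pred <- gt[1:10, ]
  f1 <- fMeasure(pred, gt, dmax = 2)$f
  f2 <- fMeasure(gt[1:11, ], gt, dmax = 2)$f
  expect_gte(f2, f1)
})

test_that("matching is minimum-cost among maximum matchings", {
  # two predictions, two gt; greedy-by-order would mismatch
  pred <- rbind(c(0, 0), c(1, 0))
  gt <- rbind(c(1.2, 0), c(-0.1, 0))
  r <- fMeasure(pred, gt, dmax = 1.5)
  expect_equal(r$matched, 2L)
  expect_equal(r$f, 1)
})

test_that("ODS/OIS aggregate pooled and per-image optima correctly", {
  kern <- kernelSpec("gaussian", 2)
  mk <- function(y) {
    poly <- rbind(c(-5, y), c(45, y))
    list(hm = heatmapValues(renderHeatmap(poly, kern, "min", c(30, 40))),
         gt = raster_points(polyline(poly), c(30, 40)))
  }
  a <- mk(10); b <- mk(18)
  thr <- seq(0.1, 0.9, by = 0.1)
  one <- odsOis(list(a$hm), list(a$gt), thresholds = thr, dmax = 3)
  expect_equal(one$ods, one$ois)           # single image
  two <- odsOis(list(a$hm, a$hm), list(a$gt, a$gt), thresholds = thr, dmax = 3)
  expect_equal(two$ods, one$ods, tolerance = 1e-12)  # identical images pool
  mixed <- odsOis(list(a$hm, b$hm), list(a$gt, b$gt), thresholds = thr, dmax = 3)
  expect_gte(mixed$ois, mixed$ods)         # per-image optimum dominates
  expect_gt(mixed$ods, 0.8)                # clean renders score high
  # pooled-count recomputation consistency
  tab <- mixed$table
  s <- tab[tab$threshold == mixed$odsThreshold, ]
  P <- sum(s$matched) / sum(s$npred); R <- sum(s$matched) / sum(s$ngt)
  expect_equal(mixed$ods, 2 * P * R / (P + R))
})
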