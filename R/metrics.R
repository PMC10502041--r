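shift_mat <- function(m, dr, dc) {
  # shift with zero fill: result[i, j] = m[i + dr, j + dc]
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Morphological thinning of a binary image (Zhang-Suen)
#'
#' Iterative two-subiteration thinning to a one-pixel-wide skeleton. A
#' binary image that is already one pixel wide is a fixed point.
#'
#' @param binary logical or 0/1 matrix.
#' @return 0/1 integer matrix of the skeleton.
#' @export
thinBinary <- function(binary) {
  m <- (as.matrix(binary) > 0) + 0L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbors clockwise from north: P2..P9
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
           (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
           (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
           (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      if (sub == 1L) {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- m == 1L & B >= 2L & B <= 6L & A == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# ---- 3D thinning by sequential removal of simple border voxels ----

n26_offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
n26_offsets <- n26_offsets[rowSums(abs(n26_offsets)) > 0, ]
n6_offsets <- n26_offsets[rowSums(abs(n26_offsets)) == 1, ]

# is the foreground of the 26-neighborhood one 26-connected component,
# and the background 6-neighbors one 6-connected component within N18?
is_simple_voxel <- function(nb) {
  # nb: 3x3x3 0/1 array with center at [2,2,2]
  fg <- which(nb == 1L)
  fg <- setdiff(fg, 14L)
  if (length(fg) == 0L) return(FALSE)
  pos <- arrayInd(fg, c(3L, 3L, 3L))
  # 26-connectivity components of foreground neighbors
  ncomp <- function(pts, maxd) {
    n <- nrow(pts)
    lab <- integer(n)
    comp <- 0L
    for (i in seq_len(n)) {
      if (lab[i]) next
      comp <- comp + 1L
      queue <- i; lab[i] <- comp
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        d <- abs(pts[, 1L] - pts[cur, 1L]) + abs(pts[, 2L] - pts[cur, 2L]) +
          abs(pts[, 3L] - pts[cur, 3L])
        cheb <- pmax(abs(pts[, 1L] - pts[cur, 1L]),
                     pmax(abs(pts[, 2L] - pts[cur, 2L]),
                          abs(pts[, 3L] - pts[cur, 3L])))
        adj <- if (maxd == 26L) cheb == 1L else d == 1L
        nxt <- which(adj & lab == 0L)
        lab[nxt] <- comp
        queue <- c(queue, nxt)
      }
    }
    comp
  }
  if (ncomp(pos, 26L) != 1L) return(FALSE)
  # background 6-neighbors, connected via 6-adjacency within the 18-neighborhood
  bgmask <- nb == 0L
  six <- rbind(c(1,2,2), c(3,2,2), c(2,1,2), c(2,3,2), c(2,2,1), c(2,2,3))
  bg6 <- six[bgmask[six], , drop = FALSE]
  if (nrow(bg6) == 0L) return(FALSE)
  # 18-neighborhood background cells (|off| sum <= 2, excluding corners)
  all18 <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  keep <- rowSums(abs(all18 - 2L)) <= 2L & rowSums(abs(all18 - 2L)) > 0L
  cand <- all18[keep, , drop = FALSE]
  cand <- cand[bgmask[cand], , drop = FALSE]
  if (nrow(cand) == 0L) return(FALSE)
  # components of cand under 6-adjacency; count those containing a 6-neighbor
  n <- nrow(cand)
  lab <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (lab[i]) next
    comp <- comp + 1L
    queue <- i; lab[i] <- comp
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      d <- abs(cand[, 1L] - cand[cur, 1L]) + abs(cand[, 2L] - cand[cur, 2L]) +
        abs(cand[, 3L] - cand[cur, 3L])
      nxt <- which(d == 1L & lab == 0L)
      lab[nxt] <- comp
      queue <- c(queue, nxt)
    }
  }
  is6 <- rowSums(abs(cand - 2L)) == 1L
  length(unique(lab[is6])) == 1L
}

#' Morphological thinning of a binary volume
#'
#' Sequentially removes simple border voxels (one 26-connected foreground
#' component and one 6-connected background component in the local
#' neighborhood) while preserving curve endpoints (voxels with a single
#' 26-neighbor), yielding a unit-width 26-connected skeleton.
#'
#' @param vol logical or 0/1 3D array.
#' @return 0/1 integer array of the skeleton.
#' @export
thinBinary3d <- function(vol) {
  v <- (as.array(vol) > 0) + 0L
  d <- dim(v)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  dirs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  repeat {
    changed <- FALSE
    # six directional subiterations erode the object symmetrically
    for (dd in seq_len(nrow(dirs))) {
      idx <- which(pad == 1L)
      if (length(idx) == 0L) break
      ai <- arrayInd(idx, dim(pad))
      off <- dirs[dd, ]
      border <- pad[cbind(ai[, 1L] + off[1L], ai[, 2L] + off[2L],
                          ai[, 3L] + off[3L])] == 0L
      for (k in which(border)) {
        i <- ai[k, 1L]; j <- ai[k, 2L]; l <- ai[k, 3L]
        if (pad[i, j, l] == 0L) next
        nb <- pad[(i - 1):(i + 1), (j - 1):(j + 1), (l - 1):(l + 1)]
        if (sum(nb) - 1L <= 1L) next           # endpoint: keep
        if (is_simple_voxel(nb)) {
          pad[i, j, l] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
}

otsu_threshold <- function(x) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) < 1e-12)
    stop("cannot threshold a constant map")
  scaled <- (v - rng[1L]) / diff(rng)
  n <- length(scaled)
  side <- ceiling(sqrt(n))
  padded <- c(scaled, rep(scaled[n], side * side - n))
  thr <- EBImage::otsu(EBImage::Image(matrix(padded, side, side)),
                       range = c(0, 1))
  thr * diff(rng) + rng[1L]
}

#' Extract a unit-width centerline from a heatmap
#'
#' Variant-1 signal recovery: Otsu thresholding of the heatmap followed by
#' morphological thinning to unit width (Zhang-Suen in 2D, simple-point
#' thinning in 3D).
#'
#' @param hm a [Heatmap-class] or numeric matrix/array.
#' @return Matrix of 0-based point coordinates (`x, y[, z]`), one per row.
#' @export
extractCenterline <- function(hm) {
  x <- if (is(hm, "Heatmap")) heatmapValues(hm) else as.array(hm)
  thr <- otsu_threshold(x)
  b <- (x > thr) + 0L
  nd <- length(dim(x))
  sk <- if (nd == 2L) thinBinary(b) else thinBinary3d(b)
  ai <- which(sk == 1L, arr.ind = TRUE)
  if (nd == 2L) cbind(x = ai[, 2L] - 1L, y = ai[, 1L] - 1L)
  else cbind(x = ai[, 2L] - 1L, y = ai[, 1L] - 1L, z = ai[, 3L] - 1L)
}

min_cross_dist <- function(A, B) {
  # for each row of A, min Euclidean distance to rows of B (chunked)
  n <- nrow(A)
  out <- numeric(n)
  chunk <- max(1L, floor(4e6 / nrow(B)))
  i <- 1L
  while (i <= n) {
    j <- min(n, i + chunk - 1L)
    As <- A[i:j, , drop = FALSE]
    d2 <- matrix(0, nrow(As), nrow(B))
    for (ax in seq_len(ncol(A)))
      d2 <- d2 + (As[, ax] - rep(B[, ax], each = nrow(As)))^2
    out[i:j] <- sqrt(apply(d2, 1L, min))
    i <- j + 1L
  }
  out
}

#' Average symmetric surface distance between two point sets
#'
#' `ASSD = (sum_{x in C} d(x, C') + sum_{x' in C'} d(x', C)) / (|C| + |C'|)`
#' with `d` the minimum Euclidean distance. Symmetric, non-negative, and
#' zero exactly when the two sets coincide. Works identically for 2D pixel
#' and 3D voxel sets.
#'
#' @param C,Cp coordinate matrices (one point per row), both non-empty.
#' @return The ASSD in px/voxels.
#' @export
assd <- function(C, Cp) {
  C <- as.matrix(C); Cp <- as.matrix(Cp)
  if (nrow(C) == 0L || nrow(Cp) == 0L)
    stop("assd requires two non-empty point sets")
  (sum(min_cross_dist(C, Cp)) + sum(min_cross_dist(Cp, C))) /
    (nrow(C) + nrow(Cp))
}

#' Non-maximum suppression of a curve response map
#'
#' Suppresses cells whose response is exceeded by an interpolated neighbor
#' in the across-ridge direction within radius `rspr`. The local
#' orientation is estimated from second derivatives of the smoothed map
#' (the standard boundary-benchmark scheme); cells with no orientation
#' signal (e.g. constant regions) are kept.
#'
#' @param hm a [Heatmap-class] or numeric matrix (2D).
#' @param rspr suppression radius in px (>= 1, default 1).
#' @return The suppressed map (matrix).
#' @export
nmsHeatmap <- function(hm, rspr = 1) {
  E <- if (is(hm, "Heatmap")) heatmapValues(hm) else as.matrix(hm)
  if (rspr < 1) stop("rspr must be >= 1")
  # triangle-smoothed copy for orientation estimation
  k <- outer(c(1, 2, 1), c(1, 2, 1)); k <- k / sum(k)
  Es <- conv2_padded(E, k)
  gx <- (shift_mat_num(Es, 0L, 1L) - shift_mat_num(Es, 0L, -1L)) / 2
  gy <- (shift_mat_num(Es, 1L, 0L) - shift_mat_num(Es, -1L, 0L)) / 2
  gxx <- (shift_mat_num(gx, 0L, 1L) - shift_mat_num(gx, 0L, -1L)) / 2
  gxy <- (shift_mat_num(gx, 1L, 0L) - shift_mat_num(gx, -1L, 0L)) / 2
  gyy <- (shift_mat_num(gy, 1L, 0L) - shift_mat_num(gy, -1L, 0L)) / 2
  theta <- atan2(gyy * sign(-gxy + 1e-15), gxx + 1e-15) %% pi
  mag <- abs(gxx) + abs(gyy) + abs(gxy)
  out <- E
  nr <- nrow(E); nc <- ncol(E)
  co <- cos(theta); si <- sin(theta)
  xs <- matrix(rep(seq_len(nc), each = nr), nr)
  ys <- matrix(rep(seq_len(nr), nc), nr)
  interp <- function(xq, yq) {
    x0 <- floor(xq); y0 <- floor(yq)
    fx <- xq - x0; fy <- yq - y0
    get <- function(xi, yi) {
      v <- matrix(0, nr, nc)
      ok <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
      v[ok] <- E[cbind(yi[ok], xi[ok])]
      v
    }
    get(x0, y0) * (1 - fx) * (1 - fy) + get(x0 + 1, y0) * fx * (1 - fy) +
      get(x0, y0 + 1) * (1 - fx) * fy + get(x0 + 1, y0 + 1) * fx * fy
  }
  for (d in seq_len(ceiling(rspr))) {
    for (sgn in c(-1, 1)) {
      nb <- interp(xs + sgn * d * co, ys + sgn * d * si)
      out[E * 1.0001 < nb & mag > 1e-10] <- 0
    }
  }
  out
}

shift_mat_num <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

match_point_sets <- function(pred, gt, dmax, greedyAbove = 5000L) {
  # number of one-to-one matches with pairwise distance <= dmax
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0L || ng == 0L) return(0L)
  d2max <- dmax^2
  pairs <- NULL
  for (i in seq_len(np)) {
    d2 <- rowSums(sweep(gt, 2L, pred[i, ])^2)
    j <- which(d2 <= d2max)
    if (length(j))
      pairs <- rbind(pairs, cbind(i, j, sqrt(d2[j])))
  }
  if (is.null(pairs)) return(0L)
  if (np > greedyAbove || ng > greedyAbove) {
    # greedy by increasing distance
    ord <- order(pairs[, 3L])
    usedP <- logical(np); usedG <- logical(ng)
    cnt <- 0L
    for (k in ord) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!usedP[i] && !usedG[j]) { usedP[i] <- TRUE; usedG[j] <- TRUE; cnt <- cnt + 1L }
    }
    return(cnt)
  }
  # maximum-weight bipartite matching; edge weight C - d with C large makes
  # the optimum a maximum-cardinality, minimum-total-distance matching
  C <- (min(np, ng) + 1) * dmax + 1
  edges <- as.vector(t(cbind(pairs[, 1L], np + pairs[, 2L])))
  g <- igraph::make_bipartite_graph(c(rep(FALSE, np), rep(TRUE, ng)), edges)
  mm <- igraph::max_bipartite_match(
    g, types = c(rep(FALSE, np), rep(TRUE, ng)),
    weights = C - pairs[, 3L])
  mm$matching_size
}

#' Boundary F-measure between predicted and ground-truth curve points
#'
#' One-to-one minimum-cost correspondence between the two point sets with
#' matches farther than `dmax` forbidden; precision is the matched fraction
#' of predictions, recall the matched fraction of ground truth, and
#' `F = 2PR/(P+R)` (0 when `P + R = 0`).
#'
#' @param pred predicted curve points (matrix, possibly 0 rows).
#' @param gt ground-truth curve points (matrix, non-empty).
#' @param dmax matching distance tolerance in px (> 0); the benchmark
#'   convention is 0.0075 of the image diagonal.
#' @return List with `precision`, `recall`, `f` and `matched`.
#' @export
fMeasure <- function(pred, gt, dmax) {
  gt <- as.matrix(gt)
  if (nrow(gt) == 0L) stop("ground-truth point set must be non-empty")
  if (dmax <= 0) stop("dmax must be positive")
  pred <- as.matrix(pred)
  if (nrow(pred) == 0L)
    return(list(precision = 0, recall = 0, f = 0, matched = 0L))
  m <- match_point_sets(pred, gt, dmax)
  P <- m / nrow(pred); R <- m / nrow(gt)
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  list(precision = P, recall = R, f = f, matched = m)
}

#' ODS and OIS summary F-measures over a set of images
#'
#' Variant-2 evaluation: each predicted response map is non-maximum
#' suppressed, binarized at every threshold of a common grid, thinned to
#' unit width and matched one-to-one against the ground-truth points within
#' `dmax`. ODS is the F-measure of the pooled matched/total counts at the
#' single best dataset-wide threshold; OIS averages each image's best
#' F-measure.
#'
#' @param preds list of predicted heatmaps (matrices or [Heatmap-class]).
#' @param gts list of ground-truth point matrices (same length).
#' @param thresholds common threshold grid (default 99 uniform in (0,1)).
#' @param dmax matching tolerance in px; default 0.0075 of the first
#'   image's diagonal.
#' @param rspr NMS radius (default 1); `NULL` disables NMS.
#' @return List with `ods`, `ois`, `odsThreshold` and the per-image,
#'   per-threshold count table.
#' @export
odsOis <- function(preds, gts, thresholds = seq(0.01, 0.99, by = 0.01),
                   dmax = NULL, rspr = 1) {
  stopifnot(length(preds) >= 1L, length(preds) == length(gts))
  rows <- list()
  for (ii in seq_along(preds)) {
    E <- if (is(preds[[ii]], "Heatmap")) heatmapValues(preds[[ii]])
         else as.matrix(preds[[ii]])
    if (is.null(dmax)) dmax <- 0.0075 * sqrt(sum(dim(E)^2))
    En <- if (!is.null(rspr)) nmsHeatmap(E, rspr) else E
    gt <- as.matrix(gts[[ii]])
    for (thr in thresholds) {
      b <- (En >= thr) + 0L
      if (!any(b == 1L)) {
        rows[[length(rows) + 1L]] <- data.frame(
          image = ii, threshold = thr, matched = 0L, npred = 0L,
          ngt = nrow(gt))
        next
      }
      sk <- thinBinary(b)
      ai <- which(sk == 1L, arr.ind = TRUE)
      pts <- cbind(ai[, 2L] - 1L, ai[, 1L] - 1L)
      m <- match_point_sets(pts, gt, dmax)
      rows[[length(rows) + 1L]] <- data.frame(
        image = ii, threshold = thr, matched = m, npred = nrow(pts),
        ngt = nrow(gt))
    }
  }
  tab <- do.call(rbind, rows)
  fof <- function(m, np, ng) {
    P <- if (np > 0) m / np else 0
    R <- if (ng > 0) m / ng else 0
    if (P + R > 0) 2 * P * R / (P + R) else 0
  }
  pooled <- vapply(thresholds, function(thr) {
    s <- tab[tab$threshold == thr, ]
    fof(sum(s$matched), sum(s$npred), sum(s$ngt))
  }, 0)
  per_image_best <- vapply(seq_along(preds), function(ii) {
    s <- tab[tab$image == ii, ]
    max(mapply(fof, s$matched, s$npred, s$ngt))
  }, 0)
  list(ods = max(pooled), odsThreshold = thresholds[which.max(pooled)],
       ois = mean(per_image_best), table = tab)
}
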