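#' Euclidean distance from points to a closed line segment
#'
#' `f(x) = || x - (l1 + s b / ||b||) ||` with `a = x - l1`, `b = l2 - l1`
#' and `s = clamp(a . b / ||b||, 0, ||b||)`: the exact distance to the closed
#' segment, in any dimension.
#'
#' @param x point coordinates: vector or matrix (one point per row).
#' @param l1,l2 segment start and end point (distinct).
#' @return Numeric vector of distances.
#' @examples
#' pointSegmentDistance(c(1, 1), c(0, 0), c(2, 0))   # 1
#' pointSegmentDistance(c(-1, 1), c(0, 0), c(2, 0))  # sqrt(2)
#' @export
pointSegmentDistance <- function(x, l1, l2) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  b <- l2 - l1
  bl <- sqrt(sum(b^2))
  if (bl <= 0) stop("degenerate segment: l1 and l2 coincide")
  u <- b / bl
  a <- sweep(x, 2L, l1)
  s <- pmin(pmax(as.vector(a %*% u), 0), bl)
  proj <- outer(s, u)
  sqrt(rowSums((a - proj)^2))
}

#' Build axis-aligned hull boxes for a polyline
#'
#' One axis-aligned box per segment, enclosing the segment dilated by `w/2`
#' along every axis, plus two end-cap boxes of side `w` centered on the
#' first and last polyline points (the per-segment hull does not extend in
#' the curve direction beyond the endpoints). Boxes are expressed as
#' inclusive integer cell-index ranges (0-based cell-center coordinates),
#' rounded outward and clipped to the grid; boxes falling entirely outside
#' the grid are dropped. In 3D the boxes are axis-aligned cuboids (with
#' cubic end caps), the axis-aligned realization of the right rectangular
#' prism hulls.
#'
#' @param poly a [Polyline-class] (or coordinate matrix).
#' @param w support width in px (> 0); cells farther than `w/2` from the
#'   segment carry no kernel mass.
#' @param shape grid dimensions `c(H, W)` or `c(H, W, D)`.
#' @return A data.frame with one row per retained box: `segment` (1-based
#'   segment index), `cap` (logical), and per-axis inclusive ranges `x0,x1`,
#'   `y0,y1` (and `z0,z1` in 3D).
#' @export
buildHulls <- function(poly, w, shape) {
  poly <- polyline(poly)
  if (!is.numeric(w) || w <= 0) stop("support w must be positive")
  p <- coords(poly)
  nd <- ncol(p)
  if (length(shape) != nd)
    stop("grid shape has ", length(shape), " dimensions but polyline is ", nd, "D")
  # per-axis grid extents in x,y[,z] order: x ~ cols, y ~ rows, z ~ slices
  ext <- if (nd == 2L) c(shape[2L], shape[1L]) else c(shape[2L], shape[1L], shape[3L])
  ns <- nrow(p) - 1L
  a <- p[-nrow(p), , drop = FALSE]
  b <- p[-1L, , drop = FALSE]
  lo <- floor(pmin(a, b) - w / 2)
  hi <- ceiling(pmax(a, b) + w / 2)
  seg_idx <- seq_len(ns)
  cap_lo <- floor(p[c(1L, nrow(p)), , drop = FALSE] - w / 2)
  cap_hi <- ceiling(p[c(1L, nrow(p)), , drop = FALSE] + w / 2)
  lo <- rbind(lo, cap_lo)
  hi <- rbind(hi, cap_hi)
  segment <- c(seg_idx, 1L, ns)
  cap <- c(rep(FALSE, ns), TRUE, TRUE)
  keep <- rep(TRUE, nrow(lo))
  for (ax in seq_len(nd)) {
    lo[, ax] <- pmax(lo[, ax], 0)
    hi[, ax] <- pmin(hi[, ax], ext[ax] - 1L)
    keep <- keep & lo[, ax] <= hi[, ax]
  }
  out <- data.frame(segment = segment, cap = cap,
                    x0 = lo[, 1L], x1 = hi[, 1L],
                    y0 = lo[, 2L], y1 = hi[, 2L])
  if (nd == 3L) { out$z0 <- lo[, 3L]; out$z1 <- hi[, 3L] }
  out[keep, , drop = FALSE]
}

#' Winner-take-all reduction of distance estimates
#'
#' Maps a collection of per-segment distance estimates at one cell to a
#' heatmap value by evaluating the kernel at the smallest estimate.
#'
#' @param f non-empty numeric vector of distance estimates.
#' @param kernel a [KernelSpec-class].
#' @return `h(min(f))`.
#' @export
reduceMin <- function(f, kernel) {
  if (length(f) == 0L) stop("no distance estimates to reduce")
  evaluateKernel(kernel, min(f))
}

#' Inverse-distance-weighted reduction of distance estimates
#'
#' Shepard weighting of all estimates, `sum(lambda h(f)) / sum(lambda)` with
#' `lambda_i = 1 / f_i^p`. A zero distance (cell exactly on the curve) takes
#' the continuous limit `h(0)`.
#'
#' @param f non-empty numeric vector of distance estimates.
#' @param kernel a [KernelSpec-class].
#' @param p power parameter, 1 (linear) or 2 (quadratic).
#' @return The weighted heatmap value.
#' @examples
#' g <- kernelSpec("gaussian", 1)
#' reduceIdw(c(1, 2), g, p = 2)  # (exp(-1/2) + 0.25 exp(-2)) / 1.25
#' @export
reduceIdw <- function(f, kernel, p = 1) {
  if (length(f) == 0L) stop("no distance estimates to reduce")
  if (any(f == 0)) return(evaluateKernel(kernel, 0))
  lam <- 1 / f^p
  sum(lam * evaluateKernel(kernel, f)) / sum(lam)
}

# cell-center coordinate arrays for a hull box (2D)
box_cells_2d <- function(bx) {
  xs <- bx$x0:bx$x1
  ys <- bx$y0:bx$y1
  nx <- length(xs); ny <- length(ys)
  cbind(x = rep(xs, each = ny), y = rep(ys, nx))
}

#' Render a polyline into a heatmap
#'
#' For every hull box the exact point-to-segment distance is evaluated at
#' all contained cell centers; cells covered by several boxes combine their
#' estimates with the chosen reduction (running minimum, or accumulated
#' Shepard weights); cells in no hull are 0. The support is `w = 6 sigma`
#' (the two-sided compact support of the kernel), so runtime scales with
#' the number of covered cells, not the grid size.
#'
#' @param poly a [Polyline-class] (or coordinate matrix); 2D or 3D.
#' @param kernel a [KernelSpec-class].
#' @param reduction `"min"`, `"idw1"` or `"idw2"`.
#' @param shape grid dimensions `c(H, W)` or `c(H, W, D)`.
#' @return A [Heatmap-class] of dimension `shape`.
#' @examples
#' hm <- renderHeatmap(rbind(c(5, 10), c(25, 10)), kernelSpec("gaussian", 2),
#'                     shape = c(21, 31))
#' max(heatmapValues(hm))  # 1 (curve crosses cell centers)
#' @export
renderHeatmap <- function(poly, kernel, reduction = c("min", "idw1", "idw2"),
                          shape) {
  reduction <- match.arg(reduction)
  stopifnot(is(kernel, "KernelSpec"))
  poly <- polyline(poly)
  nd <- spatialDim(poly)
  if (length(shape) != nd)
    stop("grid shape has ", length(shape), " dimensions but polyline is ", nd, "D")
  w <- 2 * kernelSupport(kernel)
  hulls <- buildHulls(poly, w, shape)
  p <- coords(poly)
  h0 <- evaluateKernel(kernel, 0)
  pw <- if (reduction == "idw2") 2 else 1
  if (reduction == "min") {
    md <- array(Inf, dim = shape)
  } else {
    sw <- array(0, dim = shape)
    swh <- array(0, dim = shape)
    zero <- array(FALSE, dim = shape)
  }
  for (i in seq_len(nrow(hulls))) {
    bx <- hulls[i, ]
    l1 <- p[bx$segment, ]
    l2 <- p[bx$segment + 1L, ]
    if (nd == 2L) {
      cells <- box_cells_2d(bx)
      idx <- cbind(cells[, 2L] + 1L, cells[, 1L] + 1L)
    } else {
      xy <- box_cells_2d(bx)
      zs <- bx$z0:bx$z1
      nxy <- nrow(xy)
      cells <- cbind(xy[rep(seq_len(nxy), times = length(zs)), , drop = FALSE],
                     z = rep(zs, each = nxy))
      idx <- cbind(cells[, 2L] + 1L, cells[, 1L] + 1L, cells[, 3L] + 1L)
    }
    # integer index ranges are rounded outward; keep only cells whose
    # center lies in the exact (unrounded) hull box so that grid rendering
    # and continuous field evaluation collect identical estimates
    ref <- if (bx$cap) {
      if (bx$segment == 1L) p[1L, ] else p[nrow(p), ]
    } else NULL
    lo_ex <- if (is.null(ref)) pmin(l1, l2) - w / 2 else ref - w / 2
    hi_ex <- if (is.null(ref)) pmax(l1, l2) + w / 2 else ref + w / 2
    keep <- rep(TRUE, nrow(cells))
    for (ax in seq_len(nd))
      keep <- keep & cells[, ax] >= lo_ex[ax] & cells[, ax] <= hi_ex[ax]
    if (!any(keep)) next
    cells <- cells[keep, , drop = FALSE]
    idx <- idx[keep, , drop = FALSE]
    d <- pointSegmentDistance(cells, l1, l2)
    if (reduction == "min") {
      md[idx] <- pmin(md[idx], d)
    } else {
      z <- d < 1e-9
      zero[idx[z, , drop = FALSE]] <- TRUE
      lam <- 1 / pmax(d, 1e-12)^pw
      sw[idx] <- sw[idx] + lam
      swh[idx] <- swh[idx] + lam * evaluateKernel(kernel, d)
    }
  }
  if (reduction == "min") {
    vals <- array(0, dim = shape)
    fin <- is.finite(md)
    vals[fin] <- evaluateKernel(kernel, md[fin])
  } else {
    vals <- array(0, dim = shape)
    pos <- sw > 0
    vals[pos] <- swh[pos] / sw[pos]
    vals[zero] <- h0
  }
  asHeatmap(vals)
}

#' Evaluate the heatmap field at arbitrary points
#'
#' Point-wise analogue of [renderHeatmap()]: each query point collects
#' distance estimates from every segment whose hull box (axis-aligned
#' bounding box dilated by `w/2`, plus end caps) contains it, and the
#' estimates are combined with the chosen reduction. Points inside no hull
#' evaluate to 0.
#'
#' @param poly a [Polyline-class] (or coordinate matrix).
#' @param kernel a [KernelSpec-class].
#' @param points query coordinates, one per row.
#' @param reduction `"min"`, `"idw1"` or `"idw2"`.
#' @return Numeric vector of heatmap values at the query points.
#' @export
evaluateHeatmapField <- function(poly, kernel, points,
                                 reduction = c("min", "idw1", "idw2")) {
  reduction <- match.arg(reduction)
  poly <- polyline(poly)
  p <- coords(poly)
  nd <- ncol(p)
  points <- as.matrix(points)
  w2 <- kernelSupport(kernel)          # w / 2 = 3 sigma
  n <- nrow(points)
  pw <- if (reduction == "idw2") 2 else 1
  if (reduction == "min") {
    best <- rep(Inf, n)
  } else {
    sw <- numeric(n); swh <- numeric(n); zero <- logical(n)
  }
  ns <- nrow(p) - 1L
  boxes <- vector("list", ns + 2L)
  for (si in seq_len(ns))
    boxes[[si]] <- list(seg = si,
                        lo = pmin(p[si, ], p[si + 1L, ]) - w2,
                        hi = pmax(p[si, ], p[si + 1L, ]) + w2)
  boxes[[ns + 1L]] <- list(seg = 1L, lo = p[1L, ] - w2, hi = p[1L, ] + w2)
  boxes[[ns + 2L]] <- list(seg = ns, lo = p[ns + 1L, ] - w2, hi = p[ns + 1L, ] + w2)
  for (bx in boxes) {
    sel <- rep(TRUE, n)
    for (ax in seq_len(nd))
      sel <- sel & points[, ax] >= bx$lo[ax] & points[, ax] <= bx$hi[ax]
    if (!any(sel)) next
    d <- pointSegmentDistance(points[sel, , drop = FALSE],
                              p[bx$seg, ], p[bx$seg + 1L, ])
    if (reduction == "min") {
      best[sel] <- pmin(best[sel], d)
    } else {
      ii <- which(sel)
      zero[ii[d < 1e-9]] <- TRUE
      lam <- 1 / pmax(d, 1e-12)^pw
      sw[ii] <- sw[ii] + lam
      swh[ii] <- swh[ii] + lam * evaluateKernel(kernel, d)
    }
  }
  if (reduction == "min") {
    out <- numeric(n)
    fin <- is.finite(best)
    out[fin] <- evaluateKernel(kernel, best[fin])
  } else {
    out <- numeric(n)
    pos <- sw > 0
    out[pos] <- swh[pos] / sw[pos]
    out[zero] <- evaluateKernel(kernel, 0)
  }
  out
}

#' Per-cell distance estimates within hull boxes
#'
#' Collects, for each query point, the individual per-segment distance
#' estimates contributed by every hull box containing it (the inputs to
#' [reduceMin()] / [reduceIdw()]).
#'
#' @param poly a [Polyline-class] (or coordinate matrix).
#' @param points query coordinates, one per row.
#' @param w support width in px.
#' @return A list with one numeric vector of estimates per query point
#'   (possibly empty for points outside every hull).
#' @export
distanceEstimates <- function(poly, points, w) {
  poly <- polyline(poly)
  p <- coords(poly)
  nd <- ncol(p)
  points <- as.matrix(points)
  n <- nrow(points)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- numeric(0)
  ns <- nrow(p) - 1L
  add <- function(seg, lo, hi) {
    sel <- rep(TRUE, n)
    for (ax in seq_len(nd))
      sel <- sel & points[, ax] >= lo[ax] & points[, ax] <= hi[ax]
    if (!any(sel)) return()
    d <- pointSegmentDistance(points[sel, , drop = FALSE], p[seg, ], p[seg + 1L, ])
    ii <- which(sel)
    for (k in seq_along(ii)) out[[ii[k]]] <<- c(out[[ii[k]]], d[k])
  }
  for (si in seq_len(ns))
    add(si, pmin(p[si, ], p[si + 1L, ]) - w / 2, pmax(p[si, ], p[si + 1L, ]) + w / 2)
  add(1L, p[1L, ] - w / 2, p[1L, ] + w / 2)
  add(ns, p[ns + 1L, ] - w / 2, p[ns + 1L, ] + w / 2)
  out
}
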