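#' @import methods
NULL

KERNEL_FAMILIES <- c("gaussian", "laplace", "triangular", "rectangular",
                     "cosine", "catheter")

#' Ordered curve data points
#'
#' An ordered set of 2D or 3D coordinates describing an elongated structure.
#' Coordinates are in pixel/voxel units, 0-based, with `x` the column
#' direction, `y` the row direction and (3D only) `z` the slice direction.
#'
#' @slot coords numeric matrix, one point per row, 2 or 3 columns.
#' @export
setClass("ControlPoints", representation(coords = "matrix"))

setValidity("ControlPoints", function(object) {
  p <- object@coords
  if (!is.numeric(p)) return("coordinates must be numeric")
  if (!ncol(p) %in% c(2L, 3L)) return("points must be 2D or 3D")
  if (nrow(p) < 2L) return("at least two data points are required")
  if (any(!is.finite(p))) return("all coordinates must be finite")
  chords <- sqrt(rowSums((p[-1L, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(chords <= 0))
    return("consecutive data points must not coincide (degenerate chord)")
  TRUE
})

#' Construct a ControlPoints object
#'
#' @param coords numeric matrix (one point per row, 2 or 3 columns) or an
#'   object coercible to one.
#' @return A [ControlPoints-class] object.
#' @examples
#' controlPoints(rbind(c(0, 0), c(3, 4), c(3, 9)))
#' @export
controlPoints <- function(coords) {
  if (is(coords, "ControlPoints")) return(coords)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("ControlPoints", coords = coords)
}

#' Parametric B-spline curve
#'
#' A fitted parametric B-spline over the domain `[0, 1]`. The degree follows
#' the point-count rule (cubic for five or more points, quadratic for three,
#' linear for two) and the parameter values are chord-length ratios.
#'
#' @slot degree spline degree (1, 2 or 3).
#' @slot knots full knot vector (with `degree + 1` repeated boundary knots).
#' @slot coefs coefficient (control) points, one per row.
#' @slot params chord-length parameter value assigned to each data point.
#' @slot smoothing the smoothing budget `S` used for the fit (0 = interpolation).
#' @slot residual achieved sum of squared residuals at the data points.
#' @export
setClass("BSplineCurve",
         representation(degree = "integer", knots = "numeric",
                        coefs = "matrix", params = "numeric",
                        smoothing = "numeric", residual = "numeric"))

setValidity("BSplineCurve", function(object) {
  if (!object@degree %in% 1:3) return("degree must be 1, 2 or 3")
  if (is.unsorted(object@knots)) return("knot vector must be non-decreasing")
  if (nrow(object@coefs) != length(object@knots) - object@degree - 1L)
    return("coefficient count inconsistent with knots and degree")
  TRUE
})

#' Polyline sampled from a curve
#'
#' Ordered sample points connected by straight segments, produced by
#' [samplePolyline()] at uniform arc-length spacing.
#'
#' @slot coords sample point coordinates, one per row.
#' @slot cumlen cumulative chord length at each sample point (starts at 0).
#' @export
setClass("Polyline", representation(coords = "matrix", cumlen = "numeric"))

setValidity("Polyline", function(object) {
  if (nrow(object@coords) < 2L) return("a polyline needs at least two points")
  seg <- diff(object@cumlen)
  if (any(seg <= 0)) return("consecutive polyline samples must be distinct")
  TRUE
})

#' Construct a Polyline from vertex coordinates
#' @param coords numeric matrix of ordered vertices (one per row).
#' @return A [Polyline-class] object.
#' @export
polyline <- function(coords) {
  if (is(coords, "Polyline")) return(coords)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  seg <- sqrt(rowSums((coords[-1L, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  new("Polyline", coords = coords, cumlen = c(0, cumsum(seg)))
}

#' Distance-dependent kernel specification
#'
#' Describes the 1D distance-dependent function `h(f)` used to map
#' point-to-curve distances to heatmap values. All families have compact
#' support of half-width `3 * sigma`. In `peak` mode the maximum value is 1;
#' in `pdf` mode the profile carries the density normalization constant of
#' the corresponding full-support distribution.
#'
#' @slot family one of `"gaussian"`, `"laplace"`, `"triangular"`,
#'   `"rectangular"`, `"cosine"`, `"catheter"`.
#' @slot sigma width parameter in px, positive.
#' @slot s catheter inner-radius fraction in `[0, 1)` (catheter family only).
#' @slot mode `"peak"` or `"pdf"`.
#' @export
setClass("KernelSpec",
         representation(family = "character", sigma = "numeric",
                        s = "numeric", mode = "character"))

setValidity("KernelSpec", function(object) {
  if (!object@family %in% KERNEL_FAMILIES)
    return(paste("unknown kernel family:", object@family))
  if (!is.finite(object@sigma) || object@sigma <= 0)
    return("sigma must be positive and finite")
  if (object@family == "catheter" && (object@s < 0 || object@s >= 1))
    return("catheter wall fraction s must lie in [0, 1)")
  if (!object@mode %in% c("peak", "pdf")) return("mode must be 'peak' or 'pdf'")
  TRUE
})

#' Construct a KernelSpec
#'
#' @param family kernel family name.
#' @param sigma width in px (> 0).
#' @param s catheter inner-radius fraction in `[0, 1)`; default 0.5.
#' @param mode `"peak"` (maximum 1) or `"pdf"` (density constants).
#' @return A [KernelSpec-class] object.
#' @examples
#' kernelSpec("gaussian", sigma = 3)
#' kernelSpec("catheter", sigma = 3, s = 0.5)
#' @export
kernelSpec <- function(family = KERNEL_FAMILIES, sigma, s = 0.5,
                       mode = c("peak", "pdf")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  new("KernelSpec", family = family, sigma = as.numeric(sigma),
      s = as.numeric(s), mode = mode)
}

#' Heatmap on a pixel/voxel grid
#'
#' A non-negative scalar field sampled at cell centers. Cell centers sit at
#' integer coordinates starting from the origin `(0, 0[, 0])`; `x` indexes
#' columns, `y` rows and `z` slices, so `values[y + 1, x + 1 (, z + 1)]` is
#' the cell at coordinate `(x, y[, z])`.
#'
#' @slot values numeric array of dimension `H x W` (2D) or `H x W x D` (3D).
#' @export
setClass("Heatmap", representation(values = "array"))

setValidity("Heatmap", function(object) {
  nd <- length(dim(object@values))
  if (!nd %in% c(2L, 3L)) return("heatmap must be a 2D or 3D array")
  if (any(object@values < 0)) return("heatmap values must be non-negative")
  TRUE
})

#' Construct a Heatmap from an array
#' @param values numeric matrix (2D) or 3D array of non-negative values.
#' @return A [Heatmap-class] object.
#' @export
asHeatmap <- function(values) {
  if (is(values, "Heatmap")) return(values)
  values <- as.array(values)
  storage.mode(values) <- "double"
  new("Heatmap", values = values)
}

#' Simulated curve-on-background sample
#'
#' Bundles the outputs of [simulateSample()]: random-walk control points,
#' the rendered target heatmap and the composite image built from the
#' overlay model `X_sim = X_img + a * H * (1 + Z)`.
#'
#' @slot points generating [ControlPoints-class].
#' @slot heatmap rendered target [Heatmap-class].
#' @slot background grayscale background image in `[0, 1]`.
#' @slot composite overlay image (not clipped; may exceed 1).
#' @export
setClass("SimulatedSample",
         representation(points = "ControlPoints", heatmap = "Heatmap",
                        background = "matrix", composite = "matrix"))

# ---- accessors ----

#' @describeIn controlPoints Extract the coordinate matrix of a spatial object.
#' @param object a ControlPoints, Polyline or Heatmap object.
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @export
setMethod("coords", "ControlPoints", function(object) object@coords)

#' @export
setMethod("coords", "Polyline", function(object) object@coords)

#' Number of points of a spatial object
#' @param object a ControlPoints or Polyline object.
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @export
setMethod("nPoints", "ControlPoints", function(object) nrow(object@coords))

#' @export
setMethod("nPoints", "Polyline", function(object) nrow(object@coords))

#' Spatial dimensionality (2 or 3)
#' @param object a spatial object.
#' @export
setGeneric("spatialDim", function(object) standardGeneric("spatialDim"))

#' @export
setMethod("spatialDim", "ControlPoints", function(object) ncol(object@coords))

#' @export
setMethod("spatialDim", "Polyline", function(object) ncol(object@coords))

#' @export
setMethod("spatialDim", "BSplineCurve", function(object) ncol(object@coefs))

#' @export
setMethod("spatialDim", "Heatmap", function(object) length(dim(object@values)))

#' Total chord length of a polyline
#' @param object a [Polyline-class].
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))

#' @export
setMethod("totalLength", "Polyline",
          function(object) object@cumlen[length(object@cumlen)])

#' Heatmap value array
#' @param object a [Heatmap-class].
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))

#' @export
setMethod("heatmapValues", "Heatmap", function(object) object@values)

# ---- show methods ----

setMethod("show", "ControlPoints", function(object) {
  cat(sprintf("ControlPoints: %d points in %dD\n", nPoints(object),
              spatialDim(object)))
  print(utils::head(object@coords, 4))
  if (nPoints(object) > 4) cat(sprintf("  ... %d more\n", nPoints(object) - 4L))
})

setMethod("show", "BSplineCurve", function(object) {
  cat(sprintf(
    "BSplineCurve: degree %d, %d control points, %dD, S = %.4g (RSS = %.3g)\n",
    object@degree, nrow(object@coefs), spatialDim(object),
    object@smoothing, object@residual))
})

setMethod("show", "Polyline", function(object) {
  cat(sprintf("Polyline: %d points (%d segments), length %.4g px\n",
              nPoints(object), nPoints(object) - 1L, totalLength(object)))
})

setMethod("show", "KernelSpec", function(object) {
  extra <- if (object@family == "catheter") sprintf(", s = %.3g", object@s) else ""
  cat(sprintf("KernelSpec: %s, sigma = %.4g px%s, %s mode (support %.4g px)\n",
              object@family, object@sigma, extra, object@mode, 3 * object@sigma))
})

setMethod("show", "Heatmap", function(object) {
  d <- dim(object@values)
  cat(sprintf("Heatmap: %s grid, values in [%.4g, %.4g]\n",
              paste(d, collapse = " x "), min(object@values), max(object@values)))
})

setMethod("show", "SimulatedSample", function(object) {
  cat(sprintf("SimulatedSample: %d control points on a %s background\n",
              nPoints(object@points),
              paste(dim(object@background), collapse = " x ")))
})
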