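#' @import methods
NULL

#' Segmented pixels of one root individual
#'
#' A \code{PixelTrace} holds the raw per-root output of an upstream image
#' segmentation toolchain: the set of segmented pixel coordinates, the pixel
#' closest to the seed (the start point from which parameterization grows),
#' the acquisition day and the scan resolution. Image coordinates are
#' 0-based \code{(row, col)} with the origin at the top-left corner and rows
#' increasing downward.
#'
#' @slot pixels integer matrix with columns \code{row}, \code{col}
#' @slot start integer vector of length 2, \code{(row, col)} of the start
#'   pixel; must be one of \code{pixels}
#' @slot day positive number, acquisition day
#' @slot dpi positive number, scanner resolution in dots per inch
#' @slot rootId,genotype character labels
#' @seealso [reconstructRoot()], [readPixelTraces()]
#' @export
setClass("PixelTrace",
  representation(
    pixels   = "matrix",
    start    = "integer",
    day      = "numeric",
    dpi      = "numeric",
    rootId   = "character",
    genotype = "character"
  )
)

setValidity("PixelTrace", function(object) {
  msg <- character()
  p <- object@pixels
  if (nrow(p) < 1L) msg <- c(msg, "pixels must be non-empty")
  if (ncol(p) != 2L) msg <- c(msg, "pixels must have two columns (row, col)")
  if (any(p < 0L)) msg <- c(msg, "pixel coordinates must be non-negative")
  if (length(object@start) != 2L)
    msg <- c(msg, "start must be a (row, col) pair")
  else if (nrow(p) >= 1L &&
           !any(p[, 1L] == object@start[1L] & p[, 2L] == object@start[2L]))
    msg <- c(msg, "start pixel must be one of the trace pixels")
  if (length(object@day) != 1L || !is.finite(object@day) || object@day <= 0)
    msg <- c(msg, "day must be a single positive number")
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    msg <- c(msg, "dpi must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Planar B-spline curve
#'
#' An order-4 (cubic) non-uniform B-spline curve in image/world coordinates
#' (\code{x} = column, \code{y} = row; one unit is one pixel). The knot
#' vector is clamped: the first and last knot values are each repeated
#' \code{order} times, so the curve interpolates its terminal control points.
#' The parameter domain is \code{[knots[order], knots[n+1]]}; after
#' reconstruction the domain is \code{[0, d]} where \code{d} is the
#' acquisition day, making the parameter a (daily-resolution) time axis.
#'
#' @slot order integer spline order (degree + 1); 4 throughout the package
#' @slot knots numeric, non-decreasing clamped knot vector of length
#'   \code{nrow(controlPoints) + order}
#' @slot controlPoints numeric matrix with columns \code{x}, \code{y}
#' @slot rootId,genotype character labels (may be empty)
#' @slot dpi numeric, scan resolution the coordinates refer to (NA allowed)
#' @seealso [fitBSpline()], [evalCurve()], [reparameterizeToDays()]
#' @export
setClass("BSplineCurve",
  representation(
    order         = "integer",
    knots         = "numeric",
    controlPoints = "matrix",
    rootId        = "character",
    genotype      = "character",
    dpi           = "numeric"
  )
)

setValidity("BSplineCurve", function(object) {
  msg <- character()
  k <- object@knots
  cp <- object@controlPoints
  ord <- object@order
  if (length(ord) != 1L || ord < 2L) msg <- c(msg, "order must be >= 2")
  if (ncol(cp) != 2L) msg <- c(msg, "controlPoints must have columns x, y")
  if (nrow(cp) < ord) msg <- c(msg, "need at least `order` control points")
  if (length(k) != nrow(cp) + ord)
    msg <- c(msg, "knot count must equal #control points + order")
  if (is.unsorted(k)) msg <- c(msg, "knots must be non-decreasing")
  if (length(k) >= 2L * ord) {
    if (any(k[seq_len(ord)] != k[1L]) ||
        any(k[seq(length(k) - ord + 1L, length(k))] != k[length(k)]))
      msg <- c(msg, "knot vector must be clamped (end knots repeated `order` times)")
  }
  if (length(msg)) msg else TRUE
})

#' Curve ensemble on a shared B-spline basis
#'
#' All member curves are refit onto one common clamped basis (shared order
#' and knot vector, \code{n} control points per curve) and stored as rows of
#' a coefficient matrix: row \code{i} is \eqn{x_i \in R^{2n}}, the
#' x-coordinate control coefficients followed by the y-coordinate ones.
#' Euclidean geometry on these rows (distances, medians, depth) stands in
#' for the corresponding curve-space geometry.
#'
#' @slot order integer spline order (4)
#' @slot knots shared clamped knot vector of length \code{n + order}
#' @slot n integer, control points per curve (max over the members)
#' @slot coeffMatrix numeric matrix, one row of length \code{2n} per curve
#' @slot labels character root ids, one per row
#' @slot dpi numeric scan resolution carried through for unit conversion
#' @seealso [commonBasisEnsemble()], [ensembleDepths()], [geometricMedianCurve()]
#' @export
setClass("CommonBasisEnsemble",
  representation(
    order       = "integer",
    knots       = "numeric",
    n           = "integer",
    coeffMatrix = "matrix",
    labels      = "character",
    dpi         = "numeric"
  )
)

setValidity("CommonBasisEnsemble", function(object) {
  msg <- character()
  if (nrow(object@coeffMatrix) < 1L) msg <- c(msg, "ensemble must hold >= 1 curve")
  if (ncol(object@coeffMatrix) != 2L * object@n)
    msg <- c(msg, "coefficient rows must have length 2n")
  if (length(object@knots) != object@n + object@order)
    msg <- c(msg, "knot count must equal n + order")
  if (length(object@labels) != nrow(object@coeffMatrix))
    msg <- c(msg, "one label per coefficient row required")
  if (length(msg)) msg else TRUE
})

#' Result of the modified Weiszfeld iteration
#'
#' @slot y numeric, the estimated geometric median (Fermat-Weber minimizer)
#' @slot iterations integer, iterations performed
#' @slot finalStep numeric, Euclidean norm of the last update step
#' @slot rAtSolution numeric, norm of the summed unit direction vectors at
#'   the solution (near zero at an interior median)
#' @slot converged logical
#' @export
setClass("MedianEstimate",
  representation(
    y           = "numeric",
    iterations  = "integer",
    finalStep   = "numeric",
    rAtSolution = "numeric",
    converged   = "logical"
  )
)

#' L1-depth report for a curve ensemble
#'
#' Per-curve L1 data depths, curve box-plot zone labels, the index of the
#' deepest (most central) member, and the geometric-median curve (a virtual
#' representative that need not be a member of the ensemble).
#'
#' Zones follow the curve box-plot convention: curves whose depth is at
#' least the median depth form the interquartile set; curves whose depth
#' falls below \code{median - tukeyFactor * (max - median)} are outliers;
#' the rest are inliers.
#'
#' @slot depths numeric in (0, 1], one per curve
#' @slot zones factor with levels interquartile, inlier, outlier
#' @slot medianDepth,outlierThreshold numeric scalars
#' @slot tukeyFactor numeric, whisker multiplier (default 3)
#' @slot deepestIndex integer, row index of the maximal depth
#' @slot medianCurve the geometric-median \linkS4class{BSplineCurve}
#' @slot labels character root ids
#' @seealso [depthReport()], [classifyZones()]
#' @export
setClass("DepthReport",
  representation(
    depths           = "numeric",
    zones            = "factor",
    medianDepth      = "numeric",
    outlierThreshold = "numeric",
    tukeyFactor      = "numeric",
    deepestIndex     = "integer",
    medianCurve      = "BSplineCurve",
    labels           = "character"
  )
)

setValidity("DepthReport", function(object) {
  msg <- character()
  m <- length(object@depths)
  if (length(object@zones) != m) msg <- c(msg, "one zone per depth required")
  if (length(object@labels) != m) msg <- c(msg, "one label per depth required")
  if (m > 0L && object@deepestIndex != which.max(object@depths))
    msg <- c(msg, "deepestIndex must maximize depths")
  if (length(msg)) msg else TRUE
})

#' Thin-plate-spline time field
#'
#' The scalar field \eqn{F(x) = \beta_0 + \beta^T x + \sum_j \alpha_j
#' \phi_j(x)} with kernels \eqn{\phi_j(x) = \|x - c_j\|^2 \log\|x - c_j\|}
#' (defined as 0 at \eqn{x = c_j} by continuous extension). Fitted so that
#' F maps a planar position to the (fractional) day at which roots of the
#' ensemble typically reach it; its isocurves are the time-lines.
#'
#' @slot beta0 numeric intercept
#' @slot beta numeric length-2 linear coefficients
#' @slot alpha numeric kernel coefficients, one per center
#' @slot centers numeric matrix of kernel centers (columns x, y)
#' @slot cgIterations integer, conjugate-gradient iterations used
#' @slot cgResidual numeric, final relative residual of the normal equations
#' @seealso [fitTPS()], [evalTPS()], [extractIsocurves()]
#' @export
setClass("TPSSurface",
  representation(
    beta0        = "numeric",
    beta         = "numeric",
    alpha        = "numeric",
    centers      = "matrix",
    cgIterations = "integer",
    cgResidual   = "numeric"
  )
)

setValidity("TPSSurface", function(object) {
  msg <- character()
  if (length(object@beta) != 2L) msg <- c(msg, "beta must have length 2")
  if (nrow(object@centers) < 1L) msg <- c(msg, "at least one center required")
  if (length(object@alpha) != nrow(object@centers))
    msg <- c(msg, "one alpha per center required")
  if (length(msg)) msg else TRUE
})

#' Set of time-lines with confidence information
#'
#' For each requested time stamp: the isocurve polyline(s) of the TPS time
#' field at that level, the variance of the field residuals of the member
#' curves at that stamp, and a display color from a blue colormap in which
#' earlier days are brighter.
#'
#' @slot levels numeric time stamps (days)
#' @slot isocurves list (per level) of lists of polylines (matrices x, y)
#' @slot variances,sigmas numeric per level; sigma = sqrt(variance)
#' @slot bands list (per level) of confidence sub-band polygons covering
#'   the strip between the isocurves of \code{t - sigma} and
#'   \code{t + sigma}; empty for sigma = 0
#' @slot colors character per-level hex colors
#' @slot bbox numeric length-4 (xmin, xmax, ymin, ymax) evaluation window
#' @seealso [buildTimelines()]
#' @export
setClass("TimelineSet",
  representation(
    levels    = "numeric",
    isocurves = "list",
    variances = "numeric",
    sigmas    = "numeric",
    bands     = "list",
    colors    = "character",
    bbox      = "numeric"
  )
)

setValidity("TimelineSet", function(object) {
  msg <- character()
  k <- length(object@levels)
  if (length(object@isocurves) != k) msg <- c(msg, "one isocurve set per level")
  if (length(object@variances) != k) msg <- c(msg, "one variance per level")
  if (any(object@variances < 0, na.rm = TRUE)) msg <- c(msg, "variances must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Bootstrap replicate medians and validity indicator
#'
#' Holds the with-replacement resample index lists, the geometric-median
#' coefficient vector of every replicate ensemble (rows of \code{medians}),
#' and - once rendered - the outline polygon(s) and area of the validity
#' indicator: the spatial interquartile zone of the replicate median curves.
#'
#' @slot B integer, number of bootstrap iterations
#' @slot seed integer seed that generated the index draws
#' @slot indices list of integer vectors, one with-replacement draw per iteration
#' @slot medians numeric matrix, B rows in \eqn{R^{2n}}
#' @slot outline list of polygon matrices (columns x, y), may be empty
#' @slot area numeric, indicator area in square pixels
#' @seealso [bootstrapMedians()], [validityIndicator()]
#' @export
setClass("BootstrapRun",
  representation(
    B       = "integer",
    seed    = "integer",
    indices = "list",
    medians = "matrix",
    outline = "list",
    area    = "numeric"
  )
)

setValidity("BootstrapRun", function(object) {
  msg <- character()
  if (object@B < 1L) msg <- c(msg, "B must be >= 1")
  if (nrow(object@medians) != object@B)
    msg <- c(msg, "one median vector per iteration required")
  if (length(object@indices) != object@B)
    msg <- c(msg, "one index draw per iteration required")
  if (length(object@area) == 1L && !is.na(object@area) && object@area < 0)
    msg <- c(msg, "area must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Declarative figure description
#'
#' A figure is an ordered list of layers (bands, curve strokes, time-lines,
#' indicator outline, ruler) over a world-coordinate bounding box, plus the
#' pixel size of the output. Layer order encodes z-order: zones below
#' time-lines below member curves below representative curves below the
#' indicator below the ruler.
#'
#' @slot layers list of layer descriptions (see [composeBoxplotFigure()])
#' @slot bbox numeric length-4 (xmin, xmax, ymin, ymax) in world pixels
#' @slot width,height integer output size in pixels
#' @slot dpi numeric, scan resolution used for the mm ruler
#' @slot background character hex color
#' @seealso [exportFigure()]
#' @export
setClass("FigureSpec",
  representation(
    layers     = "list",
    bbox       = "numeric",
    width      = "integer",
    height     = "integer",
    dpi        = "numeric",
    background = "character"
  )
)

#' Expert survey score table
#'
#' Ratings of a two-way method comparison by domain experts, one row per
#' expert and one column per assessed ensemble. Scores live on the
#' five-point preference scale -2..2 (0 = no difference); 1..5 ratings are
#' converted on entry by subtracting 3.
#'
#' @slot scores integer matrix (experts x ensembles), values in -2..2
#' @slot ensembleSizes integer, number of curves in each assessed ensemble
#' @seealso [surveyTable()], [ensemblePreferenceMeans()]
#' @export
setClass("SurveyTable",
  representation(
    scores        = "matrix",
    ensembleSizes = "integer"
  )
)

setValidity("SurveyTable", function(object) {
  msg <- character()
  if (any(object@scores < -2L | object@scores > 2L))
    msg <- c(msg, "scores must lie in -2..2")
  if (length(object@ensembleSizes) != ncol(object@scores))
    msg <- c(msg, "one ensemble size per column required")
  if (length(msg)) msg else TRUE
})
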