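# B-spline primitives: construction, evaluation, knot placement, LSQ fit.
# All curves are clamped non-uniform B-splines, order 4 (cubic) by default.

.DEFAULT_ORDER <- 4L

#' Construct a B-spline curve
#'
#' @param knots non-decreasing clamped knot vector
#' @param controlPoints numeric matrix (or 2-column data.frame) of x, y
#' @param order spline order (degree + 1); the package uses 4 throughout
#' @param rootId,genotype optional labels
#' @param dpi optional scan resolution (dots per inch)
#' @return a \linkS4class{BSplineCurve}
#' @examples
#' bez <- BSplineCurve(c(0, 0, 0, 0, 1, 1, 1, 1),
#'                     cbind(x = c(0, 1, 2, 3), y = c(0, 2, 2, 0)))
#' evalCurve(bez, c(0, 0.5, 1))
#' @export
BSplineCurve <- function(knots, controlPoints, order = 4L,
                         rootId = "", genotype = "", dpi = NA_real_) {
  cp <- as.matrix(controlPoints)
  storage.mode(cp) <- "double"
  colnames(cp) <- c("x", "y")
  new("BSplineCurve", order = as.integer(order), knots = as.numeric(knots),
      controlPoints = cp, rootId = as.character(rootId),
      genotype = as.character(genotype), dpi = as.numeric(dpi))
}

#' @rdname BSplineCurve-class
#' @export
setMethod("curveOrder", "BSplineCurve", function(x) x@order)

#' @rdname BSplineCurve-class
#' @export
setMethod("curveKnots", "BSplineCurve", function(x) x@knots)

#' @rdname BSplineCurve-class
#' @export
setMethod("controlPoints", "BSplineCurve", function(x) x@controlPoints)

#' @rdname BSplineCurve-class
#' @export
setMethod("curveDomain", "BSplineCurve", function(x) {
  k <- x@knots
  c(k[x@order], k[length(k) - x@order + 1L])
})

#' @rdname PixelTrace-class
#' @export
setMethod("rootId", "BSplineCurve", function(x) x@rootId)

#' @rdname PixelTrace-class
#' @export
setMethod("genotype", "BSplineCurve", function(x) x@genotype)

setMethod("show", "BSplineCurve", function(object) {
  dom <- curveDomain(object)
  cat(sprintf(
    "BSplineCurve: order %d, %d control points, domain [%g, %g]%s\n",
    object@order, nrow(object@controlPoints), dom[1L], dom[2L],
    if (nzchar(object@rootId)) paste0(", root '", object@rootId, "'") else ""))
})

# Basis design matrix for parameters u on the knot vector; u is clamped to
# the domain ends to absorb floating-point drift at the boundaries.
.basisMatrix <- function(knots, order, u) {
  a <- knots[order]
  b <- knots[length(knots) - order + 1L]
  u <- pmin(pmax(u, a), b)
  splines::splineDesign(knots, u, ord = order)
}

#' @rdname evalCurve
#' @examples
#' crv <- BSplineCurve(c(0, 0, 0, 0, 1, 1, 1, 1),
#'                     cbind(x = 0:3, y = c(0, 1, 1, 0)))
#' evalCurve(crv, 0.5)
#' @export
setMethod("evalCurve", "BSplineCurve", function(x, t) {
  dom <- curveDomain(x)
  if (any(t < dom[1L] - 1e-9) || any(t > dom[2L] + 1e-9))
    stop("parameter t outside the curve domain [", dom[1L], ", ", dom[2L], "]")
  pts <- .basisMatrix(x@knots, x@order, t) %*% x@controlPoints
  colnames(pts) <- c("x", "y")
  pts
})

#' Polyline arc length of a curve
#'
#' Numeric approximation by dense uniform evaluation.
#'
#' @param curve a \linkS4class{BSplineCurve}
#' @param nEval number of evaluation points
#' @return arc length in curve units (pixels)
#' @export
arcLength <- function(curve, nEval = 512L) {
  dom <- curveDomain(curve)
  p <- evalCurve(curve, seq(dom[1L], dom[2L], length.out = nEval))
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Number of control points for a sample count
#'
#' Spectral arguments bound the number of control points needed to
#' represent \code{nSamples} samples over a unit domain from below by
#' \code{nSamples / (4 * pi)}; the fit uses 1.2 times that bound (ceiling),
#' floored at the spline order so a basis always exists. Staying close to
#' the bound smooths segmentation noise without over-fitting.
#'
#' @param nSamples number of parameterized pixel samples
#' @param multiplier safety factor above the lower bound (default 1.2)
#' @param order spline order
#' @return integer number of control points
#' @examples
#' chooseNumControlPoints(500)  # 48
#' @export
chooseNumControlPoints <- function(nSamples, multiplier = 1.2, order = 4L) {
  if (nSamples < order)
    stop("need at least `order` (", order, ") samples, got ", nSamples)
  max(as.integer(order), as.integer(ceiling(multiplier * nSamples / (4 * pi))))
}

#' Knot placement from sample parameters
#'
#' Places a clamped knot vector of length \code{nCp + order} so that curve
#' segments hold approximately equal numbers of sample parameters (de
#' Boor-style averaging). When \code{nCp} equals the number of parameters
#' the classic interpolation averaging is used; otherwise interior knots are
#' parameter quantile averages, which keeps the Schoenberg-Whitney
#' feasibility condition for the given parameters.
#'
#' @param params sorted sample parameters (typically in [0, 1])
#' @param nCp number of control points
#' @param order spline order
#' @return clamped knot vector of length \code{nCp + order}
#' @export
selectKnotsDeBoor <- function(params, nCp, order = 4L) {
  m <- length(params)
  if (m < nCp) stop("need at least nCp (", nCp, ") parameters, got ", m)
  if (is.unsorted(params)) stop("params must be sorted")
  a <- params[1L]
  b <- params[m]
  nInterior <- nCp - order
  interior <- numeric(0)
  if (nInterior > 0L) {
    if (nCp == m) {
      # interpolation: average runs of order-1 consecutive parameters
      interior <- vapply(seq_len(nInterior), function(j)
        mean(params[(j + 1L):(j + order - 2L + 1L)]), numeric(1))
    } else {
      # approximation: quantile positions so segments share samples evenly
      d <- m / (nCp - order + 1L)
      interior <- vapply(seq_len(nInterior), function(j) {
        pos <- j * d
        i <- floor(pos)
        alpha <- pos - i
        (1 - alpha) * params[i] + alpha * params[i + 1L]
      }, numeric(1))
    }
  }
  c(rep(a, order), interior, rep(b, order))
}

#' Least-squares B-spline fit
#'
#' Finds the control points minimizing the summed squared residuals of the
#' parameterized samples on the given basis, per coordinate.
#'
#' @param u sample parameters
#' @param points numeric matrix of sample coordinates (columns x, y)
#' @param knots clamped knot vector
#' @param order spline order
#' @param rootId,genotype,dpi labels carried into the result
#' @return a \linkS4class{BSplineCurve} over the knot domain
#' @export
fitBSpline <- function(u, points, knots, order = 4L,
                       rootId = "", genotype = "", dpi = NA_real_) {
  points <- as.matrix(points)
  nCp <- length(knots) - order
  if (length(u) < nCp)
    stop("need at least as many samples (", length(u), ") as control points (",
         nCp, ")")
  B <- .basisMatrix(knots, order, u)
  qrB <- qr(B)
  if (qrB$rank < nCp)
    stop("rank-deficient design matrix: knot placement leaves empty segments")
  cp <- qr.coef(qrB, points)
  BSplineCurve(knots, cp, order = order, rootId = rootId,
               genotype = genotype, dpi = dpi)
}

#' Rescale the parameter domain to days
#'
#' Affinely maps the knot vector from \code{[0, 1]} (or any domain starting
#' at 0) to \code{[0, d]}, leaving the geometry untouched:
#' \code{C_new(d * t) = C_old(t)}. The parameter then reads as time in days,
#' accurate at daily resolution.
#'
#' @param curve a \linkS4class{BSplineCurve} over \code{[0, 1]}
#' @param d acquisition day (> 0)
#' @return the same curve over \code{[0, d]}
#' @export
reparameterizeToDays <- function(curve, d) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("d must be a single positive number")
  BSplineCurve(curve@knots * d, curve@controlPoints, order = curve@order,
               rootId = curve@rootId, genotype = curve@genotype,
               dpi = curve@dpi)
}
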