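#' @rdname BSplineCurve-class
#' @param object,x an object
#' @export
setGeneric("curveOrder", function(x) standardGeneric("curveOrder"))

#' @rdname BSplineCurve-class
#' @export
setGeneric("curveKnots", function(x) standardGeneric("curveKnots"))

#' @rdname BSplineCurve-class
#' @export
setGeneric("controlPoints", function(x) standardGeneric("controlPoints"))

#' @rdname BSplineCurve-class
#' @export
setGeneric("curveDomain", function(x) standardGeneric("curveDomain"))

#' @rdname PixelTrace-class
#' @export
setGeneric("rootId", function(x) standardGeneric("rootId"))

#' @rdname PixelTrace-class
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' Evaluate a curve at parameter values
#'
#' @param x a \linkS4class{BSplineCurve}
#' @param t numeric parameter values inside the curve domain
#' @return numeric matrix with columns \code{x}, \code{y}, one row per t
#' @export
setGeneric("evalCurve", function(x, t) standardGeneric("evalCurve"))

#' @rdname CommonBasisEnsemble-class
#' @export
setGeneric("coeffMatrix", function(x) standardGeneric("coeffMatrix"))

#' @rdname CommonBasisEnsemble-class
#' @export
setGeneric("nCurves", function(x) standardGeneric("nCurves"))

#' @rdname CommonBasisEnsemble-class
#' @export
setGeneric("curveLabels", function(x) standardGeneric("curveLabels"))

#' @rdname DepthReport-class
#' @export
setGeneric("depths", function(x) standardGeneric("depths"))

#' @rdname DepthReport-class
#' @export
setGeneric("zones", function(x) standardGeneric("zones"))

#' @rdname DepthReport-class
#' @export
setGeneric("deepestIndex", function(x) standardGeneric("deepestIndex"))

#' @rdname DepthReport-class
#' @export
setGeneric("medianCurve", function(x) standardGeneric("medianCurve"))

#' @rdname BootstrapRun-class
#' @export
setGeneric("medianVectors", function(x) standardGeneric("medianVectors"))

#' @rdname BootstrapRun-class
#' @export
setGeneric("indicatorOutline", function(x) standardGeneric("indicatorOutline"))

#' @rdname BootstrapRun-class
#' @export
setGeneric("indicatorArea", function(x) standardGeneric("indicatorArea"))
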