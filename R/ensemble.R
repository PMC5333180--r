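# Common-basis representation of a curve ensemble. Individually fitted
# curves live on different knot vectors; to compare them they are refit
# onto one shared clamped basis and flattened to coefficient vectors in
# R^(2n), on which Euclidean statistics (depth, medians) operate.

#' Build a common B-spline basis for an ensemble
#'
#' The shared basis uses the maximal member control-point count as \code{n}
#' and picks knots from the pool of all member knots: the pools are merged,
#' sorted, deduplicated (after rounding to 12 decimals) and restricted to
#' the common parameter domain \code{[0, min d]}. If the deduplicated pool
#' offers exactly the needed number of interior knots they are used as-is
#' (so an ensemble already sharing one basis keeps it); otherwise interior
#' knots are quantiles of the pool, falling back to uniform spacing when
#' the pool is too small.
#'
#' @param curves list of \linkS4class{BSplineCurve}
#' @return list with elements \code{order}, \code{knots}, \code{n},
#'   \code{domain}
#' @export
buildCommonBasis <- function(curves) {
  if (length(curves) < 1L) stop("empty ensemble")
  order <- curves[[1L]]@order
  doms <- vapply(curves, curveDomain, numeric(2))
  lo <- max(doms[1L, ])
  hi <- min(doms[2L, ])
  if (hi <= lo) stop("curve domains do not overlap")
  if (any(doms[2L, ] > hi + 1e-12))
    warning("differing day domains: refitting over the intersection [",
            signif(lo, 4), ", ", signif(hi, 4), "]")
  n <- max(vapply(curves, function(cu) nrow(cu@controlPoints), integer(1)))
  pool <- sort(unique(round(unlist(lapply(curves, curveKnots)), 12L)))
  pool <- pool[pool > lo + 1e-12 & pool < hi - 1e-12]
  nInterior <- n - order
  interior <- numeric(0)
  if (nInterior > 0L) {
    if (length(pool) == nInterior) {
      interior <- pool
    } else if (length(pool) >= 2L) {
      interior <- as.numeric(stats::quantile(
        pool, probs = seq_len(nInterior) / (nInterior + 1), names = FALSE))
    } else {
      interior <- lo + (hi - lo) * seq_len(nInterior) / (nInterior + 1)
    }
    if (anyDuplicated(interior) || is.unsorted(interior))
      interior <- lo + (hi - lo) * seq_len(nInterior) / (nInterior + 1)
  }
  list(order = order,
       knots = c(rep(lo, order), interior, rep(hi, order)),
       n = as.integer(n),
       domain = c(lo, hi))
}

#' Refit a curve onto a common basis
#'
#' The curve is evaluated at \code{nEval} uniform probe parameters in the
#' basis domain and refit by least squares on the shared knot vector. The
#' result is returned as the concatenated coefficient vector
#' \eqn{x = (cx_1..cx_n, cy_1..cy_n) \in R^{2n}}.
#'
#' @param curve a \linkS4class{BSplineCurve}
#' @param basis result of [buildCommonBasis()]
#' @param nEval number of probe parameters; default \code{max(128, 4n)}
#' @return numeric vector of length \code{2n}
#' @export
refitToBasis <- function(curve, basis, nEval = NULL) {
  n <- basis$n
  if (is.null(nEval)) nEval <- max(128L, 4L * n)
  if (nEval < n)
    stop("nEval (", nEval, ") must be at least the basis size n (", n, ")")
  u <- seq(basis$domain[1L], basis$domain[2L], length.out = nEval)
  pts <- evalCurve(curve, u)
  refit <- fitBSpline(u, pts, basis$knots, order = basis$order)
  cp <- refit@controlPoints
  c(cp[, 1L], cp[, 2L])
}

#' Rebuild a curve from a coefficient vector
#'
#' Inverse of the coefficient concatenation of [refitToBasis()].
#'
#' @param x numeric vector of length \code{2n}
#' @param basis result of [buildCommonBasis()], or a
#'   \linkS4class{CommonBasisEnsemble}
#' @param rootId optional label
#' @return a \linkS4class{BSplineCurve} on the shared basis
#' @export
vectorToCurve <- function(x, basis, rootId = "") {
  if (is(basis, "CommonBasisEnsemble"))
    basis <- list(order = basis@order, knots = basis@knots, n = basis@n)
  n <- basis$n
  if (length(x) != 2L * n)
    stop("coefficient vector must have length 2n = ", 2L * n,
         ", got ", length(x))
  BSplineCurve(basis$knots, cbind(x = x[seq_len(n)], y = x[n + seq_len(n)]),
               order = basis$order, rootId = rootId)
}

#' Assemble a common-basis ensemble
#'
#' Builds the shared basis and refits every member curve, stacking the
#' coefficient vectors as rows.
#'
#' @param curves list of \linkS4class{BSplineCurve}
#' @param nEval probe parameters per refit (see [refitToBasis()])
#' @return a \linkS4class{CommonBasisEnsemble}
#' @export
commonBasisEnsemble <- function(curves, nEval = NULL) {
  basis <- buildCommonBasis(curves)
  rows <- t(vapply(curves, refitToBasis, numeric(2L * basis$n),
                   basis = basis, nEval = nEval))
  labels <- vapply(curves, rootId, character(1))
  blank <- !nzchar(labels)
  labels[blank] <- paste0("curve", which(blank))
  dpis <- vapply(curves, function(cu) cu@dpi, numeric(1))
  dpi <- if (all(is.na(dpis))) NA_real_ else stats::median(dpis, na.rm = TRUE)
  new("CommonBasisEnsemble", order = basis$order, knots = basis$knots,
      n = basis$n, coeffMatrix = rows, labels = labels, dpi = dpi)
}

#' @rdname CommonBasisEnsemble-class
#' @export
setMethod("coeffMatrix", "CommonBasisEnsemble", function(x) x@coeffMatrix)

#' @rdname CommonBasisEnsemble-class
#' @export
setMethod("nCurves", "CommonBasisEnsemble", function(x) nrow(x@coeffMatrix))

#' @rdname CommonBasisEnsemble-class
#' @export
setMethod("curveLabels", "CommonBasisEnsemble", function(x) x@labels)

#' @rdname CommonBasisEnsemble-class
#' @export
setMethod("curveKnots", "CommonBasisEnsemble", function(x) x@knots)

#' @rdname CommonBasisEnsemble-class
#' @export
setMethod("curveOrder", "CommonBasisEnsemble", function(x) x@order)

#' Extract one member as a curve
#'
#' @param x a \linkS4class{CommonBasisEnsemble}
#' @param i row index
#' @return a \linkS4class{BSplineCurve}
#' @export
memberCurve <- function(x, i) {
  vectorToCurve(x@coeffMatrix[i, ], x, rootId = x@labels[i])
}

setMethod("show", "CommonBasisEnsemble", function(object) {
  dom <- range(object@knots)
  cat(sprintf(
    "CommonBasisEnsemble: %d curves, n = %d control points, domain [%g, %g]\n",
    nrow(object@coeffMatrix), object@n, dom[1L], dom[2L]))
})
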