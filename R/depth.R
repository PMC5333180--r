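# L1 data depth, the modified Weiszfeld geometric median, curve box-plot
# zoning and the geometric-median curve. All operations act on point sets
# in R^d; for curve ensembles d = 2n (the common-basis coefficient space).

# squared-distance helper: rows of X to point y
.distTo <- function(X, y) {
  sqrt(rowSums(sweep(X, 2L, y)^2))
}

# directional resultant r(z) (norm of summed unit vectors from z to the
# samples not equal to z) and the coincidence indicator w(z)
.directionalResultant <- function(z, X, eps) {
  d <- .distTo(X, z)
  on <- d <= eps
  w <- as.numeric(any(on))
  Xoff <- X[!on, , drop = FALSE]
  doff <- d[!on]
  if (nrow(Xoff) == 0L) return(list(r = 0, w = w))
  dirsum <- colSums(sweep(Xoff, 2L, z) / doff)
  list(r = sqrt(sum(dirsum^2)), w = w)
}

#' Geometric median by the modified Weiszfeld algorithm
#'
#' Computes the minimizer of \eqn{\sum_i \|y - x_i\|} (the Fermat-Weber
#' point, also called the spatial or multivariate L1 median). Starting from
#' the coordinate mean, the damped fixed-point update
#' \deqn{y_{k+1} = (1 - w/r)^+ \tilde T(y_k) + \min(1, w/r)\, y_k}
#' is iterated, where \eqn{\tilde T} is the distance-weighted mean over the
#' samples distinct from \eqn{y_k}, \eqn{r} is the norm of the summed unit
#' direction vectors toward those samples and \eqn{w} indicates that
#' \eqn{y_k} coincides with a sample. The damping makes the iteration
#' well-defined when an iterate lands exactly on a sample point: if
#' \eqn{r \le w} there, that sample is the median and the iteration stops.
#'
#' @param X numeric matrix, one sample per row
#' @param tol convergence tolerance on the step norm; default
#'   \code{1e-10 * max(1, data range)}
#' @param maxIter iteration cap (default 1000); non-convergence is reported
#'   via a warning and the \code{converged} slot, the last iterate is
#'   returned
#' @return a \linkS4class{MedianEstimate}
#' @examples
#' med <- weiszfeldMedian(rbind(c(0, 0), c(0, 0), c(0, 0), c(10, 0)))
#' med@y  # (0, 0): the tripled point dominates
#' @export
weiszfeldMedian <- function(X, tol = NULL, maxIter = 1000L) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X must hold at least one point")
  scale <- max(1, max(X) - min(X))
  if (is.null(tol)) tol <- 1e-10 * scale
  if (tol <= 0) stop("tol must be > 0")
  eps <- 1e-12 * scale

  y <- colMeans(X)
  it <- 0L
  step <- Inf
  r <- 0
  objPrev <- Inf
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    d <- .distTo(X, y)
    obj <- sum(d)
    # descent is monotone; a machine-precision objective decrease means
    # the iterate has stopped improving even if the step has not shrunk
    # below tol yet (slow crawl toward a minimizer near a sample point)
    if (objPrev - obj <= 1e-14 * max(1, obj) && it > 1L) {
      step <- 0; converged <- TRUE; break
    }
    objPrev <- obj
    on <- d <= eps
    eta <- sum(on)               # multiplicity of the coincident sample
    Xoff <- X[!on, , drop = FALSE]
    doff <- d[!on]
    if (nrow(Xoff) == 0L) {      # all samples coincide with y
      step <- 0; r <- 0; converged <- TRUE; break
    }
    inv <- 1 / doff
    Tt <- colSums(Xoff * inv) / sum(inv)
    dirsum <- colSums(sweep(Xoff, 2L, y) * inv)
    r <- sqrt(sum(dirsum^2))
    if (r <= eps) { step <- 0; converged <- TRUE; break }
    if (eta >= r) {              # optimality condition at a sample point
      step <- 0; converged <- TRUE; break
    }
    yNew <- max(0, 1 - eta / r) * Tt + min(1, eta / r) * y
    step <- sqrt(sum((yNew - y)^2))
    y <- yNew
    if (step < tol) { converged <- TRUE; break }
  }
  # a sample x_k is the exact Fermat-Weber minimizer iff the resultant of
  # the unit directions to the remaining samples does not exceed its
  # multiplicity; the damped iteration approaches such a point without
  # ever landing on it, so check the nearest sample and snap when optimal
  dy <- .distTo(X, y)
  k <- which.min(dy)
  dc <- .distTo(X, X[k, ])
  onC <- dc <= eps
  XoffC <- X[!onC, , drop = FALSE]
  rC <- if (nrow(XoffC) == 0L) 0 else
    sqrt(sum(colSums(sweep(XoffC, 2L, X[k, ]) / dc[!onC])^2))
  if (rC <= sum(onC) && sum(dc) <= sum(dy)) {
    y <- X[k, ]
    step <- 0
    converged <- TRUE
  }
  if (!converged)
    warning("Weiszfeld iteration did not converge in ", maxIter,
            " iterations (last step ", signif(step, 3), ")")
  res <- .directionalResultant(y, X, eps)
  new("MedianEstimate", y = as.numeric(y), iterations = it,
      finalStep = as.numeric(step), rAtSolution = res$r,
      converged = converged)
}

setMethod("show", "MedianEstimate", function(object) {
  cat(sprintf(
    "MedianEstimate in R^%d: %d iterations, final step %.3g, r = %.3g%s\n",
    length(object@y), object@iterations, object@finalStep,
    object@rAtSolution, if (object@converged) "" else " (NOT converged)"))
})

#' L1 data depth of a point
#'
#' \deqn{L_1D(z) = 1 - \max(r(z) - w(z), 0) / n} where \eqn{r(z)} is the
#' norm of the summed unit direction vectors from \eqn{z} to the samples
#' distinct from \eqn{z}, \eqn{w(z)} indicates coincidence with a sample
#' and \eqn{n} is the sample count. The depth lies in (0, 1] and attains 1
#' at the geometric median (where \eqn{r \to 0}) and at samples dominant
#' enough that \eqn{r \le w}. Because only direction vectors enter, depth
#' ordering is invariant under translation, rotation and uniform scaling.
#'
#' @param z numeric query point
#' @param X numeric matrix of samples, one per row
#' @return depth value in (0, 1]
#' @examples
#' X <- cbind(0:4, 0)
#' l1Depth(c(2, 0), X)  # 1: directions cancel
#' l1Depth(c(0, 0), X)  # 0.4: r = 4, w = 1, n = 5
#' @export
l1Depth <- function(z, X) {
  X <- as.matrix(X)
  if (nrow(X) < 1L) stop("X must hold at least one point")
  scale <- max(1, max(X) - min(X))
  res <- .directionalResultant(as.numeric(z), X, 1e-12 * scale)
  1 - max(res$r - res$w, 0) / nrow(X)
}

#' L1 depths of every member of an ensemble
#'
#' Each curve's coefficient vector is scored against the whole ensemble
#' (itself included, entering through the coincidence indicator).
#'
#' @param ens a \linkS4class{CommonBasisEnsemble} or a numeric matrix of
#'   coefficient rows
#' @return numeric vector of depths in (0, 1]
#' @export
ensembleDepths <- function(ens) {
  X <- if (is(ens, "CommonBasisEnsemble")) ens@coeffMatrix else as.matrix(ens)
  vapply(seq_len(nrow(X)), function(i) l1Depth(X[i, ], X), numeric(1))
}

#' Curve box-plot zone labels from depths
#'
#' Curves whose depth reaches the median depth form the interquartile set.
#' The outlier threshold extends Tukey's whisker rule to the depth scale:
#' a curve is an outlier when its depth falls more than
#' \code{tukeyFactor * (max(depths) - median(depths))} below the median
#' depth. Everything between is an inlier. The subtraction direction (below
#' the median) is this package's reading of the whisker convention; it is
#' stated here because other readings are possible.
#'
#' @param depths numeric depth values
#' @param tukeyFactor whisker multiplier (default 3)
#' @return factor with levels interquartile, inlier, outlier
#' @examples
#' classifyZones(c(1, 0.98, 0.96, 0.94, 0.1))
#' @export
classifyZones <- function(depths, tukeyFactor = 3) {
  if (length(depths) < 1L) stop("need at least one depth")
  med <- stats::median(depths)
  thr <- med - tukeyFactor * (max(depths) - med)
  z <- ifelse(depths >= med, "interquartile",
              ifelse(depths < thr, "outlier", "inlier"))
  factor(z, levels = c("interquartile", "inlier", "outlier"))
}

#' Geometric-median curve of an ensemble
#'
#' The Weiszfeld median of the coefficient vectors, rebuilt as a curve on
#' the shared basis. This representative is a virtual curve: it need not
#' coincide with any ensemble member.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble}
#' @param ... passed to [weiszfeldMedian()]
#' @return a \linkS4class{BSplineCurve}
#' @export
geometricMedianCurve <- function(ens, ...) {
  est <- weiszfeldMedian(ens@coeffMatrix, ...)
  vectorToCurve(est@y, ens, rootId = "geometric-median")
}

#' Full depth report for an ensemble
#'
#' Computes member depths, zone labels, the deepest member and the
#' geometric-median curve in one pass.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble}
#' @param tukeyFactor whisker multiplier for the outlier rule
#' @return a \linkS4class{DepthReport}
#' @export
depthReport <- function(ens, tukeyFactor = 3) {
  dep <- ensembleDepths(ens)
  zones <- classifyZones(dep, tukeyFactor = tukeyFactor)
  med <- stats::median(dep)
  thr <- med - tukeyFactor * (max(dep) - med)
  new("DepthReport", depths = dep, zones = zones, medianDepth = med,
      outlierThreshold = thr, tukeyFactor = tukeyFactor,
      deepestIndex = which.max(dep),
      medianCurve = geometricMedianCurve(ens), labels = ens@labels)
}

#' @rdname DepthReport-class
#' @export
setMethod("depths", "DepthReport", function(x) x@depths)

#' @rdname DepthReport-class
#' @export
setMethod("zones", "DepthReport", function(x) x@zones)

#' @rdname DepthReport-class
#' @export
setMethod("deepestIndex", "DepthReport", function(x) x@deepestIndex)

#' @rdname DepthReport-class
#' @export
setMethod("medianCurve", "DepthReport", function(x) x@medianCurve)

setMethod("show", "DepthReport", function(object) {
  tab <- table(object@zones)
  cat(sprintf(
    paste0("DepthReport: %d curves (IQ %d / inlier %d / outlier %d), ",
           "median depth %.3f, deepest '%s'\n"),
    length(object@depths), tab[["interquartile"]], tab[["inlier"]],
    tab[["outlier"]], object@medianDepth,
    object@labels[object@deepestIndex]))
})

#' Export a depth report
#'
#' @param report a \linkS4class{DepthReport}
#' @param path output file
#' @param format "csv" (root_id, depth, zone) or "json"
#' @return the path, invisibly
#' @export
exportDepthReport <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- data.frame(root_id = report@labels, depth = report@depths,
                   zone = as.character(report@zones))
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(curves = df,
           median_depth = report@medianDepth,
           outlier_threshold = report@outlierThreshold,
           tukey_factor = report@tukeyFactor,
           deepest = report@labels[report@deepestIndex]),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}
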