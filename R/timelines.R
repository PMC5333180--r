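# Time-line estimation: a thin-plate-spline scalar field F(x, y) is fitted
# to (position, day) samples harvested from the ensemble curves; its
# isocurves at the day stamps are the time-lines, and the spread of the
# field residuals per stamp gives each time-line a confidence zone.

.tpsKernel <- function(r) {
  phi <- r
  phi[] <- 0
  pos <- r > 0
  phi[pos] <- r[pos]^2 * log(r[pos])
  phi
}

# kernel block of the design matrix: phi_j(p_i) for all samples x centers
.tpsKernelMatrix <- function(pts, centers) {
  d2 <- outer(rowSums(pts^2), rep(1, nrow(centers))) +
        outer(rep(1, nrow(pts)), rowSums(centers^2)) -
        2 * pts %*% t(centers)
  d2[d2 < 0] <- 0
  .tpsKernel(sqrt(d2))
}

# Jacobi-preconditioned conjugate gradients for the (possibly singular but
# consistent) SPD system M x = b. Returns x, iterations, relative residual.
.cgSolve <- function(M, b, tol = 1e-13, maxIter = NULL) {
  nvar <- length(b)
  if (is.null(maxIter)) maxIter <- 10L * nvar
  d <- diag(M)
  d[d <= .Machine$double.eps] <- 1
  x <- numeric(nvar)
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iterations = 0L, relres = 0))
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Mp <- as.numeric(M %*% p)
    pMp <- sum(p * Mp)
    if (pMp <= 0) break                      # numerical null direction
    alpha <- rz / pMp
    x <- x + alpha * p
    r <- r - alpha * Mp
    if (sqrt(sum(r^2)) <= tol * bnorm) break
    z <- r / d
    rzNew <- sum(r * z)
    p <- z + (rzNew / rz) * p
    rz <- rzNew
  }
  list(x = x, iterations = it, relres = sqrt(sum(r^2)) / bnorm)
}

#' Harvest (position, day) samples from an ensemble
#'
#' Every curve covering a time stamp is evaluated there, yielding one
#' planar point with that stamp as its field value. Curves whose domain
#' does not cover a stamp are skipped for it, with a warning.
#'
#' @param curves list of \linkS4class{BSplineCurve} or a
#'   \linkS4class{CommonBasisEnsemble}
#' @param timestamps numeric day values
#' @return data.frame with columns x, y, t, curve (index), one row per
#'   curve per covered stamp
#' @export
sampleTimelinePoints <- function(curves, timestamps) {
  curves <- .asCurveList(curves)
  rows <- list()
  skipped <- 0L
  for (i in seq_along(curves)) {
    dom <- curveDomain(curves[[i]])
    for (tt in timestamps) {
      if (tt < dom[1L] - 1e-9 || tt > dom[2L] + 1e-9) {
        skipped <- skipped + 1L
        next
      }
      p <- evalCurve(curves[[i]], tt)
      rows[[length(rows) + 1L]] <-
        data.frame(x = p[1L, 1L], y = p[1L, 2L], t = tt, curve = i)
    }
  }
  if (skipped > 0L)
    warning(skipped, " (curve, stamp) pair(s) outside the curve domain ",
            "were skipped")
  if (!length(rows))
    stop("no curve covers any of the requested time stamps")
  do.call(rbind, rows)
}

.asCurveList <- function(curves) {
  if (is(curves, "CommonBasisEnsemble"))
    lapply(seq_len(nCurves(curves)), function(i) memberCurve(curves, i))
  else curves
}

#' Fit the thin-plate-spline time field
#'
#' Least-squares fit of \eqn{F(x) = \beta_0 + \beta^T x + \sum_j \alpha_j
#' \|x - c_j\|^2 \log \|x - c_j\|} to the harvested samples. The design
#' matrix has columns \code{[1, x, y, phi_1 .. phi_N]}; the normal
#' equations \eqn{A^T A y = A^T b} - symmetric but badly conditioned
#' because the kernels are not compact - are solved with Jacobi-
#' preconditioned conjugate gradients (iteration cap \code{10 (N + 3)}).
#' Control points of the ensemble curves are the recommended centers:
#' resolution-free, close to the data, and independent of the probe
#' discretization.
#'
#' @param samples data.frame from [sampleTimelinePoints()] (columns x, y, t)
#' @param centers numeric matrix of kernel centers (columns x, y); e.g.
#'   [tpsCentersFromEnsemble()]
#' @param tol conjugate-gradient tolerance on the relative residual
#' @return a \linkS4class{TPSSurface}
#' @export
fitTPS <- function(samples, centers, tol = 1e-13) {
  pts <- cbind(samples$x, samples$y)
  if (nrow(pts) < 3L) stop("need at least 3 samples")
  if (qr(cbind(1, pts))$rank < 3L)
    stop("samples are collinear: the affine part of the field is not ",
         "identifiable")
  centers <- as.matrix(centers)
  if (nrow(centers) < 1L) stop("need at least one center")
  A <- cbind(1, pts, .tpsKernelMatrix(pts, centers))
  b <- samples$t
  M <- crossprod(A)
  rhs <- as.numeric(crossprod(A, b))
  sol <- .cgSolve(M, rhs, tol = tol, maxIter = 10L * (nrow(centers) + 3L))
  if (sol$relres > 1e-4)
    warning("conjugate gradients stopped at relative residual ",
            signif(sol$relres, 3))
  new("TPSSurface", beta0 = sol$x[1L], beta = sol$x[2:3],
      alpha = sol$x[-(1:3)], centers = centers,
      cgIterations = sol$iterations, cgResidual = sol$relres)
}

#' Kernel centers from ensemble control points
#'
#' Dense center sets make the field interpolate the day samples almost
#' exactly, which drives every time-line variance toward zero; thinning
#' the centers trades interpolation accuracy for an honest residual
#' spread and a smaller linear system.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble} or list of curves
#' @param dedupTol centers closer than this are merged (default 1e-6)
#' @param maxCenters keep at most this many centers, uniformly thinned in
#'   order (default Inf: all control points)
#' @return numeric matrix of centers (columns x, y)
#' @export
tpsCentersFromEnsemble <- function(ens, dedupTol = 1e-6, maxCenters = Inf) {
  curves <- .asCurveList(ens)
  cp <- do.call(rbind, lapply(curves, controlPoints))
  ctr <- unique(round(cp / dedupTol)) * dedupTol
  if (nrow(ctr) > maxCenters)
    ctr <- ctr[round(seq(1L, nrow(ctr), length.out = maxCenters)), ,
               drop = FALSE]
  ctr
}

#' Evaluate the TPS time field
#'
#' @param surface a \linkS4class{TPSSurface}
#' @param x numeric point, or matrix of points (columns x, y)
#' @return field value(s)
#' @export
evalTPS <- function(surface, x) {
  pts <- if (is.matrix(x)) x else matrix(x, ncol = 2L)
  out <- numeric(nrow(pts))
  # chunked evaluation keeps the samples-by-centers kernel block small
  chunk <- max(1L, floor(2e6 / max(1L, nrow(surface@centers))))
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    P <- pts[s:e, , drop = FALSE]
    K <- .tpsKernelMatrix(P, surface@centers)
    out[s:e] <- surface@beta0 + P %*% surface@beta + K %*% surface@alpha
  }
  out
}

setMethod("show", "TPSSurface", function(object) {
  cat(sprintf(
    "TPSSurface: %d centers, beta0 = %.4g, beta = (%.4g, %.4g), CG %d it (relres %.2g)\n",
    nrow(object@centers), object@beta0, object@beta[1L], object@beta[2L],
    object@cgIterations, object@cgResidual))
})

#' Extract isocurves of the time field
#'
#' Marching-squares contours of the field sampled on a regular grid over
#' the bounding box. Vertices are within one grid cell of the true level
#' set (exact for affine fields, since the contouring interpolates
#' linearly along cell edges).
#'
#' @param surface a \linkS4class{TPSSurface}
#' @param level field value (day) of the isocurve
#' @param bbox numeric (xmin, xmax, ymin, ymax)
#' @param gridRes grid points per axis (default 256, minimum 2)
#' @return list of polylines, each a matrix with columns x, y (possibly
#'   empty when the level is outside the field range on the box)
#' @export
extractIsocurves <- function(surface, level, bbox, gridRes = 256L) {
  .contourAtLevels(.gridField(surface, bbox, gridRes), level)[[1L]]
}

# sample the field once on the grid; reusable for many levels
.gridField <- function(surface, bbox, gridRes = 256L) {
  if (gridRes < 2L) stop("gridRes must be at least 2")
  gx <- seq(bbox[1L], bbox[2L], length.out = gridRes)
  gy <- seq(bbox[3L], bbox[4L], length.out = gridRes)
  grid <- cbind(rep(gx, times = gridRes), rep(gy, each = gridRes))
  list(gx = gx, gy = gy,
       z = matrix(evalTPS(surface, grid), nrow = gridRes))  # z[ix, iy]
}

.contourAtLevels <- function(field, levels) {
  lapply(levels, function(lv) {
    cl <- grDevices::contourLines(field$gx, field$gy, field$z, levels = lv)
    lapply(cl, function(p) cbind(x = p$x, y = p$y))
  })
}

#' Variance of a time-line
#'
#' Every curve covering day \code{t} is evaluated there and the fitted
#' field is read back at that position; the differences
#' \eqn{F(C_k(t)) - t} measure how far each individual is from the
#' ensemble-typical timing. Their population variance (divide-by-k, about
#' the mean difference) is the time-line's variance.
#'
#' @param curves list of curves or a \linkS4class{CommonBasisEnsemble}
#' @param surface a \linkS4class{TPSSurface}
#' @param t day value
#' @return variance (>= 0); NA with a warning when no curve covers t
#' @export
timelineVariance <- function(curves, surface, t) {
  curves <- .asCurveList(curves)
  res <- c()
  for (cu in curves) {
    dom <- curveDomain(cu)
    if (t < dom[1L] - 1e-9 || t > dom[2L] + 1e-9) next
    p <- evalCurve(cu, t)
    res <- c(res, evalTPS(surface, p) - t)
  }
  if (!length(res)) {
    warning("no curve covers t = ", t, "; variance undefined")
    return(NA_real_)
  }
  mean((res - mean(res))^2)
}

#' Build the full time-line set
#'
#' Fits nothing itself: takes an already fitted surface, extracts the
#' isocurve of every stamp, computes per-stamp variances and assigns a
#' blue colormap in which earlier stamps are brighter.
#'
#' @param curves ensemble curves (list or \linkS4class{CommonBasisEnsemble})
#' @param surface fitted \linkS4class{TPSSurface}
#' @param timestamps day values
#' @param bbox bounding box (xmin, xmax, ymin, ymax); default: ensemble
#'   control-point box padded 5 percent
#' @param gridRes contouring grid resolution (default 256)
#' @return a \linkS4class{TimelineSet}
#' @export
buildTimelines <- function(curves, surface, timestamps, bbox = NULL,
                           gridRes = 256L) {
  curveList <- .asCurveList(curves)
  if (is.null(bbox)) {
    cp <- do.call(rbind, lapply(curveList, controlPoints))
    rx <- range(cp[, 1L]); ry <- range(cp[, 2L])
    padx <- 0.05 * max(diff(rx), 1); pady <- 0.05 * max(diff(ry), 1)
    bbox <- c(rx[1L] - padx, rx[2L] + padx, ry[1L] - pady, ry[2L] + pady)
  }
  field <- .gridField(surface, bbox, gridRes)   # one grid pass for all levels
  iso <- .contourAtLevels(field, timestamps)
  va <- vapply(timestamps, function(tt)
    timelineVariance(curveList, surface, tt), numeric(1))
  sig <- sqrt(pmax(va, 0))
  # confidence strip between the t - s and t + s isocurves, in nested
  # sub-bands so alpha can decay linearly toward the border when drawn
  bands <- lapply(seq_along(timestamps), function(i) {
    s <- sig[i]
    if (!is.finite(s) || s <= 0) return(list())
    out <- list()
    for (frac in c(1, 2 / 3, 1 / 3)) {
      lohi <- .contourAtLevels(field, timestamps[i] + c(-1, 1) * frac * s)
      if (!length(lohi[[1L]]) || !length(lohi[[2L]])) next
      pick <- function(ps) ps[[which.max(vapply(ps, nrow, integer(1)))]]
      a <- pick(lohi[[1L]]); b <- pick(lohi[[2L]])
      out[[length(out) + 1L]] <- rbind(a, b[rev(seq_len(nrow(b))), ])
    }
    out
  })
  new("TimelineSet", levels = as.numeric(timestamps), isocurves = iso,
      variances = va, sigmas = sig, bands = bands,
      colors = timelineColors(length(timestamps)), bbox = as.numeric(bbox))
}

#' Blue colormap for time-lines
#'
#' Monotone ramp from bright to dark blue; earlier stamps get the brighter
#' (higher-luminance) colors.
#'
#' @param k number of colors
#' @return character vector of hex colors
#' @export
timelineColors <- function(k) {
  grDevices::colorRampPalette(c("#BFDFFF", "#084594"))(max(k, 1L))[seq_len(k)]
}

setMethod("show", "TimelineSet", function(object) {
  cat(sprintf("TimelineSet: %d time-lines at days %s; sigma in [%.3g, %.3g]\n",
              length(object@levels),
              paste(signif(object@levels, 3), collapse = ", "),
              min(object@sigmas), max(object@sigmas)))
})
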