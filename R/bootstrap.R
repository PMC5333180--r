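# Bootstrap validity indicator: resample the ensemble with replacement,
# compute the geometric-median curve of every replicate, and render the
# interquartile zone of those replicate medians as a spatial confidence
# region for the representative curve.

# run fn with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
.withSeed <- function(seed, fn) {
  hasSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hasSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hasSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Bootstrap replicate medians of an ensemble
#'
#' Draws \code{B} with-replacement resamples of the ensemble rows (indices
#' need not be distinct nor cover every member), computes the Weiszfeld
#' geometric median of each replicate in coefficient space, and collects
#' the \code{B} median vectors. One seeded generator drives all index
#' draws, advancing sequentially across iterations, so a given seed always
#' reproduces the same replicate set.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble}
#' @param B number of bootstrap iterations (default 300, past which the
#'   indicator shape is empirically stable for ensembles of 15-20 roots)
#' @param seed integer seed
#' @return a \linkS4class{BootstrapRun} (outline and area unset)
#' @export
bootstrapMedians <- function(ens, B = 300L, seed = 1L) {
  X <- ens@coeffMatrix
  m <- nrow(X)
  if (B < 1L) stop("B must be >= 1")
  idx <- .withSeed(seed, function()
    lapply(seq_len(B), function(i) sample.int(m, m, replace = TRUE)))
  # replicate medians feed a raster with cells of a pixel or more; a 1e-6
  # relative tolerance is far below that while avoiding the slow tail of
  # the iteration when a replicate median sits next to a sample point
  tolRep <- 1e-6 * max(1, max(X) - min(X))
  med <- t(vapply(idx, function(ii)
    weiszfeldMedian(X[ii, , drop = FALSE], tol = tolRep)@y,
    numeric(ncol(X))))
  new("BootstrapRun", B = as.integer(B), seed = as.integer(seed),
      indices = idx, medians = med, outline = list(), area = NA_real_)
}

#' @rdname BootstrapRun-class
#' @export
setMethod("medianVectors", "BootstrapRun", function(x) x@medians)

#' @rdname BootstrapRun-class
#' @export
setMethod("indicatorOutline", "BootstrapRun", function(x) x@outline)

#' @rdname BootstrapRun-class
#' @export
setMethod("indicatorArea", "BootstrapRun", function(x) x@area)

setMethod("show", "BootstrapRun", function(object) {
  cat(sprintf("BootstrapRun: B = %d (seed %d)%s\n", object@B, object@seed,
              if (is.na(object@area)) ""
              else sprintf(", indicator area %.1f px^2", object@area)))
})

#' Validity indicator of the median estimate
#'
#' Scores the replicate medians with L1 depth, keeps the interquartile
#' subset (depth at least the median depth), rebuilds those vectors as
#' curves and renders the union of their strokes: curves are rasterized at
#' \code{probeCount} parameters, dilated by the stroke radius,
#' morphologically closed, hole-filled, and the outer contour extracted.
#' A tight indicator means the median curve is stable under resampling; its
#' area grows as the ensemble shrinks.
#'
#' @param run a \linkS4class{BootstrapRun} from [bootstrapMedians()]
#' @param ens the \linkS4class{CommonBasisEnsemble} the run was drawn from
#'   (supplies the basis)
#' @param probeCount curve probe parameters for rasterization (default 256)
#' @param strokeRadius stroke half-width in pixels (default 2)
#' @param gridCells raster cells along the larger box side (default 400)
#' @return the run with \code{outline} (list of polygons, world
#'   coordinates) and \code{area} (px^2) filled in
#' @export
validityIndicator <- function(run, ens, probeCount = 256L, strokeRadius = 2,
                              gridCells = 400L) {
  if (run@B < 4L) stop("need at least B = 4 replicate medians")
  dep <- ensembleDepths(run@medians)
  iq <- which(dep >= stats::median(dep))
  curves <- lapply(iq, function(i)
    vectorToCurve(run@medians[i, ], ens, rootId = paste0("bootstrap", i)))
  info <- .curveUnionMask(curves, probeCount = probeCount,
                          strokeRadius = strokeRadius,
                          gridCells = gridCells)
  area <- sum(info$mask) * info$cell^2
  outline <- .maskOutline(info)
  if (!length(outline)) {       # degenerate: fall back to the stroke itself
    dom <- curveDomain(curves[[1L]])
    outline <- list(evalCurve(curves[[1L]],
                              seq(dom[1L], dom[2L], length.out = probeCount)))
  }
  initialize(run, outline = outline, area = area)
}

#' Indicator area in square millimetres
#'
#' @param run a rendered \linkS4class{BootstrapRun}
#' @param dpi scan resolution
#' @return area in mm^2
#' @export
indicatorAreaMm2 <- function(run, dpi) {
  pixelsToMm(pixelsToMm(run@area, dpi), dpi)
}

#' Export the indicator outline
#'
#' @param run a rendered \linkS4class{BootstrapRun}
#' @param path output file
#' @param format "csv" (polygon, vertex, x, y) or "svg" (one path per
#'   polygon)
#' @return the path, invisibly
#' @export
exportIndicator <- function(run, path, format = c("csv", "svg")) {
  format <- match.arg(format)
  if (!length(run@outline)) stop("indicator has not been rendered yet")
  if (format == "csv") {
    df <- do.call(rbind, lapply(seq_along(run@outline), function(i) {
      p <- run@outline[[i]]
      data.frame(polygon = i, vertex = seq_len(nrow(p)),
                 x = p[, 1L], y = p[, 2L])
    }))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    paths <- vapply(run@outline, function(p) sprintf(
      '  <path d="%s Z" fill="none" stroke="#D95F02" stroke-width="1.5"/>',
      paste0("M ", paste(sprintf("%.3f %.3f", p[, 1L], p[, 2L]),
                         collapse = " L "))), character(1))
    xr <- range(unlist(lapply(run@outline, function(p) p[, 1L])))
    yr <- range(unlist(lapply(run@outline, function(p) p[, 2L])))
    writeLines(c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%.3f %.3f %.3f %.3f">',
      xr[1L] - 5, yr[1L] - 5, diff(xr) + 10, diff(yr) + 10),
      paths, "</svg>"), path)
  }
  invisible(path)
}
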