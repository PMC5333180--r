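# Synthetic root-ensemble generator with known ground truth. Emulates
# near-vertical seedling roots growing over several days: per-individual
# growth speed and tilt angle draws around a common center trajectory,
# plus smooth lateral wiggle and sample-level noise. Defaults approximate
# early-stage seedlings scanned at 1200 dpi: at that resolution 1 mm is
# about 47 px, so a base speed of 120 px/day corresponds to roughly
# 2.5 mm of daily growth.

#' Generate a synthetic root ensemble
#'
#' Each individual k grows downward from the origin with a constant speed
#' drawn from \code{Normal(baseSpeed, speedSd)} (truncated at 10 percent of
#' the base speed), tilted from vertical by an angle drawn from
#' \code{Normal(0, angleSd)}, and displaced laterally by a smooth
#' low-frequency wiggle (sum of three random sinusoids with amplitude ~
#' \code{wiggleAmp}). Trajectories are sampled densely over \code{[0,
#' days]}, perturbed with isotropic Gaussian noise of \code{noiseSd}
#' pixels, and fitted as order-4 B-splines with the control-point rule of
#' the reconstruction pipeline. The unperturbed vertical center trajectory
#' is returned alongside as ground truth. Draws are deterministic per seed.
#'
#' @param m ensemble size
#' @param days time span (domain becomes [0, days])
#' @param baseSpeed,speedSd growth speed mean and SD, px/day
#' @param angleSd tilt SD from vertical, radians
#' @param wiggleAmp lateral wiggle amplitude, px
#' @param noiseSd sample jitter SD, px
#' @param dpi nominal scan resolution carried on the curves
#' @param seed integer seed
#' @param origin (x, y) of the seed position on the virtual plate; the
#'   default keeps every coordinate positive, as in a scanned image
#' @param nSample trajectory samples per curve before fitting
#' @return list with \code{curves} (list of \linkS4class{BSplineCurve}),
#'   \code{center} (the ground-truth center \linkS4class{BSplineCurve}) and
#'   \code{fitRms} (per-curve RMS of the sample-to-fit residual, px)
#' @examples
#' gen <- generateEnsemble(m = 5, seed = 42)
#' length(gen$curves)
#' @export
generateEnsemble <- function(m = 20L, days = 5, baseSpeed = 120,
                             speedSd = 25, angleSd = 0.08, wiggleAmp = 4,
                             noiseSd = 1, dpi = 1200, seed = 1L,
                             origin = c(400, 50), nSample = 60L) {
  stopifnot(m >= 1L, days > 0, baseSpeed > 0, speedSd >= 0, angleSd >= 0,
            wiggleAmp >= 0, noiseSd >= 0)
  .withSeed(seed, function() {
    tt <- seq(0, days, length.out = nSample)
    u <- tt / days
    fitOne <- function(x, y, id) {
      nCp <- chooseNumControlPoints(nSample)
      knots <- selectKnotsDeBoor(u, nCp)
      crv <- fitBSpline(u, cbind(x = x, y = y), knots, rootId = id,
                        genotype = "synthetic", dpi = dpi)
      rms <- sqrt(mean((evalCurve(crv, u) - cbind(x, y))^2))
      list(curve = reparameterizeToDays(crv, days), rms = rms)
    }
    curves <- lapply(seq_len(m), function(k) {
      speed <- max(stats::rnorm(1, baseSpeed, speedSd), 0.1 * baseSpeed)
      angle <- stats::rnorm(1, 0, angleSd)
      amp <- stats::rnorm(3L, 0, wiggleAmp / (1:3))
      phase <- stats::runif(3L, 0, 2 * pi)
      depth <- speed * tt
      wig <- amp[1L] * sin(pi * tt / days + phase[1L]) -
             amp[1L] * sin(phase[1L])            # wiggle vanishes at t = 0
      wig <- wig + amp[2L] * (sin(2 * pi * tt / days + phase[2L]) -
                              sin(phase[2L]))
      wig <- wig + amp[3L] * (sin(3 * pi * tt / days + phase[3L]) -
                              sin(phase[3L]))
      x <- origin[1L] + sin(angle) * depth + wig +
           stats::rnorm(nSample, 0, noiseSd)
      y <- origin[2L] + cos(angle) * depth + stats::rnorm(nSample, 0, noiseSd)
      fitOne(x, y, sprintf("synthetic%03d", k))
    })
    center <- fitOne(rep(origin[1L], nSample), origin[2L] + baseSpeed * tt,
                     "center")
    list(curves = lapply(curves, `[[`, "curve"),
         center = center$curve,
         fitRms = vapply(curves, `[[`, numeric(1), "rms"))
  })
}

#' Rasterize a curve to a pixel trace
#'
#' Inverse of reconstruction, for end-to-end testing: the curve is
#' evaluated densely, consecutive points are joined with 8-connected
#' Bresenham chains, duplicates are removed in path order, and the first
#' point becomes the start pixel. Negative coordinates are shifted into
#' the image quadrant before rounding.
#'
#' @param curve a \linkS4class{BSplineCurve}
#' @param dpi recorded scan resolution (default: the curve's)
#' @param day recorded acquisition day (default: the curve domain end)
#' @param nEval dense evaluation count before chaining
#' @return a \linkS4class{PixelTrace}
#' @export
rasterizeToTrace <- function(curve, dpi = NULL, day = NULL, nEval = 2048L) {
  dom <- curveDomain(curve)
  if (is.null(day)) day <- dom[2L]
  if (is.null(dpi)) dpi <- if (is.na(curve@dpi)) 1200 else curve@dpi
  p <- evalCurve(curve, seq(dom[1L], dom[2L], length.out = nEval))
  shift <- pmin(floor(apply(p, 2L, min)), 0)
  if (any(shift < 0))
    warning("curve has negative coordinates; trace is translated by (",
            -shift[1L], ", ", -shift[2L], ") px into the image quadrant")
  xi <- round(p[, 1L] - shift[1L])
  yi <- round(p[, 2L] - shift[2L])
  chain <- list()
  cur <- c(xi[1L], yi[1L])
  chain[[1L]] <- matrix(cur, 1L)
  for (i in 2L:nEval) {
    nxt <- c(xi[i], yi[i])
    if (all(nxt == cur)) next
    seg <- .bresenham(cur[1L], cur[2L], nxt[1L], nxt[2L])
    chain[[length(chain) + 1L]] <- seg[-1L, , drop = FALSE]
    cur <- nxt
  }
  xy <- do.call(rbind, chain)
  keep <- !duplicated(xy)
  xy <- xy[keep, , drop = FALSE]
  PixelTrace(cbind(row = xy[, 2L], col = xy[, 1L]),
             start = c(xy[1L, 2L], xy[1L, 1L]), day = day, dpi = dpi,
             rootId = curve@rootId, genotype = curve@genotype)
}

#' Write pixel traces as CSV
#'
#' Emits the same CSV layout [readPixelTraces()] consumes.
#'
#' @param traces list of \linkS4class{PixelTrace}
#' @param path output CSV file
#' @return the path, invisibly
#' @export
writeTracesCsv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    isStart <- as.integer(tr@pixels[, 1L] == tr@start[1L] &
                          tr@pixels[, 2L] == tr@start[2L])
    if (sum(isStart) > 1L)     # keep a single flagged start row
      isStart[setdiff(which(isStart == 1L), which(isStart == 1L)[1L])] <- 0L
    data.frame(root_id = tr@rootId, genotype = tr@genotype, day = tr@day,
               dpi = tr@dpi, row = tr@pixels[, 1L], col = tr@pixels[, 2L],
               is_start = isStart)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
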