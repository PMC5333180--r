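# Reconstruction of one root individual from its segmented pixels:
# Dijkstra parameterization along the 8-connected pixel graph, knot
# placement, least-squares fit, and domain rescaling to days.

#' Construct a pixel trace
#'
#' @param pixels integer matrix or data.frame with columns row, col (0-based
#'   image coordinates, origin top-left)
#' @param start (row, col) of the pixel closest to the seed
#' @param day acquisition day (> 0)
#' @param dpi scan resolution in dots per inch
#' @param rootId,genotype labels
#' @return a \linkS4class{PixelTrace}
#' @export
PixelTrace <- function(pixels, start, day, dpi = 1200,
                       rootId = "", genotype = "") {
  px <- as.matrix(pixels)
  storage.mode(px) <- "integer"
  colnames(px) <- c("row", "col")
  new("PixelTrace", pixels = px, start = as.integer(start),
      day = as.numeric(day), dpi = as.numeric(dpi),
      rootId = as.character(rootId), genotype = as.character(genotype))
}

#' @rdname PixelTrace-class
#' @export
setMethod("rootId", "PixelTrace", function(x) x@rootId)

#' @rdname PixelTrace-class
#' @export
setMethod("genotype", "PixelTrace", function(x) x@genotype)

setMethod("show", "PixelTrace", function(object) {
  cat(sprintf(
    "PixelTrace '%s' (%s): %d pixels, day %g, %g dpi, start (%d, %d)\n",
    object@rootId, object@genotype, nrow(object@pixels), object@day,
    object@dpi, object@start[1L], object@start[2L]))
})

#' Order segmented pixels by shortest-path distance from the start
#'
#' Builds the 8-connected pixel graph (edge weight 1 for axis steps,
#' sqrt(2) for diagonal steps) and runs Dijkstra from the start pixel. The
#' shortest-path distances, normalized to [0, 1], become the sample
#' parameters for curve fitting. Pixels unreachable from the start (stray
#' segmentation noise) are dropped with a warning. Distance ties are broken
#' by (row, col) lexicographic order so the output is deterministic.
#'
#' @param trace a \linkS4class{PixelTrace}
#' @return data.frame with columns row, col, u (parameter in [0, 1]),
#'   ordered by increasing u
#' @export
orderPixelsDijkstra <- function(trace) {
  px <- trace@pixels
  n <- nrow(px)
  key <- paste(px[, 1L], px[, 2L])
  startIdx <- match(paste(trace@start[1L], trace@start[2L]), key)
  if (is.na(startIdx)) stop("start pixel is not part of the trace")
  if (n == 1L)
    return(data.frame(row = px[1L, 1L], col = px[1L, 2L], u = 0))

  offs <- cbind(rep(-1:1, each = 3L), rep(-1:1, times = 3L))
  offs <- offs[!(offs[, 1L] == 0L & offs[, 2L] == 0L), , drop = FALSE]
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(nrow(offs))) {
    nb <- match(paste(px[, 1L] + offs[k, 1L], px[, 2L] + offs[k, 2L]), key)
    hit <- which(!is.na(nb))
    hit <- hit[hit < nb[hit]]  # undirected: keep each edge once
    if (length(hit)) {
      from <- c(from, hit)
      to <- c(to, nb[hit])
      w <- c(w, rep(if (all(offs[k, ] != 0L)) sqrt(2) else 1, length(hit)))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  d <- as.numeric(igraph::distances(g, v = startIdx, weights =
                                      igraph::E(g)$weight))
  reach <- is.finite(d)
  if (!all(reach)) {
    warning(sum(!reach), " pixel(s) unreachable from the start were dropped")
    px <- px[reach, , drop = FALSE]
    d <- d[reach]
  }
  dmax <- max(d)
  u <- if (dmax > 0) d / dmax else d
  ord <- order(u, px[, 1L], px[, 2L])
  data.frame(row = px[ord, 1L], col = px[ord, 2L], u = u[ord])
}

#' Reconstruct a root curve from a pixel trace
#'
#' Full per-root pipeline: Dijkstra parameterization, control-point count
#' from the sample count ([chooseNumControlPoints()]), de Boor knot
#' placement, least-squares fit over [0, 1] in world coordinates
#' (x = column, y = row; one unit is one pixel), and rescaling of the
#' parameter domain to [0, day].
#'
#' @param trace a \linkS4class{PixelTrace}
#' @param multiplier control-point safety factor (default 1.2)
#' @param order spline order (default 4)
#' @return a \linkS4class{BSplineCurve} over [0, day]
#' @examples
#' tr <- PixelTrace(cbind(row = 0:10, col = rep(3L, 11)), start = c(0L, 3L),
#'                  day = 2, rootId = "r1")
#' crv <- reconstructRoot(tr)
#' curveDomain(crv)  # [0, 2]
#' @export
reconstructRoot <- function(trace, multiplier = 1.2, order = 4L) {
  ordered <- orderPixelsDijkstra(trace)
  # collapse duplicate parameters (ties) for knot feasibility; the fit
  # itself uses every sample
  nCp <- chooseNumControlPoints(nrow(ordered), multiplier = multiplier,
                                order = order)
  nCp <- min(nCp, nrow(ordered))
  knots <- selectKnotsDeBoor(ordered$u, nCp, order = order)
  curve <- fitBSpline(ordered$u, cbind(x = ordered$col, y = ordered$row),
                      knots, order = order, rootId = trace@rootId,
                      genotype = trace@genotype, dpi = trace@dpi)
  reparameterizeToDays(curve, trace@day)
}

#' Reconstruct every root of a trace list
#'
#' @param traces list of \linkS4class{PixelTrace}
#' @param ... passed on to [reconstructRoot()]
#' @return list of \linkS4class{BSplineCurve}
#' @export
reconstructRoots <- function(traces, ...) {
  lapply(traces, reconstructRoot, ...)
}
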