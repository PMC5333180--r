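# Input/output: pixel-trace readers (CSV and binary-mask formats), the
# single-file curve store, and unit conversion. The store keeps the
# two-table layout roots(root_id, genotype, day, dpi) /
# curves(root_id, order, knots, control_points) in one JSON document with
# full-precision numeric arrays, so persistence is portable and round-trip
# lossless.

.logMsg <- function(...) {
  message("[rootbox] ", sprintf(...))
}

#' Convert pixels to millimetres
#'
#' One unit of world/curve space is one pixel; metric lengths follow from
#' the scan resolution: \code{mm = px * 25.4 / dpi}.
#'
#' @param valuePx length in pixels
#' @param dpi scan resolution in dots per inch (> 0)
#' @return length in millimetres
#' @examples
#' pixelsToMm(1200, 1200)  # one inch = 25.4 mm
#' pixelsToMm(100, 508)    # 5 mm
#' @export
pixelsToMm <- function(valuePx, dpi) {
  if (!is.numeric(dpi) || any(dpi <= 0)) stop("dpi must be > 0")
  valuePx * 25.4 / dpi
}

#' @rdname pixelsToMm
#' @param valueMm length in millimetres
#' @export
mmToPixels <- function(valueMm, dpi) {
  if (!is.numeric(dpi) || any(dpi <= 0)) stop("dpi must be > 0")
  valueMm * dpi / 25.4
}

#' Read per-root pixel traces
#'
#' Two formats are supported. \code{"csv"}: one file with columns
#' \code{root_id, genotype, day, dpi, row, col, is_start}; rows are grouped
#' by \code{root_id} and each root must flag exactly one start pixel
#' (\code{is_start = 1}). \code{"mask"}: a JSON sidecar describing one or
#' more roots, each with a binary PNG mask (pixel value 0 or 1), metadata
#' fields and a start coordinate; non-binary masks are rejected.
#'
#' @param path CSV file or JSON sidecar
#' @param format "csv" or "mask"
#' @return list of \linkS4class{PixelTrace}, one per root
#' @export
readPixelTraces <- function(path, format = c("csv", "mask")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") .readTracesCsv(path) else .readTracesMask(path)
}

.readTracesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("root_id", "genotype", "day", "dpi", "row", "col", "is_start")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("csv is missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$root_id)[unique(df$root_id)], function(g) {
    st <- which(g$is_start == 1)
    if (!length(st)) stop("no start pixel for root '", g$root_id[1L], "'")
    PixelTrace(cbind(row = g$row, col = g$col),
               start = c(g$row[st[1L]], g$col[st[1L]]),
               day = g$day[1L], dpi = g$dpi[1L],
               rootId = g$root_id[1L], genotype = g$genotype[1L])
  })
}

.readTracesMask <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(meta)) meta <- split(meta, seq_len(nrow(meta)))
  if (!is.null(meta$roots)) meta <- meta$roots
  if (!is.null(meta$mask)) meta <- list(meta)    # single record
  lapply(meta, function(rec) {
    maskPath <- file.path(dirname(path), rec$mask)
    if (!file.exists(maskPath)) stop("mask file not found: ", maskPath)
    img <- png::readPNG(maskPath)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    if (any(img > 1e-6 & img < 1 - 1e-6))
      stop("mask '", rec$mask, "' is not binary")
    px <- which(img > 0.5, arr.ind = TRUE) - 1L   # 0-based (row, col)
    PixelTrace(cbind(row = px[, 1L], col = px[, 2L]),
               start = as.integer(unlist(rec$start)),
               day = rec$day, dpi = rec$dpi,
               rootId = rec$root_id,
               genotype = if (is.null(rec$genotype)) "" else rec$genotype)
  })
}

#' Save curves to a single-file store
#'
#' Writes a JSON document with a \code{roots} table (root_id, genotype,
#' day, dpi) and a \code{curves} table (root_id, order, knots,
#' control_points). Invariants (clamped knots, knot count = #control
#' points + order, at least \code{order} control points) are checked
#' before anything is written; numbers are serialized at full precision so
#' [loadCurves()] reproduces knots and control points exactly.
#'
#' @param path store file (overwritten)
#' @param curves list of \linkS4class{BSplineCurve}
#' @return number of curves saved, invisibly
#' @export
saveCurves <- function(path, curves) {
  curves <- unname(curves)             # arrays, not name-keyed objects
  for (cu in curves) validObject(cu)   # reject invariant violations first
  roots <- lapply(curves, function(cu) list(
    root_id = cu@rootId, genotype = cu@genotype,
    day = curveDomain(cu)[2L], dpi = cu@dpi))
  recs <- lapply(curves, function(cu) list(
    root_id = cu@rootId, order = cu@order, knots = cu@knots,
    control_points = unname(cu@controlPoints)))
  jsonlite::write_json(list(roots = roots, curves = recs), path,
                       auto_unbox = TRUE, digits = I(17), na = "null")
  .logMsg("saved %d curve(s) to %s", length(curves), path)
  invisible(length(curves))
}

#' Load curves from a store
#'
#' @param path store file written by [saveCurves()]
#' @param genotype optional filter: keep only curves of this genotype
#' @return list of \linkS4class{BSplineCurve}
#' @export
loadCurves <- function(path, genotype = NULL) {
  if (!file.exists(path)) stop("store not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  roots <- doc$roots
  recs <- doc$curves
  keep <- seq_len(nrow(roots))
  if (!is.null(genotype)) keep <- which(roots$genotype %in% genotype)
  lapply(keep, function(i) {
    cp <- recs$control_points[[i]]
    BSplineCurve(recs$knots[[i]], cp, order = recs$order[i],
                 rootId = recs$root_id[i], genotype = roots$genotype[i],
                 dpi = if (is.null(roots$dpi[i])) NA_real_ else roots$dpi[i])
  })
}
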