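# Figure composition and export. A FigureSpec is a declarative, ordered
# list of layers over the world bounding box (pixels, y down); export
# renders it either as layered SVG (one <g> per layer, deterministic
# output) or as a PNG rasterized in-package at the requested size.

.curvePolyline <- function(curve, probeCount = 256L) {
  dom <- curveDomain(curve)
  evalCurve(curve, seq(dom[1L], dom[2L], length.out = probeCount))
}

.ensembleBbox <- function(curves, pad = 0.05) {
  cp <- do.call(rbind, lapply(curves, .curvePolyline, probeCount = 64L))
  rx <- range(cp[, 1L]); ry <- range(cp[, 2L])
  px <- pad * max(diff(rx), 1); py <- pad * max(diff(ry), 1)
  c(rx[1L] - px, rx[2L] + px, ry[1L] - py, ry[2L] + py)
}

.rulerLayer <- function(bbox, dpi, days = NULL) {
  x <- bbox[1L]
  stepPx <- mmToPixels(1, dpi)
  yTicks <- seq(bbox[3L], bbox[4L], by = stepPx)
  list(type = "ruler", x = x, ticks = yTicks,
       labelsMm = seq_along(yTicks) - 1L, stepPx = stepPx,
       days = days, color = "#333333")
}

#' Compose a curve box-plot figure
#'
#' Builds the layered figure of the curve box plot: the light-gray band is
#' the union footprint of all non-outlier curves (the 100 percent zone),
#' the dark-gray band the union of the interquartile curves (the 50
#' percent zone), outliers are drawn as individual strokes above the
#' bands, the deepest member curve is green and the geometric-median
#' representative red. A mm ruler sits on top.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble}
#' @param report a matching \linkS4class{DepthReport}
#' @param strokeRadius band stroke half-width in px
#' @param width,height output size in px
#' @return a \linkS4class{FigureSpec}
#' @export
composeBoxplotFigure <- function(ens, report, strokeRadius = 3,
                                 width = 800L, height = 600L) {
  m <- nCurves(ens)
  if (length(report@depths) != m)
    stop("report does not match the ensemble")
  curves <- lapply(seq_len(m), function(i) memberCurve(ens, i))
  bbox <- .ensembleBbox(c(curves, list(report@medianCurve)))
  z <- report@zones
  iq <- which(z == "interquartile")
  notOut <- which(z != "outlier")
  outl <- which(z == "outlier")

  bandLayer <- function(idx, fill, name) {
    info <- .curveUnionMask(curves[idx], strokeRadius = strokeRadius,
                            bbox = bbox)
    list(type = "band", name = name, polygons = .maskOutline(info),
         fill = fill, alpha = 1)
  }
  layers <- list(
    bandLayer(notOut, "#D9D9D9", "zone100"),
    bandLayer(iq, "#8C8C8C", "zone50"))
  if (length(outl))
    layers[[length(layers) + 1L]] <- list(
      type = "curves", name = "outliers",
      polylines = lapply(curves[outl], .curvePolyline),
      color = "#4D4D4D", width = 1.2, alpha = 1)
  layers[[length(layers) + 1L]] <- list(
    type = "curves", name = "deepest",
    polylines = list(.curvePolyline(curves[[report@deepestIndex]])),
    color = "#1B9E3C", width = 2, alpha = 1)
  layers[[length(layers) + 1L]] <- list(
    type = "curves", name = "median",
    polylines = list(.curvePolyline(report@medianCurve)),
    color = "#D92020", width = 2, alpha = 1)
  dpi <- if (is.na(ens@dpi)) 1200 else ens@dpi
  layers[[length(layers) + 1L]] <- .rulerLayer(bbox, dpi)
  new("FigureSpec", layers = layers, bbox = bbox,
      width = as.integer(width), height = as.integer(height),
      dpi = dpi, background = "#FFFFFF")
}

#' Compose a time-line figure
#'
#' Confidence bands (alpha decaying linearly toward the zone border) lie
#' below their time-lines; time-lines are colored from a blue colormap in
#' which earlier days are brighter; member curves are drawn above in thin
#' gray; a ruler labeled in mm and days closes the stack.
#'
#' @param ens a \linkS4class{CommonBasisEnsemble}
#' @param tls a \linkS4class{TimelineSet}
#' @param width,height output size in px
#' @return a \linkS4class{FigureSpec}
#' @export
composeTimelineFigure <- function(ens, tls, width = 800L, height = 600L) {
  m <- nCurves(ens)
  curves <- lapply(seq_len(m), function(i) memberCurve(ens, i))
  bbox <- tls@bbox
  layers <- list()
  for (i in seq_along(tls@levels)) {
    if (length(tls@bands[[i]]))
      layers[[length(layers) + 1L]] <- list(
        type = "band", name = sprintf("zone-day%g", tls@levels[i]),
        polygons = tls@bands[[i]], fill = tls@colors[i], alpha = 0.15)
    layers[[length(layers) + 1L]] <- list(
      type = "timeline", name = sprintf("timeline-day%g", tls@levels[i]),
      polylines = tls@isocurves[[i]], color = tls@colors[i],
      width = 2, alpha = 1, level = tls@levels[i])
  }
  layers[[length(layers) + 1L]] <- list(
    type = "curves", name = "members",
    polylines = lapply(curves, .curvePolyline),
    color = "#666666", width = 0.8, alpha = 0.8)
  dpi <- if (is.na(ens@dpi)) 1200 else ens@dpi
  layers[[length(layers) + 1L]] <- .rulerLayer(bbox, dpi, days = tls@levels)
  new("FigureSpec", layers = layers, bbox = bbox,
      width = as.integer(width), height = as.integer(height),
      dpi = dpi, background = "#FFFFFF")
}

#' Add a validity-indicator layer to a figure
#'
#' @param spec a \linkS4class{FigureSpec}
#' @param run a rendered \linkS4class{BootstrapRun}
#' @return the spec with an indicator outline layer appended below the
#'   ruler
#' @export
addIndicatorLayer <- function(spec, run) {
  if (!length(run@outline)) stop("indicator has not been rendered yet")
  ruler <- spec@layers[[length(spec@layers)]]
  below <- spec@layers[-length(spec@layers)]
  below[[length(below) + 1L]] <- list(
    type = "indicator", name = "validity",
    polygons = run@outline, color = "#D95F02", width = 1.5, alpha = 1)
  initialize(spec, layers = c(below, list(ruler)))
}

setMethod("show", "FigureSpec", function(object) {
  cat(sprintf("FigureSpec: %d layers (%s), %dx%d px\n",
              length(object@layers),
              paste(vapply(object@layers, `[[`, character(1), "type"),
                    collapse = ", "),
              object@width, object@height))
})

.svgNum <- function(v) sprintf("%.3f", v)

.svgPoints <- function(p) {
  paste(sprintf("%.3f,%.3f", p[, 1L], p[, 2L]), collapse = " ")
}

#' Export a figure
#'
#' SVG output is layered (one group per layer, stable ids in stacking
#' order) and text-searchable; repeated exports of the same spec are
#' byte-identical. PNG output is rasterized in-package at exactly the
#' requested size.
#'
#' @param spec a \linkS4class{FigureSpec}
#' @param path output file
#' @param format "svg" or "png"
#' @return the path, invisibly
#' @export
exportFigure <- function(spec, path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (format == "svg") .exportSvg(spec, path) else .exportPng(spec, path)
  .logMsg("figure written to %s", path)
  invisible(path)
}

.exportSvg <- function(spec, path) {
  b <- spec@bbox
  lines <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" ',
           'viewBox="%s %s %s %s">'),
    spec@width, spec@height, .svgNum(b[1L]), .svgNum(b[3L]),
    .svgNum(b[2L] - b[1L]), .svgNum(b[4L] - b[3L])),
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
            .svgNum(b[1L]), .svgNum(b[3L]), .svgNum(b[2L] - b[1L]),
            .svgNum(b[4L] - b[3L]), spec@background))
  for (i in seq_along(spec@layers)) {
    ly <- spec@layers[[i]]
    lines <- c(lines, sprintf('<g id="layer%02d-%s">', i,
                              if (!is.null(ly$name)) ly$name else ly$type))
    if (ly$type %in% c("band", "indicator")) {
      fill <- if (ly$type == "band") ly$fill else "none"
      strk <- if (ly$type == "indicator") ly$color else "none"
      for (p in ly$polygons)
        lines <- c(lines, sprintf(
          '  <polygon points="%s" fill="%s" fill-opacity="%s" stroke="%s" stroke-width="%s"/>',
          .svgPoints(p), fill, .svgNum(ly$alpha), strk,
          if (ly$type == "indicator") .svgNum(ly$width) else "0"))
    } else if (ly$type %in% c("curves", "timeline")) {
      for (p in ly$polylines)
        lines <- c(lines, sprintf(
          '  <polyline points="%s" fill="none" stroke="%s" stroke-width="%s" stroke-opacity="%s"/>',
          .svgPoints(p), ly$color, .svgNum(ly$width), .svgNum(ly$alpha)))
    } else if (ly$type == "ruler") {
      fs <- max(8, 0.018 * (spec@bbox[4L] - spec@bbox[3L]))
      for (j in seq_along(ly$ticks)) {
        y <- ly$ticks[j]
        lines <- c(lines, sprintf(
          '  <line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="1"/>',
          .svgNum(ly$x), .svgNum(y), .svgNum(ly$x + 0.3 * ly$stepPx),
          .svgNum(y), ly$color))
        lines <- c(lines, sprintf(
          '  <text x="%s" y="%s" font-size="%s" fill="%s">%d mm</text>',
          .svgNum(ly$x + 0.35 * ly$stepPx), .svgNum(y + 0.3 * fs),
          .svgNum(fs), ly$color, ly$labelsMm[j]))
      }
      if (!is.null(ly$days))
        lines <- c(lines, sprintf(
          '  <text x="%s" y="%s" font-size="%s" fill="%s">days: %s</text>',
          .svgNum(ly$x), .svgNum(spec@bbox[3L] + fs), .svgNum(fs),
          ly$color, paste(signif(ly$days, 3), collapse = ", ")))
    }
    lines <- c(lines, "</g>")
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
}

.hex2rgb <- function(hex) {
  as.numeric(grDevices::col2rgb(hex)) / 255
}

.exportPng <- function(spec, path) {
  w <- spec@width; h <- spec@height
  b <- spec@bbox
  sx <- w / (b[2L] - b[1L]); sy <- h / (b[4L] - b[3L])
  toPix <- function(p)
    cbind((p[, 1L] - b[1L]) * sx + 0.5, (p[, 2L] - b[3L]) * sy + 0.5)
  img <- array(0, dim = c(h, w, 3L))
  bg <- .hex2rgb(spec@background)
  for (ch in 1:3) img[, , ch] <- bg[ch]
  blend <- function(img, mask, col, alpha) {
    if (!any(mask)) return(img)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[mask] <- (1 - alpha) * plane[mask] + alpha * col[ch]
      img[, , ch] <- plane
    }
    img
  }
  strokeMask <- function(polylines, width) {
    msk <- .rasterPolylines(lapply(polylines, toPix), c(h, w))
    r <- max(0L, round(width / 2))
    if (r > 0L) {
      msk <- EBImage::dilate(msk * 1,
                             EBImage::makeBrush(2L * r + 1L, "disc")) > 0.5
    }
    msk
  }
  for (ly in spec@layers) {
    if (ly$type == "band") {
      msk <- matrix(FALSE, h, w)
      for (p in ly$polygons) msk <- msk | .fillPolygonMask(toPix(p), c(h, w))
      img <- blend(img, msk, .hex2rgb(ly$fill), ly$alpha)
    } else if (ly$type %in% c("curves", "timeline")) {
      img <- blend(img, strokeMask(ly$polylines, ly$width),
                   .hex2rgb(ly$color), ly$alpha)
    } else if (ly$type == "indicator") {
      img <- blend(img, strokeMask(ly$polygons, ly$width),
                   .hex2rgb(ly$color), ly$alpha)
    } else if (ly$type == "ruler") {
      ticks <- lapply(ly$ticks, function(y)
        cbind(c(ly$x, ly$x + 0.3 * ly$stepPx), c(y, y)))
      img <- blend(img, strokeMask(ticks, 1), .hex2rgb(ly$color), 1)
    }
  }
  png::writePNG(img, path)
}
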