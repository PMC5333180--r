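# Shared raster helpers: 8-connected line rasterization, polyline masks,
# scanline polygon fill. World coordinates are pixels (x = col, y = row);
# masks are logical matrices indexed [row, col].

# 8-connected chain of integer pixels from (x0, y0) to (x1, y1), Bresenham.
.bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx - dy
  n <- dx + dy + 1L
  xs <- integer(n); ys <- integer(n)
  i <- 0L
  repeat {
    i <- i + 1L
    xs[i] <- x0; ys[i] <- y0
    if (x0 == x1 && y0 == y1) break
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x0 <- x0 + sx }
    if (e2 < dx)  { err <- err + dx; y0 <- y0 + sy }
  }
  cbind(x = xs[seq_len(i)], y = ys[seq_len(i)])
}

# rasterize polylines (list of x,y matrices in mask-cell coordinates,
# 1-based) onto a logical matrix of size dim = c(nrow, ncol)
.rasterPolylines <- function(polylines, dim) {
  mask <- matrix(FALSE, dim[1L], dim[2L])
  for (pl in polylines) {
    if (nrow(pl) == 0L) next
    xi <- pmin(pmax(round(pl[, 1L]), 1L), dim[2L])
    yi <- pmin(pmax(round(pl[, 2L]), 1L), dim[1L])
    if (nrow(pl) == 1L) {
      mask[yi, xi] <- TRUE
      next
    }
    for (s in seq_len(nrow(pl) - 1L)) {
      seg <- .bresenham(xi[s], yi[s], xi[s + 1L], yi[s + 1L])
      mask[cbind(seg[, 2L], seg[, 1L])] <- TRUE
    }
  }
  mask
}

# even-odd scanline fill of a polygon (matrix x, y in cell coordinates)
.fillPolygonMask <- function(poly, dim) {
  mask <- matrix(FALSE, dim[1L], dim[2L])
  n <- nrow(poly)
  if (n < 3L) return(mask)
  px <- poly[, 1L]; py <- poly[, 2L]
  for (row in seq_len(dim[1L])) {
    yscan <- row
    xs <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      yi <- py[i]; yj <- py[j]
      if ((yi > yscan) != (yj > yscan)) {
        xs <- c(xs, px[i] + (yscan - yi) / (yj - yi) * (px[j] - px[i]))
      }
      j <- i
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        a <- max(1L, ceiling(xs[k])); b <- min(dim[2L], floor(xs[k + 1L]))
        if (a <= b) mask[row, a:b] <- TRUE
      }
    }
  }
  mask
}

# union of dilated curve strokes: probe curves, map to a grid over bbox,
# draw, dilate by strokeRadius (px), morphological closing, fill holes.
# Returns mask, cell size and the world origin of cell (1,1).
.curveUnionMask <- function(curves, probeCount = 256L, strokeRadius = 2,
                            gridCells = 400L, bbox = NULL) {
  polys <- lapply(curves, function(cu) {
    dom <- curveDomain(cu)
    evalCurve(cu, seq(dom[1L], dom[2L], length.out = probeCount))
  })
  allp <- do.call(rbind, polys)
  if (is.null(bbox)) {
    pad <- 2 * strokeRadius + 2
    bbox <- c(min(allp[, 1L]) - pad, max(allp[, 1L]) + pad,
              min(allp[, 2L]) - pad, max(allp[, 2L]) + pad)
  }
  extent <- max(bbox[2L] - bbox[1L], bbox[4L] - bbox[3L], 1e-9)
  cell <- extent / gridCells
  ncol <- max(2L, ceiling((bbox[2L] - bbox[1L]) / cell)) + 1L
  nrow <- max(2L, ceiling((bbox[4L] - bbox[3L]) / cell)) + 1L
  toCells <- function(p)
    cbind((p[, 1L] - bbox[1L]) / cell + 1, (p[, 2L] - bbox[3L]) / cell + 1)
  mask <- .rasterPolylines(lapply(polys, toCells), c(nrow, ncol))
  rCells <- max(1L, round(strokeRadius / cell))
  brush <- EBImage::makeBrush(2L * rCells + 1L, shape = "disc")
  m <- EBImage::dilate(mask * 1, brush)
  m <- EBImage::erode(EBImage::dilate(m, brush), brush)   # closing
  m <- EBImage::fillHull(m)
  list(mask = m > 0.5, cell = cell, origin = c(bbox[1L], bbox[3L]),
       bbox = bbox)
}

# outer contour(s) of a logical mask, in world coordinates
.maskOutline <- function(maskInfo) {
  oc <- EBImage::ocontour(EBImage::Image(t(maskInfo$mask * 1)))
  lapply(oc, function(p)
    cbind(x = maskInfo$origin[1L] + (p[, 1L] - 1) * maskInfo$cell,
          y = maskInfo$origin[2L] + (p[, 2L] - 1) * maskInfo$cell))
}
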