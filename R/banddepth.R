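# Modified band depth baseline for planar curve ensembles. A curve's depth
# is its average fractional time inside bands spanned by J-subsets of the
# other curves, where the band at a parameter value is the convex hull of
# the subset members' points there.

# is point p inside the convex hull of the rows of P (2-D)? Boundary counts
# as inside, with an epsilon tolerance on the orientation tests.
.inHull <- function(p, P, eps = 1e-9) {
  P <- unique(round(P, 12L))
  k <- nrow(P)
  if (k == 1L)
    return(sqrt(sum((p - P[1L, ])^2)) <= eps)
  if (k == 2L) {
    a <- P[1L, ]; b <- P[2L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 <= eps^2) return(sqrt(sum((p - a)^2)) <= eps)
    cross <- ab[1L] * (p[2L] - a[2L]) - ab[2L] * (p[1L] - a[1L])
    if (abs(cross) > eps * sqrt(len2)) return(FALSE)
    tproj <- sum((p - a) * ab) / len2
    return(tproj >= -eps && tproj <= 1 + eps)
  }
  h <- grDevices::chull(P)
  H <- P[h, , drop = FALSE]
  nh <- nrow(H)
  if (nh < 3L) return(.inHull(p, H, eps))
  # chull returns clockwise order; test sign consistency of edge crossings
  s <- vapply(seq_len(nh), function(i) {
    a <- H[i, ]; b <- H[if (i == nh) 1L else i + 1L, ]
    (b[1L] - a[1L]) * (p[2L] - a[2L]) - (b[2L] - a[2L]) * (p[1L] - a[1L])
  }, numeric(1))
  all(s <= eps) || all(s >= -eps)
}

#' Modified band depth of planar curves
#'
#' Baseline functional depth: every curve is evaluated at \code{nSamples}
#' probe parameters on the common domain; the depth of curve \code{i} is
#' the mean, over all J-subsets of the remaining curves, of the fraction of
#' probe parameters at which curve i's point lies inside the convex hull of
#' the subset's points (the band). With \code{J = 2} a band at a parameter
#' is the segment between the two member points. Boundary membership counts
#' as inside (tolerance \code{1e-9} relative to the coordinate scale).
#'
#' @param curves list of \linkS4class{BSplineCurve} or a
#'   \linkS4class{CommonBasisEnsemble}
#' @param J band subset size (default 2, the minimal band)
#' @param nSamples probe parameters per curve (default 128)
#' @param summed if TRUE, sum the depths for subset sizes 2..J (the more
#'   robust multi-J variant); default FALSE
#' @return numeric depth vector, one value per curve
#' @examples
#' lines <- lapply(c(0, 1, 2), function(y0)
#'   BSplineCurve(c(0, 0, 0, 0, 1, 1, 1, 1),
#'                cbind(x = seq(0, 3, length.out = 4), y = y0)))
#' modifiedBandDepth(lines)  # middle line is deepest
#' @export
modifiedBandDepth <- function(curves, J = 2L, nSamples = 128L,
                              summed = FALSE) {
  if (is(curves, "CommonBasisEnsemble")) {
    ens <- curves
    curves <- lapply(seq_len(nCurves(ens)), function(i) memberCurve(ens, i))
  }
  m <- length(curves)
  if (m < J + 1L)
    stop("need at least J + 1 = ", J + 1L, " curves, got ", m)
  doms <- vapply(curves, curveDomain, numeric(2))
  lo <- max(doms[1L, ]); hi <- min(doms[2L, ])
  if (hi <= lo) stop("curves share no common domain")
  u <- seq(lo, hi, length.out = nSamples)
  pts <- lapply(curves, evalCurve, t = u)        # each nSamples x 2
  scale <- max(1, diff(range(unlist(pts))))
  eps <- 1e-9 * scale

  Js <- if (summed) 2L:J else J
  depth <- numeric(m)
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    total <- 0
    for (j in Js) {
      subsets <- utils::combn(others, j)
      frac <- apply(subsets, 2L, function(sub) {
        inside <- vapply(seq_len(nSamples), function(s) {
          P <- do.call(rbind, lapply(sub, function(k2) pts[[k2]][s, ]))
          .inHull(pts[[i]][s, ], P, eps)
        }, logical(1))
        mean(inside)
      })
      total <- total + mean(frac)
    }
    depth[i] <- total    # single-J value, or the sum over j = 2..J
  }
  depth
}
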