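# Fixture builders and independent oracles shared across the suite.

# single-segment cubic Bezier as a clamped order-4 B-spline
bezierCurve <- function(cp, rootId = "", domain = c(0, 1)) {
  BSplineCurve(c(rep(domain[1L], 4L), rep(domain[2L], 4L)), cp,
               rootId = rootId)
}

# horizontal "curve" at height y0 over x in [0, len]
lineCurve <- function(y0, len = 3, rootId = paste0("line", y0)) {
  bezierCurve(cbind(x = seq(0, len, length.out = 4L), y = y0),
              rootId = rootId)
}

# Fermat-Weber objective
fwObjective <- function(y, pts) sum(sqrt(rowSums(sweep(pts, 2L, y)^2)))

# independent derivative-free minimizer of the Fermat-Weber objective:
# Nelder-Mead polish started from the mean and from every sample point
bruteMedianObjective <- function(X) {
  obj <- function(y) fwObjective(y, X)
  starts <- rbind(colMeans(X), X)
  min(apply(starts, 1L, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 10000))$value))
}

# spatial deviation of curve a from curve b: max over probes of the
# distance from a's point to the nearest densely sampled point of b
curveDeviation <- function(a, b, nProbe = 100L, nDense = 4096L) {
  da <- curveDomain(a); db <- curveDomain(b)
  pa <- evalCurve(a, seq(da[1L], da[2L], length.out = nProbe))
  pb <- evalCurve(b, seq(db[1L], db[2L], length.out = nDense))
  max(vapply(seq_len(nProbe), function(i)
    sqrt(min((pb[, 1L] - pa[i, 1L])^2 + (pb[, 2L] - pa[i, 2L])^2)),
    numeric(1)))
}

# generator settings for the low-noise regime (about 0.4 percent relative
# variation) used by recovery harnesses
lowNoise <- list(speedSd = 0.5, angleSd = 0.001, wiggleAmp = 0.25,
                 noiseSd = 0.1)

luminance <- function(hex) {
  rgb <- grDevices::col2rgb(hex)
  as.numeric(0.2126 * rgb[1L, ] + 0.7152 * rgb[2L, ] + 0.0722 * rgb[3L, ])
}
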