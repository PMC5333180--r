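test_that("Weiszfeld median solves small Fermat-Weber instances", {
  # single point
  expect_equal(weiszfeldMedian(matrix(c(0, 0), 1L))@y, c(0, 0))
  # symmetric square: center
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(weiszfeldMedian(sq)@y, c(0, 0), tolerance = 1e-8)
  # dominant multiplicity-3 point beats a distant single point; confirmed
  # by a brute-force objective scan over a grid
  X <- rbind(c(0, 0), c(0, 0), c(0, 0), c(10, 0))
  grid <- as.matrix(expand.grid(seq(-1, 11, by = 0.25), seq(-2, 2, by = 0.25)))
  gridBest <- grid[which.min(apply(grid, 1L, fwObjective, pts = X)), ]
  expect_equal(unname(gridBest), c(0, 0))
  est <- weiszfeldMedian(X)
  expect_equal(est@y, c(0, 0), tolerance = 1e-6)
  expect_true(est@converged)

  # objective never above the independent derivative-free minimum (the
  # iteration may report slow convergence near an interior minimizer that
  # hugs a sample; the objective gap is the check here)
  set.seed(11)
  for (rep in 1:10) {
    Xr <- matrix(rnorm(2L * sample(3:12, 1L), sd = 5), ncol = 2L)
    est <- suppressWarnings(weiszfeldMedian(Xr))
    expect_lt(abs(fwObjective(est@y, pts = Xr) -
                  bruteMedianObjective(Xr)), 1e-4)
  }
})

test_that("L1 depth reproduces direct evaluations of the depth formula", {
  X <- cbind(0:4, 0)
  expect_equal(l1Depth(c(2, 0), X), 1)          # r = 0, w = 1
  expect_equal(l1Depth(c(0, 0), X), 1 - 3 / 5)  # r = 4, w = 1
  # depth at the computed geometric median is maximal
  set.seed(12)
  for (rep in 1:5) {
    Xr <- matrix(rnorm(2L * 10L, sd = 3), ncol = 2L)
    expect_gte(l1Depth(weiszfeldMedian(Xr)@y, Xr), 1 - 1e-6 * nrow(Xr))
  }
})

test_that("ensemble depths respect dominance and rigid invariance", {
  expect_equal(ensembleDepths(matrix(c(1, 2), 1L)), 1)   # singleton
  # two identical curves and one distant one: the distant one is least deep
  knots <- c(0, 0, 0, 0, 1, 1, 1, 1)
  a <- BSplineCurve(knots, cbind(x = 0:3, y = 0:3), rootId = "a1")
  a2 <- BSplineCurve(knots, cbind(x = 0:3, y = 0:3), rootId = "a2")
  b <- BSplineCurve(knots, cbind(x = 0:3 + 50, y = 0:3), rootId = "b")
  ens <- commonBasisEnsemble(list(a, a2, b))
  dep <- ensembleDepths(ens)
  expect_equal(which.min(dep), 3L)
  expect_equal(dep[1L], dep[2L])

  # depth list is invariant under translation, rotation and scaling
  set.seed(13)
  X <- matrix(rnorm(20L * 6L), ncol = 6L)
  d0 <- ensembleDepths(X)
  expect_equal(ensembleDepths(sweep(X, 2L, rnorm(6L), "+")), d0)
  expect_equal(ensembleDepths(X * 37.5), d0)
  theta <- 0.7
  R <- diag(6L)
  R[1:2, 1:2] <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L)
  expect_equal(ensembleDepths(X %*% R), d0)
})

test_that("moving a curve away from the ensemble never raises its depth", {
  set.seed(14)
  X <- matrix(rnorm(12L * 4L), ncol = 4L)
  dir <- rnorm(4L); dir <- dir / sqrt(sum(dir^2))
  deps <- vapply(c(0, 1, 2, 4, 8, 16), function(s) {
    Xs <- X
    Xs[1L, ] <- X[1L, ] + s * dir
    ensembleDepths(Xs)[1L]
  }, numeric(1))
  expect_true(all(diff(deps) <= 1e-12))
})

test_that("zone classification matches the whisker arithmetic", {
  z1 <- classifyZones(c(1.0, 0.9, 0.8, 0.5, 0.2, 0.1))
  expect_equal(as.character(z1),
               c("interquartile", "interquartile", "interquartile",
                 "inlier", "inlier", "inlier"))        # threshold -0.4
  z2 <- classifyZones(c(1.0, 0.98, 0.96, 0.94, 0.1))
  expect_equal(as.character(z2),
               c("interquartile", "interquartile", "interquartile",
                 "inlier", "outlier"))                 # threshold 0.84
  expect_equal(as.character(classifyZones(rep(0.7, 4L))),
               rep("interquartile", 4L))
  expect_error(classifyZones(numeric(0)), "at least")
})

test_that("geometric-median curve is central and recovers the generator center", {
  knots <- c(0, 0, 0, 0, 1, 1, 1, 1)
  solo <- BSplineCurve(knots, cbind(x = 0:3, y = c(0, 1, 1, 0)), rootId = "s")
  ens1 <- commonBasisEnsemble(list(solo))
  expect_equal(unname(controlPoints(geometricMedianCurve(ens1))),
               unname(controlPoints(solo)), tolerance = 1e-9)

  # mirrored pairs about x = 0 (two pairs with distinct depth profiles so
  # the coefficient-space median is unique): median curve lies on the axis
  mk <- function(sgn, yshift, id) BSplineCurve(
    knots, cbind(x = sgn * c(1, 2, 2, 1), y = c(0, 2, 4, 6) + yshift),
    rootId = id)
  ensM <- commonBasisEnsemble(list(mk(1, 0, "p1"), mk(-1, 0, "m1"),
                                   mk(2, 3, "p2"), mk(-2, 3, "m2")))
  medM <- geometricMedianCurve(ensM)
  expect_lt(max(abs(controlPoints(medM)[, 1L])), 1e-6)

  # parameter recovery on generator output, low noise
  gen <- do.call(generateEnsemble, c(list(m = 40L, seed = 15L), lowNoise))
  ens <- commonBasisEnsemble(gen$curves)
  med <- geometricMedianCurve(ens)
  u <- seq(0.05, 5, length.out = 100L)
  dev <- max(sqrt(rowSums((evalCurve(med, u) - evalCurve(gen$center, u))^2)))
  expect_lt(dev, 1)
})

test_that("depth report assembles consistent zones and representative", {
  gen <- generateEnsemble(m = 12L, seed = 16L)
  ens <- commonBasisEnsemble(gen$curves)
  rep <- depthReport(ens)
  expect_s4_class(rep, "DepthReport")
  expect_equal(deepestIndex(rep), which.max(depths(rep)))
  expect_equal(as.character(zones(rep)),
               as.character(classifyZones(depths(rep))))
  expect_true(all(depths(rep) > 0 & depths(rep) <= 1))
  csv <- withr::local_tempfile(fileext = ".csv")
  exportDepthReport(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$depth, unname(depths(rep)))
})

test_that("modified band depth favors enclosed curves and handles ties", {
  lines <- lapply(c(0, 1, 2), lineCurve)
  mbd <- modifiedBandDepth(lines)
  expect_equal(which.max(mbd), 2L)
  expect_gt(mbd[2L], max(mbd[c(1L, 3L)]))
  expect_equal(mbd[2L], 1)   # the middle line is inside its only band fully

  expect_error(modifiedBandDepth(lines[1:2]), "at least")

  # duplicating the deepest curve leaves the two copies tied
  lines4 <- c(lines, list(lineCurve(1, rootId = "dup")))
  mbd4 <- modifiedBandDepth(lines4)
  expect_equal(mbd4[2L], mbd4[4L])

  # summed multi-J variant keeps the same winner
  mbdJ3 <- modifiedBandDepth(lines4, J = 3L, summed = TRUE)
  expect_equal(which.max(mbdJ3), which.max(mbd4))
})

test_that("deepest members by L1 and band depth sit near each other", {
  gen <- generateEnsemble(m = 16L, seed = 17L)
  ens <- commonBasisEnsemble(gen$curves)
  iL1 <- which.max(ensembleDepths(ens))
  iMBD <- which.max(modifiedBandDepth(ens, nSamples = 64L))
  X <- coeffMatrix(ens)
  d <- sqrt(sum((X[iL1, ] - X[iMBD, ])^2))
  pw <- as.matrix(dist(X))
  expect_lte(d, median(pw[upper.tri(pw)]))
})
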