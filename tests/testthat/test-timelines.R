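test_that("time-line samples are harvested per curve per covered stamp", {
  gen <- generateEnsemble(m = 2L, seed = 21L, days = 5)
  s <- sampleTimelinePoints(gen$curves, c(1, 2))
  expect_equal(nrow(s), 4L)
  expect_setequal(unique(s$t), c(1, 2))

  # stamps beyond a curve's domain are skipped with a warning
  short <- reparameterizeToDays(
    bezierCurve(cbind(x = 0:3, y = c(0, 40, 80, 120))), 3)
  expect_warning(s2 <- sampleTimelinePoints(list(short, gen$curves[[1L]]), 5),
                 "skipped")
  expect_equal(nrow(s2), 1L)
  expect_error(suppressWarnings(sampleTimelinePoints(list(short), 9)),
               "no curve")

  # straight vertical unit-speed curves: y at stamp t is t * speed
  vert <- reparameterizeToDays(
    bezierCurve(cbind(x = 0, y = c(0, 100, 200, 300))), 5)
  sv <- sampleTimelinePoints(list(vert), c(1, 3))
  expect_equal(sv$y, c(1, 3) * 60, tolerance = 1e-9)
})

test_that("TPS fit reproduces affine fields and interpolates when square", {
  set.seed(22)
  pts <- cbind(runif(40L, 0, 10), runif(40L, 0, 10))
  s <- data.frame(x = pts[, 1L], y = pts[, 2L],
                  t = 1 + 2 * pts[, 1L] - pts[, 2L])
  centers <- cbind(runif(6L, 0, 10), runif(6L, 0, 10))
  surf <- fitTPS(s, centers)
  grid <- as.matrix(expand.grid(seq(0, 10, length.out = 15L),
                                seq(0, 10, length.out = 15L)))
  expect_lt(max(abs(evalTPS(surf, grid) - (1 + 2 * grid[, 1L] - grid[, 2L]))),
            1e-8)
  expect_equal(surf@beta0, 1, tolerance = 1e-8)
  expect_equal(surf@beta, c(2, -1), tolerance = 1e-8)
  expect_lt(max(abs(surf@alpha)), 1e-8)

  # centers = samples: interpolation regime
  p5 <- cbind(c(0, 3, 7, 2, 9), c(1, 8, 2, 6, 5))
  t5 <- c(1, 2, 3, 4, 5)
  surf5 <- fitTPS(data.frame(x = p5[, 1L], y = p5[, 2L], t = t5), p5)
  expect_lt(max(abs(evalTPS(surf5, p5) - t5)), 1e-6)

  # constant field
  surfC <- fitTPS(data.frame(x = pts[, 1L], y = pts[, 2L], t = 4.5), centers)
  expect_equal(surfC@beta0, 4.5, tolerance = 1e-8)
  expect_lt(max(abs(surfC@beta)), 1e-8)
  expect_lt(max(abs(surfC@alpha)), 1e-8)

  # collinear samples are rejected
  bad <- data.frame(x = 1:5, y = 2 * (1:5), t = 1:5)
  expect_error(fitTPS(bad, centers), "collinear")
})

test_that("TPS kernels vanish at centers and at unit distance", {
  surf <- new("TPSSurface", beta0 = 0, beta = c(0, 0), alpha = 1,
              centers = matrix(c(2, 3), 1L), cgIterations = 0L,
              cgResidual = 0)
  expect_equal(evalTPS(surf, c(2, 3)), 0)        # r^2 log r -> 0
  expect_equal(evalTPS(surf, c(3, 3)), 0)        # log 1 = 0
  expect_equal(evalTPS(surf, c(2, 3 + exp(1))), exp(2))
})

test_that("isocurves track analytic level sets on the grid", {
  set.seed(23)
  sp <- data.frame(x = runif(20L), y = runif(20L))
  sp$t <- sp$x                                  # plane t = x
  surf <- fitTPS(sp, cbind(0.5, 0.5))
  iso <- extractIsocurves(surf, 0.5, c(0, 1, 0, 1), 64L)
  expect_length(iso, 1L)
  cell <- 1 / 63
  expect_lt(max(abs(iso[[1L]][, 1L] - 0.5)), cell)
  expect_length(extractIsocurves(surf, 7, c(0, 1, 0, 1), 32L), 0L)

  # radial-ish single-kernel field yields a closed contour
  surfR <- new("TPSSurface", beta0 = 0, beta = c(0, 0), alpha = 1,
               centers = matrix(c(0, 0), 1L), cgIterations = 0L,
               cgResidual = 0)
  isoR <- extractIsocurves(surfR, .Machine$double.eps + 25 * log(5),
                           c(-8, 8, -8, 8), 101L)
  expect_gte(length(isoR), 1L)
  ring <- isoR[[1L]]
  expect_lt(max(abs(sqrt(rowSums(ring^2)) - 5)), 0.4)
  expect_equal(unname(ring[1L, ]), unname(ring[nrow(ring), ]),
               tolerance = 1e-6)
})

test_that("time-line variance follows the residual spread", {
  # interpolating surface: zero variance
  p5 <- cbind(c(0, 3, 7, 2, 9), c(1, 8, 2, 6, 5))
  vertAt <- function(x0, speed) reparameterizeToDays(
    bezierCurve(cbind(x = x0, y = speed * c(0, 1 / 3, 2 / 3, 1) * 5)), 5)
  curves <- list(vertAt(0, 60), vertAt(30, 60))
  s <- sampleTimelinePoints(curves, c(1, 2, 3))
  surf <- fitTPS(s, cbind(s$x, s$y))
  expect_equal(timelineVariance(curves, surf, 2), 0, tolerance = 1e-10)

  # two curves whose field readings are t + delta and t - delta: the
  # variance is exactly delta^2. The field F(x, y) = y / 20 assigns time
  # by depth; the curves grow at 20 px/day but are shifted by +-20*delta.
  delta <- 0.3
  planeSurf <- new("TPSSurface", beta0 = 0, beta = c(0, 1 / 20), alpha = 0,
                   centers = matrix(c(1e6, 1e6), 1L), cgIterations = 0L,
                   cgResidual = 0)
  shiftUp <- function(dy) reparameterizeToDays(
    bezierCurve(cbind(x = 0, y = 20 * c(0, 1 / 3, 2 / 3, 1) * 5 + dy)), 5)
  cA <- shiftUp(20 * delta); cB <- shiftUp(-20 * delta)
  v <- timelineVariance(list(cA, cB), planeSurf, 2)
  expect_equal(v, delta^2, tolerance = 1e-10)

  # duplicating the whole ensemble leaves the variance unchanged
  expect_equal(timelineVariance(c(list(cA, cB), list(cA, cB)), planeSurf, 2),
               v)
  expect_warning(vv <- timelineVariance(list(vertAt(0, 60)), planeSurf, 99),
                 "variance undefined")
  expect_true(is.na(vv))
})

test_that("time-line sets are ordered, colored and non-crossing", {
  gen <- generateEnsemble(m = 10L, seed = 24L)
  ens <- commonBasisEnsemble(gen$curves)
  s <- sampleTimelinePoints(gen$curves, 1:5)
  surf <- fitTPS(s, tpsCentersFromEnsemble(ens))
  tls <- buildTimelines(gen$curves, surf, 1:5, gridRes = 96L)
  expect_length(tls@levels, 5L)
  # earlier stamps brighter: luminance strictly decreasing with day
  expect_true(all(diff(luminance(tls@colors)) < 0))
  expect_true(all(tls@variances >= 0))
  # isocurves of consecutive day levels stay apart on the grid (the field
  # is single-valued, so level sets of distinct levels cannot touch)
  for (i in 1:4) {
    a <- do.call(rbind, tls@isocurves[[i]])
    b <- do.call(rbind, tls@isocurves[[i + 1L]])
    if (is.null(a) || is.null(b)) next
    minGap <- min(vapply(seq_len(nrow(a)), function(k)
      min((b[, 1L] - a[k, 1L])^2 + (b[, 2L] - a[k, 2L])^2), numeric(1)))
    expect_gt(sqrt(minGap), 0)
  }
})
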