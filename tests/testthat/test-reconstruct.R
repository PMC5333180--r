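test_that("Dijkstra parameterization matches hand-computed path lengths", {
  # horizontal run: unit steps force parameters k/10
  tr <- PixelTrace(cbind(row = 0L, col = 0:10), start = c(0L, 0L), day = 1)
  ord <- orderPixelsDijkstra(tr)
  expect_equal(ord$u, (0:10) / 10)
  expect_equal(ord$col, 0:10)

  # degenerate single pixel
  single <- PixelTrace(cbind(row = 2L, col = 2L), start = c(2L, 2L), day = 1)
  expect_equal(orderPixelsDijkstra(single)$u, 0)

  # L-path: 5 horizontal then 4 vertical pixels. Under 8-connectivity the
  # shortest path into the vertical arm cuts the corner diagonally, so the
  # hand-computed distances are 0..4 then 3 + sqrt(2), 4 + sqrt(2), ...
  px <- rbind(cbind(0L, 0:4), cbind(1:4, 4L))
  trL <- PixelTrace(px, start = c(0L, 0L), day = 1)
  ordL <- orderPixelsDijkstra(trL)
  dHand <- c(0:4, 3 + sqrt(2), 4 + sqrt(2), 5 + sqrt(2), 6 + sqrt(2))
  expect_equal(ordL$u, dHand / max(dHand))

  # stray unreachable pixel is dropped with a warning
  trU <- PixelTrace(rbind(cbind(0L, 0:3), c(10L, 10L)),
                    start = c(0L, 0L), day = 1)
  expect_warning(ordU <- orderPixelsDijkstra(trU), "unreachable")
  expect_equal(nrow(ordU), 4L)

  # diagonal steps weigh sqrt(2)
  trD <- PixelTrace(cbind(row = 0:3, col = 0:3), start = c(0L, 0L), day = 1)
  expect_equal(orderPixelsDijkstra(trD)$u, (0:3) / 3)
})

test_that("control-point count follows the ceiling rule above the bound", {
  expect_identical(chooseNumControlPoints(500), 48L)
  expect_identical(chooseNumControlPoints(42), 5L)
  expect_identical(chooseNumControlPoints(4), 4L)   # floored at the order
  expect_error(chooseNumControlPoints(3), "at least")
  # always above the spectral lower bound n / (4 pi)
  for (n in c(4, 13, 50, 201, 999))
    expect_gte(chooseNumControlPoints(n), n / (4 * pi))
  # ratio tends to 1.2 / (4 pi) for large n
  for (n in c(1000, 5000, 20000)) {
    ratio <- chooseNumControlPoints(n) / n
    expect_lt(abs(ratio - 1.2 / (4 * pi)) / (1.2 / (4 * pi)), 0.02)
  }
})

test_that("knot placement balances samples and stays fit-feasible", {
  # no interior knots when nCp equals the order
  expect_equal(selectKnotsDeBoor(seq(0, 1, length.out = 10L), 4L),
               c(0, 0, 0, 0, 1, 1, 1, 1))
  # 100 uniform parameters, 6 control points: interior knots near 1/3, 2/3
  k <- selectKnotsDeBoor(seq(0, 1, length.out = 100L), 6L)
  expect_length(k, 10L)
  expect_lt(abs(k[5L] - 1 / 3), 0.02)
  expect_lt(abs(k[6L] - 2 / 3), 0.02)
  # interpolation regime: Schoenberg-Whitney holds (full-rank design)
  set.seed(1)
  params <- sort(runif(12L))
  ki <- selectKnotsDeBoor(params, 12L)
  B <- splines::splineDesign(ki, params, ord = 4L)
  expect_equal(qr(B)$rank, 12L)
  expect_error(selectKnotsDeBoor(seq(0, 1, length.out = 5L), 6L), "at least")
})

test_that("least-squares fit recovers exact and collinear geometry", {
  knots <- c(0, 0, 0, 0, 0.4, 0.7, 1, 1, 1, 1)
  set.seed(2)
  cp <- cbind(x = rnorm(6L), y = rnorm(6L))
  truth <- BSplineCurve(knots, cp)
  u <- seq(0, 1, length.out = 40L)
  fit <- fitBSpline(u, evalCurve(truth, u), knots)
  expect_equal(unname(controlPoints(fit)), unname(cp), tolerance = 1e-10)

  # collinear pixels on y = 2x stay on the line
  u2 <- seq(0, 1, length.out = 30L)
  pts <- cbind(x = 3 * u2, y = 6 * u2)
  fit2 <- fitBSpline(u2, pts, selectKnotsDeBoor(u2, 5L))
  chk <- evalCurve(fit2, seq(0, 1, length.out = 200L))
  expect_lt(max(abs(chk[, 2L] - 2 * chk[, 1L])), 1e-6)

  expect_error(fitBSpline(c(0, 0.5, 1), cbind(0:2, 0:2), knots), "samples")
})

test_that("day reparameterization rescales time but not geometry", {
  set.seed(3)
  crv <- fitBSpline(seq(0, 1, length.out = 30L),
                    cbind(x = cumsum(rnorm(30L)), y = cumsum(rnorm(30L))),
                    selectKnotsDeBoor(seq(0, 1, length.out = 30L), 6L))
  expect_equal(reparameterizeToDays(crv, 1), crv)
  c5 <- reparameterizeToDays(crv, 5)
  expect_equal(curveDomain(c5), c(0, 5))
  expect_equal(evalCurve(c5, 2.5), evalCurve(crv, 0.5))
  expect_identical(controlPoints(c5), controlPoints(crv))
  c3 <- reparameterizeToDays(crv, 3)
  expect_equal(arcLength(c3), arcLength(crv), tolerance = 1e-9)
  expect_error(reparameterizeToDays(crv, 0), "positive")
  expect_error(reparameterizeToDays(crv, -2), "positive")
})

test_that("curve evaluation is clamped and matches the Bezier closed form", {
  cp <- cbind(x = c(0, 1, 3, 4), y = c(0, 2, 2, 0))
  bez <- bezierCurve(cp)
  expect_equal(evalCurve(bez, 0)[1L, ], c(x = 0, y = 0))
  expect_equal(evalCurve(bez, 1)[1L, ], c(x = 4, y = 0))
  # cubic Bezier midpoint: (P0 + 3 P1 + 3 P2 + P3) / 8
  expect_equal(unname(evalCurve(bez, 0.5)[1L, ]),
               unname((cp[1L, ] + 3 * cp[2L, ] + 3 * cp[3L, ] + cp[4L, ]) / 8))
  expect_error(evalCurve(bez, 1.5), "domain")
  d2 <- reparameterizeToDays(bez, 2)
  expect_equal(evalCurve(d2, 2)[1L, ], c(x = 4, y = 0))
})

test_that("fit residuals shrink monotonically with sample noise", {
  set.seed(4)
  u <- seq(0, 1, length.out = 200L)
  truth <- cbind(x = 10 * sin(2 * u), y = 60 * u)
  rms <- vapply(c(2, 1, 0.5, 0), function(sigma) {
    pts <- truth + rnorm(length(truth), 0, sigma)
    fit <- fitBSpline(u, pts, selectKnotsDeBoor(u, chooseNumControlPoints(200L)))
    sqrt(mean((evalCurve(fit, u) - truth)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
})
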