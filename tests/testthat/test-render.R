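test_that("box-plot figure stacks the expected layers in z-order", {
  gen <- generateEnsemble(m = 6L, seed = 41L)
  ens <- commonBasisEnsemble(gen$curves)
  rep <- depthReport(ens)
  spec <- composeBoxplotFigure(ens, rep)
  types <- vapply(spec@layers, `[[`, character(1), "type")
  names <- vapply(spec@layers, function(l)
    if (is.null(l$name)) l$type else l$name, character(1))
  expect_equal(sum(types == "band"), 2L)
  expect_true(all(c("zone100", "zone50", "deepest", "median") %in% names))
  expect_equal(types[length(types)], "ruler")
  # bands precede strokes which precede the ruler
  expect_lt(max(which(types == "band")), min(which(names == "deepest")))
  hasOutlier <- any(zones(rep) == "outlier")
  expect_equal("outliers" %in% names, hasOutlier)

  # when every curve is interquartile the two band footprints coincide
  knots <- c(0, 0, 0, 0, 1, 1, 1, 1)
  same <- lapply(1:3, function(i)
    BSplineCurve(knots, cbind(x = 0:3, y = c(0, 30, 60, 90)),
                 rootId = paste0("s", i)))
  ensS <- commonBasisEnsemble(same)
  repS <- depthReport(ensS)
  expect_true(all(zones(repS) == "interquartile"))
  specS <- composeBoxplotFigure(ensS, repS)
  expect_identical(specS@layers[[1L]]$polygons, specS@layers[[2L]]$polygons)
})

test_that("time-line figure colors, bands and ruler follow the contract", {
  gen <- generateEnsemble(m = 8L, seed = 42L)
  ens <- commonBasisEnsemble(gen$curves)
  s <- sampleTimelinePoints(gen$curves, 1:5)
  surf <- fitTPS(s, tpsCentersFromEnsemble(ens))
  tls <- buildTimelines(gen$curves, surf, 1:5, gridRes = 64L)
  spec <- composeTimelineFigure(ens, tls)
  types <- vapply(spec@layers, `[[`, character(1), "type")
  tlLayers <- spec@layers[types == "timeline"]
  cols <- vapply(tlLayers, `[[`, character(1), "color")
  expect_length(unique(cols), 5L)
  expect_true(all(diff(luminance(cols)) < 0))   # earlier days brighter

  # mm ruler tick spacing is dpi / 25.4 pixels
  ruler <- spec@layers[[length(spec@layers)]]
  expect_equal(ruler$stepPx, 1200 / 25.4)
  expect_equal(ruler$days, 1:5)

  # a zero-variance stamp renders no confidence band
  flat <- new("TimelineSet", levels = 1, isocurves = list(list()),
              variances = 0, sigmas = 0, bands = list(list()),
              colors = timelineColors(1L), bbox = c(0, 1, 0, 1))
  specF <- composeTimelineFigure(ens, flat)
  typesF <- vapply(specF@layers, `[[`, character(1), "type")
  expect_equal(sum(typesF == "band"), 0L)
})

test_that("figure export is layered, deterministic and size-exact", {
  gen <- generateEnsemble(m = 5L, seed = 43L)
  ens <- commonBasisEnsemble(gen$curves)
  spec <- composeBoxplotFigure(ens, depthReport(ens))

  svg1 <- withr::local_tempfile(fileext = ".svg")
  svg2 <- withr::local_tempfile(fileext = ".svg")
  suppressMessages(exportFigure(spec, svg1, "svg"))
  suppressMessages(exportFigure(spec, svg2, "svg"))
  expect_identical(readBin(svg1, "raw", file.size(svg1)),
                   readBin(svg2, "raw", file.size(svg2)))
  doc <- xml2::read_xml(svg1)
  groups <- xml2::xml_find_all(doc, "//*[local-name() = 'g']")
  expect_length(groups, length(spec@layers))
  expect_match(as.character(xml2::xml_attr(groups[[1L]], "id")), "^layer01-")

  png <- withr::local_tempfile(fileext = ".png")
  spec2 <- initialize(spec, width = 320L, height = 240L)
  suppressMessages(exportFigure(spec2, png, "png"))
  img <- png::readPNG(png)
  expect_equal(dim(img)[1:2], c(240L, 320L))
})

test_that("indicator layer slots in below the ruler", {
  gen <- generateEnsemble(m = 8L, seed = 44L)
  ens <- commonBasisEnsemble(gen$curves)
  spec <- composeBoxplotFigure(ens, depthReport(ens))
  run <- validityIndicator(bootstrapMedians(ens, B = 25L, seed = 2L), ens)
  spec2 <- addIndicatorLayer(spec, run)
  types <- vapply(spec2@layers, `[[`, character(1), "type")
  expect_equal(types[length(types)], "ruler")
  expect_equal(types[length(types) - 1L], "indicator")
})
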