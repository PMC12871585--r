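test_that("loading conserves cells and rejects bad input", {
  expect_identical(simulateLoading(0, 100, seed = 1), integer(100))
  occ <- simulateLoading(4000, 4000, seed = 1)
  expect_identical(sum(occ), 4000L)
  expect_equal(mean(occ), 1.0)
  expect_error(simulateLoading(-1, 10), "nCells")
  expect_error(simulateLoading(2.5, 10), "integer")
  expect_error(simulateLoading(10, 0), "nMicrowells")
})

test_that("single-occupancy fraction converges to the Poisson limit", {
  ## closed form: P(k = 1) = e^-1 at lambda 1; binomial sampling SE
  occ <- simulateLoading(4000, 4000, seed = 1)
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / 4000)
  expect_lt(abs(mean(occ == 1) - p), 3 * se)
})

test_that("growth trajectories follow rounded exponentials", {
  g <- simulateGrowth(c(1L, 1L), list(medianRate = 1, sigma = 0,
                                      deathFraction = 0),
                      c(0, 24, 48, 72), seed = 1)
  expect_identical(g$counts[1, ], c(1L, 2L, 4L, 8L))
  ## empty microwells stay empty, with undefined rate
  g0 <- simulateGrowth(c(0L, 0L), list(), c(0, 24), seed = 1)
  expect_true(all(g0$counts == 0L))
  expect_true(all(is.na(g0$rTrue)))
  ## a trajectory reaching zero stays zero
  gd <- simulateGrowth(rep(1L, 200), list(medianRate = 1.5, sigma = 0.2,
                                          deathFraction = 1),
                       seq(0, 96, 24), seed = 2)
  hitZero <- apply(gd$counts, 1, function(v) any(v == 0))
  stillZero <- apply(gd$counts, 1, function(v) {
    z <- which(v == 0)
    length(z) == 0 || all(v[z[1]:length(v)] == 0)
  })
  expect_true(all(stillZero[hitZero]))
})

test_that("sampled division rates hit the configured median", {
  g <- simulateGrowth(rep(1L, 2000),
                      list(medianRate = 0.8, sigma = 0.35,
                           deathFraction = 0.05),
                      seq(0, 96, 4), seed = 7)
  expect_lt(abs(median(g$rTrue) - 0.8), 0.05)
})

test_that("scene geometry matches ground truth on a noiseless render", {
  sc <- emptyScene(6, 6, seed = 3)
  tm <- microwells(sc$truth)
  bf <- getFrame(sc$stack, 1, "BF")
  ## each true center is the local minimum of its brightfield cone
  for (i in seq_len(nrow(tm))) {
    y <- tm$y[i]; x <- tm$x[i]
    win <- bf[(y - 10):(y + 10), (x - 10):(x + 10)]
    expect_equal(unname(which(win == min(win), arr.ind = TRUE)[1, ]),
                 c(11, 11))
  }
})

test_that("drift translates frame content exactly before noise", {
  cfg <- sceneConfig(gridRows = 4, gridCols = 4, nTimepoints = 2,
                     loadingDensity = 1, driftPxPerT = c(2, 3), seed = 5)
  sc <- renderScene(cfg)
  f0 <- getFrame(sc$stack, 1, "BF")
  f1 <- getFrame(sc$stack, 2, "BF")
  n <- nrow(f0)
  ## interior of f1 equals f0 translated by (2, 3)
  expect_equal(f1[(1 + 2):n, (1 + 3):n], f0[1:(n - 2), 1:(n - 3)])
})

test_that("rendered secretion-positive set equals the planted label set", {
  cfg <- sceneConfig(gridRows = 10, gridCols = 10, nTimepoints = 3,
                     channels = c("BF", "IFNg"), occupancyMode = "coculture",
                     secretionModel = list(positiveFraction = 0.05,
                                           crossTalkFraction = 0),
                     seed = 9)
  sc <- renderScene(cfg)
  tm <- microwells(sc$truth)
  expect_identical(sum(tm$secretion_label == "positive"), 5L)
  ## exactly the 5 planted microwells have an elevated annulus at final t
  cyto <- getFrame(sc$stack, 3, "IFNg")
  elevated <- vapply(seq_len(nrow(tm)), function(i) {
    cr <- cropMicrowell(sc$stack, sc$grid, tm$id[i], 3, "IFNg")
    ringIntensity(cr, pitchPx = sc$grid@pitchPx) > 110  # background is 100
  }, logical(1))
  expect_identical(which(elevated), which(tm$secretion_label == "positive"))
})

test_that("identical seeds give bit-identical scenes", {
  cfg <- sceneConfig(gridRows = 3, gridCols = 3, nTimepoints = 2,
                     loadingDensity = 1, noise = list(sigma = 4), seed = 11)
  a <- renderScene(cfg)
  b <- renderScene(cfg)
  expect_identical(a$stack@data, b$stack@data)
  expect_identical(a$truth@counts, b$truth@counts)
  expect_identical(microwells(a$truth), microwells(b$truth))
})

test_that("scene truth conserves the loaded cell total", {
  cfg <- sceneConfig(gridRows = 5, gridCols = 5, nTimepoints = 1,
                     loadingDensity = 1.3, seed = 13)
  sc <- renderScene(cfg)
  expect_identical(sc$truth@nCellsLoaded,
                   sum(microwells(sc$truth)$occupancy_t0))
  expect_identical(sc$truth@nCellsLoaded, as.integer(round(1.3 * 25)))
})

test_that("config validation rejects impossible geometry", {
  expect_error(sceneConfig(pitchUm = 60, bottomDiamUm = 65), "pitch")
  expect_error(sceneConfig(nTimepoints = 0), "nTimepoints")
  expect_error(validObject(sceneConfig(
    secretionModel = list(positiveFraction = 1.4))), "fraction")
  expect_error(renderScene(sceneConfig(gridRows = 500, gridCols = 500)),
               "frame size overflow")
})

test_that("presets carry the study parameters", {
  n6 <- scenePreset("nalm6_default")
  expect_equal(n6@growthModel$medianRate, 0.8)
  expect_equal(n6@intervalHours, 4)
  pp <- scenePreset("peptide_pulsed")
  expect_equal(pp@secretionModel$positiveFraction, 0.40)
  expect_equal(pp@secretionModel$crossTalkFraction, 0.05)
  expect_identical(pp@occupancyMode, "coculture")
})
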