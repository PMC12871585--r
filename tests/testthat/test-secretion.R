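ann <- annulusSpec()

test_that("ring intensity matches the pixel-counting oracle", {
  expect_identical(ringIntensity(matrix(0, 33, 33)), 0)
  expect_identical(ringIntensity(matrix(9, 33, 33)), 9)
  ## ring of amplitude A over background B confined to the annulus:
  ## mean = B + A * (ring pixels / annulus pixels); the oracle crop is
  ## built by explicit pixel distances with a ring narrower than the band
  side <- 65; pitch <- 65
  rin <- ann$innerFrac * pitch; rout <- ann$outerFrac * pitch
  crop <- oracleRingCrop(side, rin + 3, rout - 3, background = 10,
                         amplitude = 40)
  nAnn <- sum(oracleRingCrop(side, rin, rout, 0, 1))
  nRing <- sum(oracleRingCrop(side, rin + 3, rout - 3, 0, 1))
  expect_equal(ringIntensity(crop, ann, pitch), 10 + 40 * nRing / nAnn)
  ## degenerate annulus at coarse pixel size
  expect_error(ringIntensity(matrix(0, 3, 3), ann, pitchPx = 1),
               "no pixels")
})

test_that("relative signal differences against t0", {
  expect_identical(relativeSignal(c(10, 25), 1), 0)
  expect_identical(relativeSignal(c(10, 25), 2), 15)
  expect_equal(relativeSignal(c(7, 9, 30)), c(0, 2, 23))
  expect_error(relativeSignal(c(1, 2), 5), "missing")
  ## invariance under a global additive offset
  I <- c(3, 8, 21)
  expect_equal(relativeSignal(I + 1000), relativeSignal(I))
})

test_that("symmetry score separates uniform rings from one-sided arcs", {
  side <- 65; pitch <- 65
  rin <- ann$innerFrac * pitch; rout <- ann$outerFrac * pitch
  ring <- oracleRingCrop(side, rin, rout, 0, 50)
  expect_lt(symmetryScore(ring, ann, pitch), 0.05)
  ## arc covering 2 of 8 sectors
  arc <- oracleArcCrop(side, rin, rout, 50, 0, pi / 2)
  expect_gt(symmetryScore(arc, ann, pitch), 1)
  ## flat zero background hits the sentinel
  expect_identical(symmetryScore(matrix(0, side, side), ann, pitch), Inf)
  ## invariant to rotation by the sector angle and to global scaling
  rot90 <- t(arc)[, rev(seq_len(side))]
  expect_equal(symmetryScore(rot90, ann, pitch),
               symmetryScore(arc, ann, pitch), tolerance = 1e-6)
  expect_equal(symmetryScore(arc * 3, ann, pitch),
               symmetryScore(arc, ann, pitch))
})

test_that("linear accumulation scenes produce linear relative signals", {
  cfg <- sceneConfig(gridRows = 4, gridCols = 4, nTimepoints = 4,
                     channels = c("BF", "IFNg"),
                     occupancyMode = "coculture",
                     secretionModel = list(positiveFraction = 0.25,
                                           ratePerHour = 10),
                     seed = 47)
  sc <- renderScene(cfg)
  sig <- quantifySecretion(sc$stack, sc$grid)
  tm <- microwells(sc$truth)
  pos <- tm$id[tm$secretion_label == "positive"]
  for (id in pos) {
    s <- sig$S[sig$microwell_id == id]
    ## S(t_k) = rate * hours_k within rounding of the rendered ring
    expect_equal(s, 10 * c(0, 4, 8, 12), tolerance = 0.05)
  }
  neg <- sig$S[!sig$microwell_id %in% pos]
  expect_true(all(abs(neg) < 1e-9))
})

test_that("the joint intensity + symmetry gate rejects cross-talk arcs", {
  cfg <- scenePreset("peptide_pulsed", gridRows = 6, gridCols = 6,
                     seed = 42)
  sc <- renderScene(cfg)
  sig <- quantifySecretion(sc$stack, sc$grid)
  cfgC <- scenePreset("peptide_pulsed", gridRows = 6, gridCols = 6,
                      seed = 43,
                      secretionModel = list(positiveFraction = 0,
                                            crossTalkFraction = 0))
  thr <- deriveSecretionThreshold(
    quantifySecretion(renderScene(cfgC)$stack, renderScene(cfgC)$grid))
  calls <- callPositive(sig, thr)
  tm <- microwells(sc$truth)
  lab <- tm$secretion_label[match(calls$microwell_id, tm$id)]
  expect_true(all(calls$positive[lab == "positive"]))
  expect_false(any(calls$positive[lab == "cross_talk_victim"]))
  expect_false(any(calls$positive[lab == "negative"]))
  ## positives are caught at the first accumulation step above threshold
  expect_true(all(calls$first_positive_t[lab == "positive"] == 1L))
  ## no threshold at all is a configuration error
  expect_error(callPositive(sig), "configuration error")
})

test_that("scenes without positives produce no calls under realistic noise", {
  cfg <- scenePreset("peptide_pulsed", gridRows = 10, gridCols = 10,
                     seed = 51, secretionModel = list(positiveFraction = 0,
                                                      crossTalkFraction = 0))
  sc <- renderScene(cfg)
  sig <- quantifySecretion(sc$stack, sc$grid)
  cfgC <- scenePreset("peptide_pulsed", gridRows = 10, gridCols = 10,
                      seed = 52, secretionModel = list(positiveFraction = 0,
                                                       crossTalkFraction = 0))
  scC <- renderScene(cfgC)
  thr <- deriveSecretionThreshold(quantifySecretion(scC$stack, scC$grid))
  calls <- callPositive(sig, thr)
  expect_lte(mean(calls$positive), 0.001)
})

test_that("per-well positive counts accumulate stepwise", {
  calls <- data.frame(microwell_id = 1:6,
                      positive = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                      first_positive_t = c(1L, 1L, NA, 2L, 3L, 1L),
                      first_positive_hours = c(4, 4, NA, 8, 12, 4))
  out <- positiveCountsOverTime(calls, wells = c(rep("A1", 3), rep("A2", 3)),
                                timepoints = 0:3)
  a1 <- out$n_positive[out$well == "A1"]
  a2 <- out$n_positive[out$well == "A2"]
  expect_identical(a1, c(0L, 2L, 2L, 2L))
  expect_identical(a2, c(0L, 1L, 2L, 3L))
  ## no positives -> all zeros
  none <- calls; none$positive <- FALSE; none$first_positive_t <- NA_integer_
  z <- positiveCountsOverTime(none, timepoints = 0:2)
  expect_true(all(z$n_positive == 0L))
})
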