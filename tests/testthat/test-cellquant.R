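test_that("counting recovers planted occupancies and filters artifacts", {
  ## empty crop -> no cells
  sc <- emptyScene(3, 3, seed = 2)
  crop <- cropMicrowell(sc$stack, sc$grid, 5, 1, "BF")
  expect_identical(nrow(countCells(crop, pixelSizeUm = 2)), 0L)

  ## three non-touching planted blobs -> count 3 with ~10 um diameters
  cfg <- sceneConfig(gridRows = 3, gridCols = 3, nTimepoints = 1,
                     occupancyMode = "coculture", seed = 23)
  sc3 <- renderScene(cfg)   # exactly 2 cells/microwell
  tm <- microwells(sc3$truth)
  cells <- countCells(cropMicrowell(sc3$stack, sc3$grid, tm$id[1], 1, "BF"),
                      pixelSizeUm = 2)
  expect_identical(nrow(cells), 2L)
  expect_true(all(cells$diameter_um > 5 & cells$diameter_um < 20))

  ## oversized artifact next to a real cell is removed by the size gate:
  ## one 10 um cell and one 25 um dark object planted in a flat crop
  crop <- matrix(1000, 65, 65)
  for (y in 1:65) for (x in 1:65) {
    if (sqrt((y - 20)^2 + (x - 20)^2) <= 10 / 2 / 2) crop[y, x] <- 750
    if (sqrt((y - 46)^2 + (x - 46)^2) <= 25 / 2 / 2) crop[y, x] <- 750
  }
  counted <- countCells(crop, pixelSizeUm = 2)
  expect_identical(nrow(counted), 1L)
  expect_lt(counted$diameter_um[1], 20)
})

test_that("count accuracy is at least 95% across loading densities", {
  for (lam in c(0.5, 1, 2)) {
    cfg <- sceneConfig(gridRows = 6, gridCols = 6, nTimepoints = 1,
                       loadingDensity = lam, seed = 100 + round(10 * lam))
    sc <- renderScene(cfg)
    tm <- microwells(sc$truth)
    got <- vapply(seq_len(nrow(tm)), function(i)
      nrow(countCells(cropMicrowell(sc$stack, sc$grid, tm$id[i], 1, "BF"),
                      pixelSizeUm = 2)), integer(1))
    expect_gte(mean(got == tm$occupancy_t0), 0.95)
  }
})

test_that("counting is deterministic and offset-invariant", {
  cfg <- sceneConfig(gridRows = 3, gridCols = 3, nTimepoints = 1,
                     loadingDensity = 1.5, noise = list(sigma = 4),
                     seed = 31)
  sc <- renderScene(cfg)
  crop <- cropMicrowell(sc$stack, sc$grid, 5, 1, "BF")
  a <- countCells(crop, pixelSizeUm = 2)
  b <- countCells(crop, pixelSizeUm = 2)
  expect_identical(a, b)
  shifted <- countCells(crop + 137, pixelSizeUm = 2)
  expect_identical(nrow(shifted), nrow(a))
  expect_equal(shifted$diameter_um, a$diameter_um)
})

test_that("fluorescence means use the brightfield mask with background subtraction", {
  cfg <- sceneConfig(gridRows = 3, gridCols = 3, nTimepoints = 1,
                     channels = c("BF", "GFP"), loadingDensity = 0.9,
                     markerModel = list(classes = "GFP", channels = "GFP",
                                        fractions = 1, amplitude = 300),
                     seed = 37)
  sc <- renderScene(cfg)
  tm <- microwells(sc$truth)
  id <- tm$id[which(tm$occupancy_t0 == 1)[1]]
  cells <- countCells(cropMicrowell(sc$stack, sc$grid, id, 1, "BF"),
                      pixelSizeUm = 2)
  gfp <- cropMicrowell(sc$stack, sc$grid, id, 1, "GFP")
  out <- cellIntensities(cells, list(GFP = gfp))
  ## planted additive brightness is recovered (mask edge pixels only dilute)
  expect_gt(out$GFP_mean, 0.8 * 300)
  expect_lt(out$GFP_mean, 1.05 * 300)
  ## a uniform channel reads 0 after background subtraction
  flat <- cellIntensities(cells, list(U = matrix(7, nrow(gfp), ncol(gfp))))
  expect_equal(flat$U_mean, 0)
  ## empty record list passes through unchanged
  none <- countCells(matrix(1000, 65, 65), pixelSizeUm = 2)
  expect_identical(nrow(cellIntensities(none, list(U = matrix(0, 65, 65)))),
                   0L)
  ## shape mismatch is an error
  expect_error(cellIntensities(cells, list(U = matrix(0, 3, 3))),
               "shape")
})

test_that("marker classification reproduces scene truth on clean renders", {
  cfg <- sceneConfig(gridRows = 5, gridCols = 5, nTimepoints = 1,
                     channels = c("BF", "GFP", "mCherry"),
                     loadingDensity = 1,
                     markerModel = list(classes = c("GFP", "mCherry"),
                                        channels = c("GFP", "mCherry"),
                                        fractions = c(0.5, 0.5),
                                        amplitude = 300),
                     seed = 21)
  sc <- renderScene(cfg)
  tm <- microwells(sc$truth)
  rules <- list(markerRule("GFP", 150), markerRule("mCherry", 150),
                markerRule("GFP", 150, "-", "GFP-"),
                markerRule("mCherry", 150, "-", "mCherry-"))
  for (i in which(tm$occupancy_t0 > 0)) {
    cells <- countCells(cropMicrowell(sc$stack, sc$grid, tm$id[i], 1, "BF"),
                        pixelSizeUm = 2)
    if (nrow(cells) == 0) next
    crops <- list(
      GFP = cropMicrowell(sc$stack, sc$grid, tm$id[i], 1, "GFP"),
      mCherry = cropMicrowell(sc$stack, sc$grid, tm$id[i], 1, "mCherry"))
    cells <- classifyCells(cellIntensities(cells, crops), rules)
    if (tm$marker_class[i] == "GFP") {
      expect_true(all(cells[["GFP+"]] & cells[["mCherry-"]]))
    } else {
      expect_true(all(cells[["mCherry+"]] & cells[["GFP-"]]))
    }
  }
  ## rule against an unmeasured channel is an error
  cells <- countCells(cropMicrowell(sc$stack, sc$grid, tm$id[1], 1, "BF"),
                      pixelSizeUm = 2)
  expect_error(classifyCells(cells, list(markerRule("CD8", 1))),
               "no measured intensities")
})

test_that("crop mean intensity is plain arithmetic", {
  expect_identical(cropMeanIntensity(matrix(0, 5, 5)), 0)
  expect_identical(cropMeanIntensity(matrix(7, 5, 5)), 7)
  cb <- matrix(c(0, 10), 6, 6)   # exact half-and-half checkerboard columns
  expect_identical(cropMeanIntensity(cb), 5)
})
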