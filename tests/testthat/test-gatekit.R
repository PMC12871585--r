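test_that("single-node trees select all microwells", {
  ft <- randomFeatureTable(50, seed = 3)
  tr <- applyGateTree(ft, gateNode("all"))
  expect_identical(tr@count, 50L)
  expect_identical(tr@memberIds, 1:50)
  expect_equal(tr@fractionOfParent, 100)
})

test_that("gate-tree evaluation equals brute-force row filtering", {
  ## randomized 1,000-microwell fixtures, 3-level trees, exhaustive
  ## member-set equality against plain vectorized subsetting
  for (seed in 1:3) {
    ft <- randomFeatureTable(1000, nT = 3, seed = seed)
    tree <- gateNode("all", "", list(
      gateNode("singles", "count@t0 == 1", list(
        gateNode("bright_any", "gfp@any(t>=4) >= 60", list(
          gateNode("growing", "r@last >= 0.5")))))))
    got <- applyGateTree(ft, tree)

    ## brute-force oracle on the wide per-microwell view
    t0 <- ft[ft$timepoint == 0, ]
    tl <- ft[ft$timepoint == 2, ]
    lv1 <- t0$microwell_id[t0$count == 1]
    bright <- unique(ft$microwell_id[ft$hours >= 4 & ft$gfp >= 60])
    lv2 <- intersect(lv1, bright)
    lv3 <- intersect(lv2, tl$microwell_id[tl$r >= 0.5])

    n1 <- got@children[[1]]
    n2 <- n1@children[[1]]
    n3 <- n2@children[[1]]
    expect_identical(n1@memberIds, sort(as.integer(lv1)))
    expect_identical(n2@memberIds, sort(as.integer(lv2)))
    expect_identical(n3@memberIds, sort(as.integer(lv3)))
    ## monotonicity down the path
    expect_true(n1@count >= n2@count && n2@count >= n3@count)
    ## fraction bookkeeping
    expect_equal(n2@fractionOfParent, 100 * n2@count / n1@count)
  }
})

test_that("sibling gates are evaluated independently of order", {
  ft <- randomFeatureTable(300, seed = 9)
  a <- gateNode("low", "gfp@t0 < 50")
  b <- gateNode("high", "gfp@t0 >= 50")
  t1 <- applyGateTree(ft, gateNode("all", "", list(a, b)))
  t2 <- applyGateTree(ft, gateNode("all", "", list(b, a)))
  expect_identical(t1@children[[1]]@memberIds, t2@children[[2]]@memberIds)
  expect_identical(sort(c(t1@children[[1]]@memberIds,
                          t1@children[[2]]@memberIds)),
                   t1@memberIds)
})

test_that("predicate errors name the offending piece", {
  ft <- randomFeatureTable(10, seed = 1)
  expect_error(applyGateTree(ft, gateNode("x", "nope@t0 > 1")),
               "unknown feature")
  expect_error(applyGateTree(ft, gateNode("x", "count@t9 > 1")),
               "no matching timepoint")
  expect_error(applyGateTree(ft, gateNode("x", "count ~ 1")),
               "cannot parse")
})

test_that("gate fractions reproduce printed-percentage arithmetic", {
  expect_identical(gateFraction(47597, 137758), 35)
  expect_identical(gateFraction(16070, 47597), 34)
  expect_identical(gateFraction(107, 16070, digits = 1), 0.7)
  expect_identical(gateFraction(0, 500), 0)
  expect_error(gateFraction(1, 0), "zero parent")
  ## GateNode method
  ft <- randomFeatureTable(40, seed = 2)
  tr <- applyGateTree(ft, gateNode("all", "",
                                   list(gateNode("s", "count@t0 == 1"))))
  ch <- tr@children[[1]]
  expect_identical(gateFraction(ch, digits = 1),
                   roundHalfUp(100 * ch@count / 40, 1))
})

test_that("expected library hit rate is plain proportion arithmetic", {
  expect_identical(expectedLibraryHitRate(100, 1), 1)
  expect_identical(expectedLibraryHitRate(100, 100), 100)
  expect_identical(expectedLibraryHitRate(50, 2), 4)
  expect_error(expectedLibraryHitRate(10, 11), "exceed")
  expect_error(expectedLibraryHitRate(0, 1), "librarySize")
})

## a small grid with a known accessibility ring for pick-list tests
mkPickGrid <- function() {
  pts <- expand.grid(row = 1:9, col = 1:9)
  info <- data.frame(id = seq_len(nrow(pts)), row = pts$row, col = pts$col,
                     y = pts$row * 10, x = pts$col * 10, score = 1,
                     accessible = TRUE)
  g <- new("MicrowellGrid", info = info,
           shifts = matrix(c(0, 0, 2, 3), 2, 2, byrow = TRUE),
           pitchPx = 10, pixelSizeUm = 2, thetaDeg = 0)
  accessible(g) <- accessibleMask(g, plateLayout(accessibleAreaFraction = 0.75))
  g
}

test_that("pick lists interleave labels and never leave the accessible set", {
  g <- mkPickGrid()
  acc <- microwells(g)$id[accessible(g)]
  sel <- acc[1:4]
  pl <- buildPickList(sel, g, labels = c("GFP+", "GFP+", "mCherry+",
                                         "mCherry+"))
  expect_identical(pl$gate_path, c("GFP+", "mCherry+", "GFP+", "mCherry+"))
  expect_true(all(pl$microwell_id %in% acc))
  ## stage coordinates include the last registered shift, in micrometers
  i <- match(pl$microwell_id[1], microwells(g)$id)
  expect_equal(pl$y_um[1], (microwells(g)$y[i] + 2) * 2)
  expect_equal(pl$x_um[1], (microwells(g)$x[i] + 3) * 2)
  ## deposition wells unique
  expect_false(anyDuplicated(pl$deposition_well) > 0)
})

test_that("inaccessible or unknown selections are hard errors", {
  g <- mkPickGrid()
  inacc <- microwells(g)$id[!accessible(g)]
  expect_error(buildPickList(inacc[1], g), "inaccessible")
  expect_error(buildPickList(99999, g), "unknown microwell")
  ## adversarial: an accessible selection mixed with one inaccessible id
  acc <- microwells(g)$id[accessible(g)]
  expect_error(buildPickList(c(acc[1], inacc[1]), g), "inaccessible")
  ## capacity
  expect_error(buildPickList(acc[1:5], g,
                             depositionLayout = list(rows = 1L, cols = 4L)),
               "capacity")
})

test_that("blank controls are empty accessible microwells at seeded positions", {
  g <- mkPickGrid()
  acc <- microwells(g)$id[accessible(g)]
  sel <- acc[1:10]
  empty <- acc[21:40]
  p1 <- buildPickList(sel, g, nBlanks = 2, seed = 7, emptyIds = empty)
  p2 <- buildPickList(sel, g, nBlanks = 2, seed = 7, emptyIds = empty)
  expect_identical(p1, p2)                        # deterministic given seed
  expect_identical(sum(p1$is_blank), 2L)
  expect_true(all(p1$microwell_id[p1$is_blank] %in% empty))
  expect_true(all(p1$microwell_id %in% acc))
  expect_identical(nrow(p1), 12L)
  ## blanks must exist among empty accessible microwells
  expect_error(buildPickList(sel, g, nBlanks = 3, emptyIds = integer()),
               "not enough empty")
  ## adversarial: inaccessible empties are not eligible
  inaccEmpty <- microwells(g)$id[!accessible(g)][1:3]
  expect_error(buildPickList(sel, g, nBlanks = 3, emptyIds = inaccEmpty),
               "not enough empty")
})
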