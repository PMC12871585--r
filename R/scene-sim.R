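#' Construct a synthetic scene configuration
#'
#' Defaults reflect the array geometry (65 um microwell bottoms on a 130 um
#' pitch), a 4-hour imaging cadence and a desk-scale pixel size of 2 um/px
#' (the instrument natively images at 0.5 um/px; pixel size is a free
#' parameter). See [SceneConfig-class] for the meaning of each field and
#' [scenePreset()] for study presets.
#'
#' @param lattice `"square"` (default) or `"hex"`.
#' @param pitchUm,bottomDiamUm microwell pitch and bottom diameter, um.
#' @param pixelSizeUm rendered pixel size, um/px.
#' @param gridRows,gridCols lattice dimensions.
#' @param nTimepoints,intervalHours imaging schedule.
#' @param channels channel names; `"BF"` must be included.
#' @param occupancyMode `"poisson"` or `"coculture"`.
#' @param loadingDensity mean cells/microwell for Poisson loading.
#' @param growthModel,secretionModel,markerModel,noise model parameter lists
#'   (partial lists are merged into the defaults).
#' @param driftPxPerT per-timepoint stage drift (dy, dx), integer pixels.
#' @param seed integer seed; every random choice in the scene flows from it.
#' @return a validated [SceneConfig-class].
#' @examples
#' cfg <- sceneConfig(gridRows = 4, gridCols = 4, nTimepoints = 2)
#' @export
sceneConfig <- function(lattice = "square", pitchUm = 130, bottomDiamUm = 65,
                        pixelSizeUm = 2, gridRows = 10L, gridCols = 10L,
                        nTimepoints = 1L, intervalHours = 4,
                        channels = "BF", occupancyMode = "poisson",
                        loadingDensity = 1,
                        growthModel = list(), secretionModel = list(),
                        markerModel = NULL,
                        driftPxPerT = c(0, 0), noise = list(), seed = 1L) {
  gDef <- list(medianRate = 0.8, sigma = 0.35, deathFraction = 0.05)
  sDef <- list(positiveFraction = 0, ratePerHour = 10, crossTalkFraction = 0,
               crossTalkRel = 0.6, arcDeg = 90)
  nDef <- list(sigma = 0, bfBackground = 1000, fluorBackground = 100)
  gm <- modifyList(gDef, growthModel)
  sm <- modifyList(sDef, secretionModel)
  nm <- modifyList(nDef, noise)
  if (!"BF" %in% channels) stop("channels must include 'BF'")
  new("SceneConfig", lattice = lattice, pitchUm = pitchUm,
      bottomDiamUm = bottomDiamUm, pixelSizeUm = pixelSizeUm,
      gridRows = as.integer(gridRows), gridCols = as.integer(gridCols),
      nTimepoints = as.integer(nTimepoints), intervalHours = intervalHours,
      channels = channels, occupancyMode = occupancyMode,
      loadingDensity = loadingDensity, growthModel = gm,
      secretionModel = sm, markerModel = markerModel,
      driftPxPerT = driftPxPerT, noise = nm, seed = as.integer(seed))
}

#' Named scene presets
#'
#' `"nalm6_default"` emulates a suspension-line proliferation experiment:
#' single-cell Poisson loading (lambda = 1), 4-day time-lapse at 4-hour
#' intervals, and lognormal division rates with median 0.8 divisions/day.
#' `"peptide_pulsed"` emulates a peptide-stimulated co-culture cytokine
#' assay: every microwell holds a T cell/APC pair, 40% of microwells secrete
#' (uniform ring accumulation in the `IFNg` channel), and 5% are cross-talk
#' victims showing a one-sided arc captured from a neighbor.
#'
#' @param name `"nalm6_default"` or `"peptide_pulsed"`.
#' @param ... overrides forwarded to [sceneConfig()] (e.g. `gridRows`,
#'   `seed`).
#' @return a [SceneConfig-class].
#' @export
scenePreset <- function(name = c("nalm6_default", "peptide_pulsed"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    nalm6_default = list(
      nTimepoints = 25L, intervalHours = 4, channels = "BF",
      occupancyMode = "poisson", loadingDensity = 1,
      growthModel = list(medianRate = 0.8, sigma = 0.35,
                         deathFraction = 0.05)),
    peptide_pulsed = list(
      nTimepoints = 7L, intervalHours = 4, channels = c("BF", "IFNg"),
      occupancyMode = "coculture",
      secretionModel = list(positiveFraction = 0.40, ratePerHour = 10,
                            crossTalkFraction = 0.05, crossTalkRel = 0.6,
                            arcDeg = 90),
      noise = list(sigma = 5)))
  do.call(sceneConfig, modifyList(base, list(...)))
}

#' Simulate stochastic cell loading into microwells
#'
#' Each cell independently lands in a uniformly chosen microwell, i.e. the
#' occupancy vector is a multinomial draw with equal site probabilities —
#' which converges to Poisson(lambda = nCells / nMicrowells) for large
#' arrays, the model used to optimize loading density.
#'
#' @param nCells total number of cells loaded (non-negative integer).
#' @param nMicrowells number of microwells (positive integer).
#' @param seed optional integer seed.
#' @return integer vector of length `nMicrowells`; sums to `nCells`.
#' @examples
#' occ <- simulateLoading(4000, 4000, seed = 1)
#' mean(occ == 1)  # ~ exp(-1)
#' @export
simulateLoading <- function(nCells, nMicrowells, seed = NULL) {
  nCells <- .checkCount(nCells, "nCells", min = 0)
  nMicrowells <- .checkCount(nMicrowells, "nMicrowells", min = 1)
  if (!is.null(seed)) set.seed(seed)
  if (nCells == 0) return(integer(nMicrowells))
  tabulate(sample.int(nMicrowells, nCells, replace = TRUE), nMicrowells)
}

#' Simulate clonal growth trajectories
#'
#' Each occupied microwell draws a division rate r (divisions/day) once from
#' a lognormal distribution with the configured median; a `deathFraction` of
#' occupied microwells have their rate negated (cell death). Counts follow
#' deterministic exponential growth, rounded half-up:
#' `n(t) = round(n(0) * 2^(r * t_days))`; a trajectory that reaches 0 stays
#' 0, and empty microwells stay empty.
#'
#' @param occupancy integer vector of cells per microwell at t0.
#' @param growthModel list with `medianRate`, `sigma`, `deathFraction`
#'   (see [sceneConfig()]).
#' @param timesHours strictly increasing acquisition times, hours.
#' @param seed optional integer seed.
#' @return list with `counts` (integer matrix `[n, T]`) and `rTrue`
#'   (divisions/day; `NA` for empty microwells).
#' @examples
#' g <- simulateGrowth(rep(1L, 5), list(medianRate = 0.8, sigma = 0.3,
#'                     deathFraction = 0), seq(0, 96, 24), seed = 1)
#' @export
simulateGrowth <- function(occupancy, growthModel, timesHours, seed = NULL) {
  if (any(occupancy < 0) || any(occupancy != round(occupancy)))
    stop("occupancy must be non-negative integers")
  if (length(timesHours) < 1 || any(diff(timesHours) <= 0))
    stop("timesHours must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  n <- length(occupancy)
  gm <- modifyList(list(medianRate = 0.8, sigma = 0.35, deathFraction = 0.05),
                   growthModel)
  r <- rlnorm(n, meanlog = log(gm$medianRate), sdlog = gm$sigma)
  dying <- runif(n) < gm$deathFraction
  r[dying] <- -r[dying]
  tDays <- timesHours / 24
  counts <- floor(outer(occupancy, rep(1, length(tDays))) *
                    2^(outer(r, tDays)) + 0.5)
  ## absorbing zero: once a trajectory hits 0 it never recovers
  if (ncol(counts) > 1)
    for (k in 2:ncol(counts))
      counts[counts[, k - 1] == 0, k] <- 0
  counts[occupancy == 0, ] <- 0
  r[occupancy == 0] <- NA_real_
  storage.mode(counts) <- "integer"
  list(counts = counts, rTrue = r)
}

## lattice centers (t0, unshifted) for a config; returns data.frame + frame dims
.sceneGeometry <- function(config) {
  pitchPx <- config@pitchUm / config@pixelSizeUm
  rowPitch <- if (config@lattice == "hex") pitchPx * sqrt(3) / 2 else pitchPx
  margin <- ceiling(pitchPx) +
    max(abs(config@driftPxPerT)) * (config@nTimepoints - 1)
  rows <- rep(seq_len(config@gridRows), each = config@gridCols)
  cols <- rep(seq_len(config@gridCols), config@gridRows)
  y <- margin + (rows - 0.5) * rowPitch
  x <- margin + (cols - 0.5) * pitchPx
  if (config@lattice == "hex")
    x <- x + (rows %% 2) * pitchPx / 2
  ## stamps are placed at integer pixels; truth records the rendered centers
  y <- round(y)
  x <- round(x)
  H <- ceiling(max(y) + margin)
  W <- ceiling(max(x) + margin + (config@lattice == "hex") * pitchPx / 2)
  if (H * W > 5e7)
    stop(sprintf(paste0("frame size overflow: configured grid needs ",
                        "%d x %d px; reduce the grid or increase ",
                        "pixelSizeUm"), H, W))
  list(df = data.frame(id = seq_along(y), row = rows, col = cols,
                       y = y, x = x),
       H = H, W = W, pitchPx = pitchPx)
}

## radially symmetric brightfield stamp of one conical microwell:
## smooth dark cone toward the center plus a darker bottom disk
.coneStamp <- function(pitchPx, bottomDiamPx) {
  s <- .odd(pitchPx)
  rm <- .radiusMap(s)$r
  rOpen <- 0.48 * pitchPx
  rBottom <- bottomDiamPx / 2
  -300 * pmax(1 - rm / rOpen, 0) - 150 * (rm <= rBottom)
}

## add `stamp` into frame `M` centered at integer (cy, cx); clips at edges
.addStamp <- function(M, stamp, cy, cx) {
  s <- nrow(stamp)
  h <- (s - 1L) %/% 2L
  y0 <- cy - h; y1 <- cy + h; x0 <- cx - h; x1 <- cx + h
  sy0 <- max(1L, 2L - y0); sx0 <- max(1L, 2L - x0)
  sy1 <- s - max(0L, y1 - nrow(M)); sx1 <- s - max(0L, x1 - ncol(M))
  yy <- max(1L, y0):min(nrow(M), y1); xx <- max(1L, x0):min(ncol(M), x1)
  M[yy, xx] <- M[yy, xx] + stamp[sy0:sy1, sx0:sx1]
  M
}

#' Render a synthetic microwell-array scene with ground truth
#'
#' Produces a complete emulation of the instrument output: a TCZYX
#' [FrameStack-class] in which microwells appear as dark cones in
#' brightfield, cells as dark blobs at the microwell bottoms (with matching
#' additive fluorescence in any marker channels), and cytokine secretion as
#' annular wall fluorescence accumulating linearly in the `IFNg` channel —
#' uniform rings for true positives, one-sided arcs for cross-talk victims.
#' Whole-frame integer stage drift is applied per timepoint before Gaussian
#' noise. The returned ground truth is consistent with the rendered pixels
#' by construction.
#'
#' @param config a [SceneConfig-class]; `config@seed` drives all randomness.
#' @return list with `stack` ([FrameStack-class]), `grid` (ground-truth
#'   [MicrowellGrid-class]) and `truth` ([SceneTruth-class]).
#' @examples
#' sc <- renderScene(sceneConfig(gridRows = 3, gridCols = 3,
#'                               nTimepoints = 2, seed = 7))
#' dim(sc$stack)
#' @export
renderScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  set.seed(config@seed)
  geo <- .sceneGeometry(config)
  df <- geo$df
  n <- nrow(df)
  nT <- config@nTimepoints
  times <- (seq_len(nT) - 1) * config@intervalHours

  ## --- loading -------------------------------------------------------------
  if (config@occupancyMode == "coculture") {
    occupancy <- rep(2L, n)
  } else {
    occupancy <- simulateLoading(round(config@loadingDensity * n), n)
  }

  ## --- growth --------------------------------------------------------------
  growth <- simulateGrowth(occupancy, config@growthModel, times)
  counts <- growth$counts

  ## --- secretion labels (planted with exact counts) ------------------------
  sm <- config@secretionModel
  occIdx <- which(occupancy > 0)
  lab <- rep("negative", n)
  nPos <- round(sm$positiveFraction * length(occIdx))
  nCT <- round(sm$crossTalkFraction * length(occIdx))
  pick <- sample(occIdx, nPos + nCT)
  lab[pick[seq_len(nPos)]] <- "positive"
  if (nCT > 0) lab[pick[nPos + seq_len(nCT)]] <- "cross_talk_victim"
  arcStart <- runif(n, 0, 2 * pi)

  ## --- marker classes ------------------------------------------------------
  mm <- config@markerModel
  marker <- rep(NA_character_, n)
  if (config@occupancyMode == "coculture") {
    marker[] <- "coculture"
  } else if (!is.null(mm)) {
    marker[occIdx] <- sample(mm$classes, length(occIdx), replace = TRUE,
                             prob = mm$fractions)
  }

  ## --- per-microwell cell positions (static; cells appear as counts grow) --
  pitchPx <- geo$pitchPx
  rBottom <- config@bottomDiamUm / 2 / config@pixelSizeUm
  cellR <- max(1, 10 / config@pixelSizeUm / 2)      # 10 um cell blobs -> px
  maxCount <- pmin(apply(counts, 1, max), 60L)
  cellPos <- vector("list", n)
  for (i in seq_len(n)) {
    m <- maxCount[i]
    if (m == 0) next
    ## cells are solid: resample positions that would overlap an earlier
    ## cell (up to 25 tries; crowded colonies are allowed to touch)
    pos <- matrix(0, m, 2)
    rmax <- max(cellR + 0.5, rBottom - cellR - 1)
    for (j in seq_len(m)) {
      for (try in 1:25) {
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * rmax
        p <- c(rad * sin(ang), rad * cos(ang))
        if (j == 1 || all(sqrt(colSums((t(pos[seq_len(j - 1), ,
              drop = FALSE]) - p)^2)) > 2 * cellR + 1)) break
      }
      pos[j, ] <- p
    }
    cellPos[[i]] <- pos
  }

  ## --- precomputed stamps ---------------------------------------------------
  stampBF <- .coneStamp(pitchPx, config@bottomDiamUm / config@pixelSizeUm)
  s <- nrow(stampBF)
  rmap <- .radiusMap(s)
  rIn <- 0.25 * pitchPx                    # wall annulus: defaults tied to
  rOut <- 0.475 * pitchPx                  # the cone geometry (see vignette)
  ringMask <- rmap$r >= rIn & rmap$r <= rOut
  ringAngle <- atan2(rmap$dy, rmap$dx) + pi      # [0, 2pi)
  cellOff <- which(.radiusMap(2 * ceiling(cellR) + 1)$r <= cellR,
                   arr.ind = TRUE) - (ceiling(cellR) + 1)

  drift <- cbind(round(config@driftPxPerT[1] * (seq_len(nT) - 1)),
                 round(config@driftPxPerT[2] * (seq_len(nT) - 1)))

  hasIFN <- "IFNg" %in% config@channels
  nC <- length(config@channels)
  A <- array(0, c(nT, nC, 1L, geo$H, geo$W))
  nz <- config@noise

  arcW <- sm$arcDeg * pi / 180
  for (t in seq_len(nT)) {
    cy <- as.integer(round(df$y)) + drift[t, 1]
    cx <- as.integer(round(df$x)) + drift[t, 2]
    for (ci in seq_len(nC)) {
      ch <- config@channels[ci]
      M <- matrix(if (ch == "BF") nz$bfBackground else nz$fluorBackground,
                  geo$H, geo$W)
      for (i in seq_len(n)) {
        if (ch == "BF") {
          M <- .addStamp(M, stampBF, cy[i], cx[i])
        } else if (ch == "IFNg" && lab[i] != "negative") {
          amp <- sm$ratePerHour * times[t]
          stampS <- matrix(0, s, s)
          if (lab[i] == "positive") {
            stampS[ringMask] <- amp
          } else {                               # cross-talk arc (one-sided)
            dAng <- (ringAngle - arcStart[i]) %% (2 * pi)
            stampS[ringMask & dAng <= arcW] <- amp * sm$crossTalkRel
          }
          M <- .addStamp(M, stampS, cy[i], cx[i])
        }
        ## cells: dark in BF, bright in their marker channel
        nCells <- min(counts[i, t], maxCount[i])
        if (nCells > 0) {
          delta <- if (ch == "BF") -250
            else if (!is.null(mm) && ch %in% mm$channels &&
                     !is.na(marker[i]) &&
                     identical(ch, mm$channels[match(marker[i], mm$classes)]))
              mm$amplitude else 0
          if (delta != 0) {
            pos <- cellPos[[i]][seq_len(nCells), , drop = FALSE]
            for (j in seq_len(nCells)) {
              yy <- cy[i] + round(pos[j, 1]) + cellOff[, 1]
              xx <- cx[i] + round(pos[j, 2]) + cellOff[, 2]
              ok <- yy >= 1 & yy <= geo$H & xx >= 1 & xx <= geo$W
              M[cbind(yy[ok], xx[ok])] <- M[cbind(yy[ok], xx[ok])] + delta
            }
          }
        }
      }
      if (nz$sigma > 0)
        M <- M + matrix(rnorm(length(M), 0, nz$sigma), nrow(M))
      A[t, ci, 1L, , ] <- pmax(M, 0)
    }
  }

  stack <- frameStack(A, channels = config@channels, timesHours = times,
                      pixelSizeUm = config@pixelSizeUm)
  info <- data.frame(id = df$id, row = df$row, col = df$col,
                     y = df$y, x = df$x, score = 1,
                     accessible = TRUE)
  grid <- new("MicrowellGrid", info = info, shifts = drift,
              pitchPx = pitchPx, pixelSizeUm = config@pixelSizeUm,
              thetaDeg = 0)
  mw <- data.frame(df, occupancy_t0 = occupancy, r_true = growth$rTrue,
                   secretion_label = lab, marker_class = marker)
  truth <- new("SceneTruth", microwells = mw, counts = counts,
               timesHours = times, drift = drift,
               nCellsLoaded = sum(occupancy))
  list(stack = stack, grid = grid, truth = truth)
}
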