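#' Specification of the secretion-ring annulus
#'
#' The wall band between the cell zone and the microwell rim, expressed as
#' radius fractions of the lattice pitch. Defaults tie the inner radius to
#' half the bottom diameter (`0.5 * 65 / 130 = 0.25`) and the outer radius
#' to 95% of the half-pitch (`0.475`), so the annulus encloses the conical
#' walls where capture antibodies accumulate cytokine.
#'
#' @param innerFrac,outerFrac annulus radii as fractions of the pitch;
#'   `0 < inner < outer <= 0.5`.
#' @param nSectors number of equal angular sectors used by
#'   [symmetryScore()] (default 8, minimum 4).
#' @return list of class `"AnnulusSpec"`.
#' @export
annulusSpec <- function(innerFrac = 0.25, outerFrac = 0.475, nSectors = 8L) {
  stopifnot(innerFrac > 0, innerFrac < outerFrac, outerFrac <= 0.5,
            nSectors >= 4)
  structure(list(innerFrac = innerFrac, outerFrac = outerFrac,
                 nSectors = as.integer(nSectors)), class = "AnnulusSpec")
}

.annulusMasks <- function(side, annulus, pitchPx) {
  rm <- .radiusMap(side)
  inA <- rm$r >= annulus$innerFrac * pitchPx &
         rm$r <= annulus$outerFrac * pitchPx
  if (!any(inA))
    stop("annulus contains no pixels at this pixel size")
  ang <- (atan2(rm$dy, rm$dx) + pi) %% (2 * pi)
  sector <- pmin(floor(ang / (2 * pi / annulus$nSectors)) + 1L,
                 annulus$nSectors)
  list(inA = inA, sector = sector)
}

#' Mean secretion-ring intensity of a crop
#'
#' Mean fluorescence over the annulus that encloses the microwell walls.
#'
#' @param crop square cytokine-channel crop centered on the microwell.
#' @param annulus an [annulusSpec()].
#' @param pitchPx lattice pitch in pixels (sets the absolute annulus
#'   radii; defaults to the crop side).
#' @return scalar mean intensity I.
#' @export
ringIntensity <- function(crop, annulus = annulusSpec(),
                          pitchPx = nrow(crop)) {
  stopifnot(is.matrix(crop), nrow(crop) == ncol(crop))
  m <- .annulusMasks(nrow(crop), annulus, pitchPx)
  mean(crop[m$inA])
}

#' Relative secretion signal
#'
#' `S(t_x) = I(t_x) - I(t_0)`: the ring intensity at timepoint t_x relative
#' to the initial timepoint, which cancels any global additive background.
#'
#' @param I numeric vector of per-timepoint ring intensities (t0 first).
#' @param tIdx timepoint index (1-based); omit for the whole series.
#' @return S at `tIdx`, or the full S series (with `S[1] == 0` exactly).
#' @export
relativeSignal <- function(I, tIdx = NULL) {
  if (length(I) < 1) stop("intensity series is empty")
  if (is.null(tIdx)) return(I - I[1])
  if (tIdx < 1 || tIdx > length(I)) stop("timepoint ", tIdx, " missing")
  I[tIdx] - I[1]
}

#' Rotational-symmetry score of a secretion pattern
#'
#' Partitions the wall annulus into equal angular sectors and returns the
#' coefficient of variation of the sector means (SD / mean). A genuine
#' secretion ring is rotationally uniform (score near 0) whereas cytokine
#' captured from an adjacent microwell forms a one-sided arc with a large
#' score, which is the basis of the false-positive filter. A non-positive
#' sector-mean average returns the `Inf` sentinel.
#'
#' For gating, the score is evaluated on the background-cancelled temporal
#' difference crop (t minus t0) — see [quantifySecretion()] — so that the
#' score is independent of the additive background level.
#'
#' @param crop square crop (raw or difference) centered on the microwell.
#' @param annulus an [annulusSpec()].
#' @param pitchPx lattice pitch in pixels (defaults to the crop side).
#' @return dimensionless score >= 0 (possibly `Inf`).
#' @export
symmetryScore <- function(crop, annulus = annulusSpec(),
                          pitchPx = nrow(crop)) {
  stopifnot(is.matrix(crop), nrow(crop) == ncol(crop))
  m <- .annulusMasks(nrow(crop), annulus, pitchPx)
  sec <- vapply(seq_len(annulus$nSectors), function(k)
    mean(crop[m$inA & m$sector == k]), numeric(1))
  mu <- mean(sec)
  if (!is.finite(mu) || mu <= 0) return(Inf)
  sd(sec) / mu
}

#' Quantify secretion signals for every microwell of a stack
#'
#' For each microwell and timepoint: the ring intensity I(t), the relative
#' signal S(t) = I(t) - I(t0), and the rotational-symmetry score computed
#' on the temporal difference crop (crop at t minus the registered crop at
#' t0), which cancels the static background so that arc asymmetry is
#' detected regardless of amplitude. At t0 the difference is identically
#' zero and the score is the `Inf` sentinel (S(t0) = 0, so t0 can never be
#' a calling timepoint).
#'
#' @param stack a [FrameStack-class].
#' @param grid a registered [MicrowellGrid-class].
#' @param channel cytokine channel name (default `"IFNg"`).
#' @param annulus an [annulusSpec()].
#' @return data.frame: `microwell_id`, `timepoint` (0-based), `hours`,
#'   `I`, `S`, `sym`.
#' @export
quantifySecretion <- function(stack, grid, channel = "IFNg",
                              annulus = annulusSpec()) {
  ids <- grid@info$id
  nT <- dim(stack)[1]
  times <- timesHours(stack)
  side <- as.integer(ceiling(grid@pitchPx))
  masks <- .annulusMasks(side, annulus, grid@pitchPx)
  nSec <- annulus$nSectors
  secIdx <- lapply(seq_len(nSec), function(k)
    which(masks$inA & masks$sector == k))
  ringIdx <- which(masks$inA)

  h <- (side - 1L) %/% 2L
  info <- grid@info
  cropAt <- function(frame, j, t) {
    cy <- as.integer(round(info$y[j] + grid@shifts[t, 1]))
    cx <- as.integer(round(info$x[j] + grid@shifts[t, 2]))
    frame[(cy - h):(cy - h + side - 1L), (cx - h):(cx - h + side - 1L)]
  }
  ## one frame fetch per timepoint; crops sliced in place
  frame0 <- getFrame(stack, 1, channel)
  crops0 <- lapply(seq_along(ids), function(j) cropAt(frame0, j, 1))
  I0 <- vapply(crops0, function(cr) mean(cr[ringIdx]), numeric(1))
  out <- vector("list", nT)
  out[[1]] <- data.frame(microwell_id = ids, timepoint = 0L,
                         hours = times[1], I = I0, S = 0, sym = Inf)
  for (t in seq_len(nT)[-1]) {
    frame <- getFrame(stack, t, channel)
    I <- numeric(length(ids)); sym <- numeric(length(ids))
    for (j in seq_along(ids)) {
      cr <- cropAt(frame, j, t)
      I[j] <- mean(cr[ringIdx])
      d <- cr - crops0[[j]]
      sec <- vapply(secIdx, function(ix) mean(d[ix]), numeric(1))
      mu <- mean(sec)
      sym[j] <- if (mu <= 0) Inf else sd(sec) / mu
    }
    out[[t]] <- data.frame(microwell_id = ids, timepoint = t - 1L,
                           hours = times[t], I = I, S = I - I0, sym = sym)
  }
  do.call(rbind, out)
}

#' Derive the relative-signal threshold from control microwells
#'
#' Per-timepoint threshold `mean(S) + nSigma * sd(S)` over
#' occupied-but-unstimulated control microwells at the matched timepoint.
#'
#' @param controlSignals a [quantifySecretion()] table from control
#'   microwells.
#' @param nSigma multiplier (default 5).
#' @return data.frame `timepoint`, `threshold`.
#' @export
deriveSecretionThreshold <- function(controlSignals, nSigma = 5) {
  sp <- split(controlSignals$S, controlSignals$timepoint)
  data.frame(timepoint = as.integer(names(sp)),
             threshold = vapply(sp, function(v) mean(v) + nSigma * sd(v),
                                numeric(1)),
             row.names = NULL)
}

#' Call secretion-positive microwells
#'
#' A microwell is positive iff, at any timepoint inside the window, its
#' relative signal meets the intensity threshold AND its symmetry score is
#' at or below the symmetry threshold — the joint gate that rejects
#' asymmetric cross-talk arcs. The first such timepoint is recorded.
#'
#' @param signals a [quantifySecretion()] table.
#' @param sThreshold either a scalar absolute threshold or a per-timepoint
#'   data.frame from [deriveSecretionThreshold()]. Required: with no
#'   control-derived table and no absolute value this is a configuration
#'   error.
#' @param symThreshold maximum symmetry score for a genuine ring
#'   (default 0.5).
#' @param windowHours optional `c(min, max)` hours restricting the calling
#'   window.
#' @return data.frame: `microwell_id`, `positive`, `first_positive_t`
#'   (0-based timepoint, NA when negative), `first_positive_hours`.
#' @export
callPositive <- function(signals, sThreshold = NULL, symThreshold = 0.5,
                         windowHours = NULL) {
  if (is.null(sThreshold))
    stop(paste("configuration error: no control-derived threshold table",
               "and no absolute sThreshold supplied"))
  if (is.data.frame(sThreshold)) {
    thr <- sThreshold$threshold[match(signals$timepoint,
                                      sThreshold$timepoint)]
    if (anyNA(thr)) stop("threshold table lacks some timepoints")
  } else thr <- rep(sThreshold, nrow(signals))
  inWin <- if (is.null(windowHours)) rep(TRUE, nrow(signals)) else
    signals$hours >= windowHours[1] & signals$hours <= windowHours[2]
  hit <- inWin & signals$S >= thr & signals$sym <= symThreshold
  sp <- split(seq_len(nrow(signals)), signals$microwell_id)
  res <- lapply(sp, function(ix) {
    h <- ix[hit[ix]]
    if (length(h) == 0) return(c(NA_integer_, NA_real_))
    first <- h[which.min(signals$timepoint[h])]
    c(signals$timepoint[first], signals$hours[first])
  })
  ids <- as.integer(names(sp))
  m <- do.call(rbind, res)
  out <- data.frame(microwell_id = ids, positive = !is.na(m[, 1]),
                    first_positive_t = as.integer(m[, 1]),
                    first_positive_hours = m[, 2])
  out[order(out$microwell_id), ]
}

#' Cumulative positive-microwell counts over time
#'
#' Number of microwells whose first positive timepoint is at or before each
#' acquisition, grouped by well — the per-well accumulation curve reported
#' for cytokine time courses.
#'
#' @param calls a [callPositive()] table.
#' @param wells well label for each row of `calls` (single label recycled).
#' @param timepoints 0-based timepoint indices of the experiment.
#' @return data.frame: `well`, `timepoint`, `n_positive` (cumulative).
#' @export
positiveCountsOverTime <- function(calls, wells = "A1",
                                   timepoints = NULL) {
  wells <- rep_len(wells, nrow(calls))
  if (is.null(timepoints))
    timepoints <- 0:max(c(0, calls$first_positive_t), na.rm = TRUE)
  out <- expand.grid(well = unique(wells), timepoint = timepoints,
                     stringsAsFactors = FALSE)
  out$n_positive <- mapply(function(w, t)
    sum(wells == w & calls$positive & calls$first_positive_t <= t,
        na.rm = TRUE),
    out$well, out$timepoint)
  out[order(out$well, out$timepoint), ]
}
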