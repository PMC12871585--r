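#' @import methods
#' @importFrom stats median sd mad quantile rnorm rlnorm runif dpois ppois
#'   chisq.test setNames fft
#' @importFrom utils read.csv write.csv modifyList head
NULL

## ---------------------------------------------------------------------------
## FrameStack: a TCZYX image stack, either in memory or backed by an
## OME-NGFF (zarr v2) directory store.  Axis order is part of the contract:
## T (timepoints), C (channels), Z (focal planes), Y, X.
## ---------------------------------------------------------------------------

#' FrameStack: multichannel time-lapse image stack (TCZYX)
#'
#' Container for the stitched microwell-array movies the pipeline consumes.
#' The pixel data live either in an in-memory 5-d array (as produced by
#' [renderScene()]) or in an OME-NGFF zarr store on disk (as opened lazily by
#' [openStack()]); in the lazy case metadata queries never touch pixel data.
#'
#' @slot data 5-d array `[T, C, Z, Y, X]`, or `NULL` for a store-backed stack.
#' @slot path path of the backing zarr store (`NA` for in-memory stacks).
#' @slot shape integer vector of length 5, the TCZYX dimensions.
#' @slot channels channel names, one per C index (e.g. `"BF"`, `"IFNg"`).
#' @slot timesHours acquisition times in hours from t0, strictly increasing.
#' @slot pixelSizeUm pixel size in micrometers.
#' @slot dtype on-disk element type (`"<f8"` little-endian double).
#'
#' @seealso [frameStack()], [openStack()], [writeStack()], [getFrame()]
#' @export
setClass("FrameStack",
  representation(data = "ANY", path = "character", shape = "integer",
                 channels = "character", timesHours = "numeric",
                 pixelSizeUm = "numeric", dtype = "character"))

setValidity("FrameStack", function(object) {
  msg <- character()
  if (length(object@shape) != 5)
    msg <- c(msg, "shape must have exactly 5 entries (TCZYX)")
  if (length(object@channels) != object@shape[2])
    msg <- c(msg, "length(channels) must equal the C dimension")
  if (length(object@timesHours) != object@shape[1])
    msg <- c(msg, "length(timesHours) must equal the T dimension")
  if (length(object@timesHours) > 1 && any(diff(object@timesHours) <= 0))
    msg <- c(msg, "timesHours must be strictly increasing")
  if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a single positive number")
  if (!is.null(object@data) && !identical(dim(object@data), object@shape))
    msg <- c(msg, "dim(data) does not match shape")
  if (length(msg)) msg else TRUE
})

#' Construct an in-memory FrameStack
#'
#' @param data 5-d numeric array in TCZYX order.
#' @param channels character vector of channel names (length = C).
#' @param timesHours numeric vector of timepoints in hours (length = T).
#' @param pixelSizeUm pixel size in micrometers.
#' @return a [FrameStack-class] object.
#' @examples
#' a <- array(0, c(2, 1, 1, 8, 8))
#' fs <- frameStack(a, channels = "BF", timesHours = c(0, 4), pixelSizeUm = 2)
#' @export
frameStack <- function(data, channels, timesHours, pixelSizeUm) {
  stopifnot(is.array(data), length(dim(data)) == 5)
  new("FrameStack", data = data, path = NA_character_,
      shape = as.integer(dim(data)), channels = as.character(channels),
      timesHours = as.numeric(timesHours),
      pixelSizeUm = as.numeric(pixelSizeUm), dtype = "<f8")
}

## ---------------------------------------------------------------------------
## SceneConfig: parameters of the synthetic scene generator.
## ---------------------------------------------------------------------------

#' SceneConfig: parameters of the synthetic microwell scene generator
#'
#' Holds the geometry, imaging, loading, growth, secretion, drift and noise
#' parameters used by [renderScene()]. Construct with [sceneConfig()] or
#' [scenePreset()].
#'
#' @slot lattice `"square"` or `"hex"` microwell arrangement.
#' @slot pitchUm center-to-center microwell distance, micrometers.
#' @slot bottomDiamUm microwell bottom diameter, micrometers.
#' @slot pixelSizeUm rendered pixel size, micrometers per pixel.
#' @slot gridRows,gridCols lattice dimensions.
#' @slot nTimepoints number of acquisitions.
#' @slot intervalHours imaging cadence, hours.
#' @slot channels channel names; `"BF"` is always first.
#' @slot occupancyMode `"poisson"` (stochastic loading at `loadingDensity`)
#'   or `"coculture"` (exactly two cells per microwell).
#' @slot loadingDensity mean cells per microwell (lambda) for Poisson loading.
#' @slot growthModel list: `medianRate` (divisions/day), `sigma` (lognormal
#'   shape), `deathFraction` (fraction of occupied microwells with negative
#'   rate).
#' @slot secretionModel list: `positiveFraction`, `ratePerHour` (AU/h ring
#'   accumulation), `crossTalkFraction`, `crossTalkRel` (victim arc rate
#'   relative to a positive ring), `arcDeg` (victim arc width, degrees).
#' @slot markerModel `NULL`, or list: `classes`, `channels`, `fractions`,
#'   `amplitude` for clonal surface-marker fluorescence.
#' @slot driftPxPerT integer (dy, dx) stage drift per timepoint, pixels.
#' @slot noise list: `sigma` (Gaussian, AU), `bfBackground`, `fluorBackground`.
#' @slot seed integer seed; all scene randomness flows from it.
#' @export
setClass("SceneConfig",
  representation(lattice = "character", pitchUm = "numeric",
                 bottomDiamUm = "numeric", pixelSizeUm = "numeric",
                 gridRows = "integer", gridCols = "integer",
                 nTimepoints = "integer", intervalHours = "numeric",
                 channels = "character", occupancyMode = "character",
                 loadingDensity = "numeric", growthModel = "list",
                 secretionModel = "list", markerModel = "ANY",
                 driftPxPerT = "numeric", noise = "list", seed = "integer"))

setValidity("SceneConfig", function(object) {
  msg <- character()
  if (!object@lattice %in% c("square", "hex"))
    msg <- c(msg, "lattice must be 'square' or 'hex'")
  if (object@pitchUm <= object@bottomDiamUm)
    msg <- c(msg, "pitchUm must exceed bottomDiamUm")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@nTimepoints < 1) msg <- c(msg, "nTimepoints must be >= 1")
  if (object@gridRows < 1 || object@gridCols < 1)
    msg <- c(msg, "grid dimensions must be >= 1")
  fr <- c(object@growthModel$deathFraction,
          object@secretionModel$positiveFraction,
          object@secretionModel$crossTalkFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@loadingDensity < 0) msg <- c(msg, "loadingDensity must be >= 0")
  if (length(object@driftPxPerT) != 2)
    msg <- c(msg, "driftPxPerT must be (dy, dx)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## MicrowellGrid: detected (or ground-truth) lattice with stable IDs.
## ---------------------------------------------------------------------------

#' MicrowellGrid: microwell centers, stable IDs and registration shifts
#'
#' One row per microwell with its stable integer id (assigned row-major at
#' t0), lattice index, t0 center in pixels, a detection score and the
#' picker-accessibility flag. Whole-frame registration shifts per timepoint
#' live in the `shifts` slot; the shift at t0 is (0, 0) by definition.
#'
#' @slot info data.frame with columns `id`, `row`, `col`, `y`, `x`, `score`,
#'   `accessible`.
#' @slot shifts numeric matrix `[T, 2]` of (dy, dx) shifts in pixels.
#' @slot pitchPx estimated lattice pitch in pixels.
#' @slot pixelSizeUm pixel size in micrometers.
#' @slot thetaDeg estimated lattice rotation, degrees.
#' @export
setClass("MicrowellGrid",
  representation(info = "data.frame", shifts = "matrix", pitchPx = "numeric",
                 pixelSizeUm = "numeric", thetaDeg = "numeric"))

setValidity("MicrowellGrid", function(object) {
  msg <- character()
  need <- c("id", "row", "col", "y", "x", "score", "accessible")
  if (!all(need %in% names(object@info)))
    msg <- c(msg, paste("info must have columns", paste(need, collapse = ", ")))
  else if (anyDuplicated(object@info$id))
    msg <- c(msg, "microwell ids must be unique")
  if (ncol(object@shifts) != 2) msg <- c(msg, "shifts must have 2 columns")
  if (nrow(object@shifts) >= 1 && any(object@shifts[1, ] != 0))
    msg <- c(msg, "shift at t0 must be (0, 0)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SceneTruth: complete ground truth for a rendered scene.
## ---------------------------------------------------------------------------

#' SceneTruth: ground truth record of a rendered synthetic scene
#'
#' @slot microwells data.frame, one row per lattice site: `id`, `row`, `col`,
#'   `y`, `x` (t0 center, px), `occupancy_t0`, `r_true` (divisions/day, NA
#'   for empty microwells), `secretion_label` (`"negative"`, `"positive"`,
#'   `"cross_talk_victim"`), `marker_class`.
#' @slot counts integer matrix `[n_microwells, T]` of true per-timepoint
#'   cell counts.
#' @slot timesHours acquisition times, hours.
#' @slot drift numeric matrix `[T, 2]`, applied cumulative (dy, dx) drift.
#' @slot nCellsLoaded total number of cells loaded at t0.
#' @export
setClass("SceneTruth",
  representation(microwells = "data.frame", counts = "matrix",
                 timesHours = "numeric", drift = "matrix",
                 nCellsLoaded = "integer"))

setValidity("SceneTruth", function(object) {
  msg <- character()
  if (nrow(object@counts) != nrow(object@microwells))
    msg <- c(msg, "counts must have one row per microwell")
  if (ncol(object@counts) != length(object@timesHours))
    msg <- c(msg, "counts must have one column per timepoint")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GateNode: one node of a hierarchical gate tree.
## ---------------------------------------------------------------------------

#' GateNode: one node of a hierarchical gating tree
#'
#' A gate is a named predicate over per-microwell features; its member set is
#' always a subset of its parent's members. Build trees with [gateNode()] and
#' evaluate them against a feature table with [applyGateTree()].
#'
#' @slot name human-readable gate name.
#' @slot predicate predicate string, e.g. `"count@t0 == 1"`; clauses joined
#'   with `AND`. The empty string matches everything.
#' @slot children list of child `GateNode`s (siblings act as disjuncts).
#' @slot memberIds integer ids of member microwells (populated on evaluation).
#' @slot count number of members.
#' @slot parentCount number of members of the parent gate.
#' @slot fractionOfParent `100 * count / parentCount` (unrounded).
#' @export
setClass("GateNode",
  representation(name = "character", predicate = "character",
                 children = "list", memberIds = "integer", count = "integer",
                 parentCount = "integer", fractionOfParent = "numeric"))

#' @describeIn GateNode-class constructor.
#' @param name gate name.
#' @param predicate predicate string (see [applyGateTree()] for the grammar).
#' @param children list of child `GateNode`s.
#' @export
gateNode <- function(name, predicate = "", children = list()) {
  stopifnot(all(vapply(children, is, logical(1), "GateNode")))
  new("GateNode", name = name, predicate = predicate, children = children,
      memberIds = integer(), count = NA_integer_, parentCount = NA_integer_,
      fractionOfParent = NA_real_)
}
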