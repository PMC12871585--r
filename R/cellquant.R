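#' Detect and count cells in a brightfield microwell crop
#'
#' Classical instance detector standing behind a pluggable interface:
#' the smooth conical-well background is flattened by subtracting a local
#' median (window wider than the largest admissible object, so blobs are
#' removed but the cone gradient is followed), the residual dark blobs are
#' thresholded, touching blobs are split by watershed on the distance
#' transform, and a size gate removes debris (objects below `minDiamUm`)
#' and artifacts (objects above `maxDiamUm`, default 20 um). Deterministic
#' given pixels.
#'
#' @param bfCrop square brightfield crop from [cropMicrowell()]; cells are
#'   darker than their surroundings.
#' @param minDiamUm,maxDiamUm equivalent-diameter gate in micrometers
#'   (defaults 5 and 20).
#' @param pixelSizeUm pixel size of the crop, um/px.
#' @param crowdedFraction if the segmented foreground covers more than this
#'   fraction of the crop, counts saturate and the result carries
#'   `attr(, "crowded") = TRUE`.
#' @return data.frame with one row per detected cell: `cell`, `y`, `x`
#'   (centroid, px), `diameter_um`, `area_px`. The labelled segmentation
#'   mask is attached as `attr(, "mask")` for use as the fluorescence
#'   template.
#' @seealso [cellIntensities()], [classifyCells()]
#' @export
countCells <- function(bfCrop, minDiamUm = 5, maxDiamUm = 20,
                       pixelSizeUm = 2, crowdedFraction = 0.5) {
  stopifnot(is.matrix(bfCrop), minDiamUm > 0, maxDiamUm > minDiamUm)
  empty <- data.frame(cell = integer(), y = numeric(), x = numeric(),
                      diameter_um = numeric(), area_px = numeric())
  attr(empty, "mask") <- matrix(0L, nrow(bfCrop), ncol(bfCrop))
  attr(empty, "crowded") <- FALSE
  rng <- diff(range(bfCrop))
  if (rng <= .Machine$double.eps * 100) return(empty)

  crn <- (max(bfCrop) - bfCrop) / rng      # darkness, normalized to [0, 1]
  r <- as.integer(round(maxDiamUm / pixelSizeUm))
  r <- max(2L, min(r, (min(dim(bfCrop)) - 1L) %/% 2L - 1L))
  bg <- EBImage::medianFilter(crn, r)
  th <- pmax(crn - bg, 0)
  mth <- max(th)
  ## residual indistinguishable from background undulation -> nothing there
  if (mth <= 0.1) return(empty)
  mask <- th > 0.5 * mth
  mask <- EBImage::opening(mask, EBImage::makeBrush(3, "disc"))
  if (!any(mask)) return(empty)
  lab <- EBImage::watershed(EBImage::distmap(mask))
  lab <- EBImage::imageData(lab)

  nlab <- max(lab)
  out <- empty
  keepMask <- matrix(0L, nrow(bfCrop), ncol(bfCrop))
  nextId <- 0L
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx)
    d <- 2 * sqrt(area / pi) * pixelSizeUm
    if (d < minDiamUm || d > maxDiamUm) next
    nextId <- nextId + 1L
    keepMask[idx] <- nextId
    out <- rbind(out, data.frame(cell = nextId, y = mean(idx[, 1]),
                                 x = mean(idx[, 2]), diameter_um = d,
                                 area_px = area))
  }
  rownames(out) <- NULL
  attr(out, "mask") <- keepMask
  attr(out, "crowded") <- mean(mask) > crowdedFraction
  out
}

#' Quantify per-cell fluorescence using the brightfield mask template
#'
#' The segmentation mask from the brightfield image is used as the template
#' to measure the mean fluorescence of each cell in every channel; the
#' crop-local background (median intensity outside all masks) is
#' subtracted, which keeps the measurement robust to secretion-ring
#' fluorescence near the crop edges.
#'
#' @param cells result of [countCells()] (carries the mask attribute).
#' @param fluorCrops named list of fluorescence crops co-registered with
#'   the brightfield crop.
#' @return `cells` with one additional column `<channel>_mean` per channel.
#' @export
cellIntensities <- function(cells, fluorCrops) {
  mask <- attr(cells, "mask")
  if (is.null(mask)) stop("cells must carry the brightfield mask attribute")
  stopifnot(is.list(fluorCrops), length(names(fluorCrops)) ==
              length(fluorCrops))
  for (ch in names(fluorCrops)) {
    crop <- fluorCrops[[ch]]
    if (!identical(dim(crop), dim(mask)))
      stop("channel '", ch, "' crop shape does not match the mask")
    bg <- median(crop[mask == 0L])
    vals <- if (nrow(cells)) vapply(cells$cell, function(l)
      mean(crop[mask == l]) - bg, numeric(1)) else numeric(0)
    cells[[paste0(ch, "_mean")]] <- vals
  }
  cells
}

#' A surface-marker classification rule
#'
#' @param channel fluorescence channel name.
#' @param threshold intensity threshold (background-subtracted units).
#' @param polarity `"+"` labels cells at or above the threshold, `"-"`
#'   below it.
#' @param label column name for the resulting boolean (default
#'   `<channel><polarity>`).
#' @return list of class `"MarkerRule"`.
#' @export
markerRule <- function(channel, threshold, polarity = "+", label = NULL) {
  stopifnot(is.finite(threshold), polarity %in% c("+", "-"))
  structure(list(channel = channel, threshold = threshold,
                 polarity = polarity,
                 label = if (is.null(label)) paste0(channel, polarity)
                         else label),
            class = "MarkerRule")
}

#' Classify cells by surface-marker rules
#'
#' Each rule contributes one boolean column; composite phenotypes (e.g.
#' GFP+/mCherry-) are conjunctions of the rule columns.
#'
#' @param cells result of [cellIntensities()].
#' @param rules list of [markerRule()]s.
#' @return `cells` with one logical column per rule label.
#' @export
classifyCells <- function(cells, rules) {
  for (r in rules) {
    col <- paste0(r$channel, "_mean")
    if (!col %in% names(cells))
      stop("rule references channel '", r$channel,
           "' with no measured intensities")
    v <- cells[[col]] >= r$threshold
    cells[[r$label]] <- if (r$polarity == "+") v else !v
  }
  cells
}

#' Default per-plate marker threshold
#'
#' Robust data-derived default when no threshold is supplied: background
#' median plus `k` median absolute deviations of the per-cell intensities.
#'
#' @param intensities background-subtracted per-cell intensities pooled
#'   over the plate.
#' @param k MAD multiplier (default 5).
#' @return numeric threshold.
#' @export
markerThreshold <- function(intensities, k = 5) {
  median(intensities) + k * mad(intensities)
}

#' Mean intensity of a crop
#'
#' Whole-crop arithmetic mean, used to flag junk and autofluorescent
#' microwells before any per-cell analysis.
#'
#' @param crop numeric matrix.
#' @return scalar mean.
#' @export
cropMeanIntensity <- function(crop) mean(crop)
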