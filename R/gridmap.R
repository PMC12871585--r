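#' Plate / array layout description
#'
#' @param wellRows,wellCols macroscopic plate format (default 8 x 12).
#' @param microwellsPerWell nominal microwells per well (default
#'   `round(380000 / 96)`).
#' @param accessibleAreaFraction fraction of the well-footprint area the
#'   picker can reach (default 0.75; the picker tip cannot reach microwells
#'   near the well perimeter, so the working region is the central 75% of
#'   the footprint).
#' @param pitchUm,bottomDiamUm,pixelSizeUm lattice geometry, as in
#'   [sceneConfig()].
#' @return a list of class `"PlateLayout"`.
#' @export
plateLayout <- function(wellRows = 8L, wellCols = 12L,
                        microwellsPerWell = round(380000 / 96),
                        accessibleAreaFraction = 0.75,
                        pitchUm = 130, bottomDiamUm = 65, pixelSizeUm = 2) {
  stopifnot(accessibleAreaFraction > 0, accessibleAreaFraction <= 1,
            pitchUm > 0)
  structure(list(wellRows = wellRows, wellCols = wellCols,
                 microwellsPerWell = microwellsPerWell,
                 accessibleAreaFraction = accessibleAreaFraction,
                 pitchUm = pitchUm, bottomDiamUm = bottomDiamUm,
                 pixelSizeUm = pixelSizeUm),
            class = "PlateLayout")
}

#' Detect the microwell lattice in a brightfield frame
#'
#' Classical detector standing behind a pluggable interface: a zero-mean
#' radial matched filter highlights microwell centers, local-extrema peak
#' picking finds candidate sites, a robust pitch/rotation fit assigns
#' lattice indices, and sub-pixel centers are refined by iterated intensity
#' centroids. IDs are assigned row-major from the top-left after rotation
#' correction.
#'
#' @param bfFrame 2-D brightfield matrix (microwells darker than
#'   background).
#' @param layout a [plateLayout()]; its pitch must be within 20% of the
#'   imaged pitch.
#' @return a [MicrowellGrid-class] with the t0 shift initialized to (0, 0).
#' @export
detectGrid <- function(bfFrame, layout) {
  stopifnot(is.matrix(bfFrame))
  pitchPx <- layout$pitchUm / layout$pixelSizeUm
  if (diff(range(bfFrame)) <= .Machine$double.eps * 100)
    stop("no lattice found: frame has no contrast")
  inv <- max(bfFrame) - bfFrame

  ## matched filter: zero-mean radial tent of radius 0.4 * pitch
  R <- max(3, round(0.4 * pitchPx))
  k <- pmax(1 - .radiusMap(2 * R + 1)$r / R, 0)
  k <- k - mean(k)
  resp <- EBImage::filter2(inv, k, boundary = "replicate")

  ## peaks: local maxima over a ~0.7 pitch neighborhood, above half-max
  w <- .odd(0.7 * pitchPx)
  mx <- EBImage::dilate(resp, EBImage::makeBrush(w, "disc"))
  thr <- 0.5 * max(resp)
  pk <- which(resp >= mx - 1e-9 & resp > thr, arr.ind = TRUE)
  ## keep centers clear of the frame edge (crop margin guarantee)
  half <- layout$bottomDiamUm / layout$pixelSizeUm / 2
  pk <- pk[pk[, 1] > half & pk[, 1] <= nrow(bfFrame) - half &
           pk[, 2] > half & pk[, 2] <= ncol(bfFrame) - half, , drop = FALSE]
  if (nrow(pk) < 4) stop("no lattice found: fewer than 4 candidate sites")

  ## collapse duplicate maxima (plateaus) closer than 0.5 pitch
  ord <- order(-resp[pk])
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    d2 <- (pk[, 1] - pk[i, 1])^2 + (pk[, 2] - pk[i, 2])^2
    close <- which(d2 < (0.5 * pitchPx)^2 & keep)
    keep[setdiff(close, i)] <- FALSE
  }
  pk <- pk[keep, , drop = FALSE]
  score <- resp[pk]

  ## robust pitch: median nearest-neighbor distance (sampled on big grids)
  nn <- .nnVectors(pk)
  pitchEst <- median(sqrt(nn[, 1]^2 + nn[, 2]^2))
  if (abs(pitchEst - pitchPx) / pitchPx > 0.2)
    stop(sprintf(paste0("calibration error: estimated pitch %.1f px ",
                        "deviates >20%% from configured %.1f px"),
                 pitchEst, pitchPx))

  ## rotation: fold nearest-neighbor angles into (-45, 45]; ties toward 0
  ang <- atan2(nn[, 1], nn[, 2]) * 180 / pi
  ang <- ((ang + 45) %% 90) - 45
  theta <- median(ang)
  if (abs(theta) > 5) theta <- 0   # beyond the supported range; assume axis-aligned

  ## sub-pixel refinement by iterated intensity centroid
  ctr <- .refineCenters(inv, pk, radius = 0.45 * pitchPx)

  ## lattice indices in the de-rotated frame
  th <- -theta * pi / 180
  y0 <- mean(ctr[, 1]); x0 <- mean(ctr[, 2])
  yr <- (ctr[, 1] - y0) * cos(th) - (ctr[, 2] - x0) * sin(th)
  xr <- (ctr[, 1] - y0) * sin(th) + (ctr[, 2] - x0) * cos(th)
  row <- as.integer(round((yr - min(yr)) / pitchEst)) + 1L
  col <- as.integer(round((xr - min(xr)) / pitchEst)) + 1L

  ## one center per lattice cell: best score wins
  cell <- paste(row, col)
  ord <- order(-score)
  first <- !duplicated(cell[ord])
  sel <- sort(ord[first])
  info <- data.frame(id = NA_integer_, row = row[sel], col = col[sel],
                     y = ctr[sel, 1], x = ctr[sel, 2], score = score[sel],
                     accessible = TRUE)
  info <- info[order(info$row, info$col), ]
  info$id <- seq_len(nrow(info))
  rownames(info) <- NULL
  new("MicrowellGrid", info = info,
      shifts = matrix(0, 1, 2, dimnames = list(NULL, c("dy", "dx"))),
      pitchPx = pitchEst, pixelSizeUm = layout$pixelSizeUm,
      thetaDeg = theta)
}

## nearest-neighbor (dy, dx) for each of up to 400 sampled points
.nnVectors <- function(pk) {
  n <- nrow(pk)
  idx <- if (n > 400) sample.int(n, 400) else seq_len(n)
  out <- matrix(0, length(idx), 2)
  for (j in seq_along(idx)) {
    i <- idx[j]
    d2 <- (pk[, 1] - pk[i, 1])^2 + (pk[, 2] - pk[i, 2])^2
    d2[i] <- Inf
    k <- which.min(d2)
    out[j, ] <- c(pk[k, 1] - pk[i, 1], pk[k, 2] - pk[i, 2])
  }
  out
}

.refineCenters <- function(inv, pk, radius) {
  h <- max(2L, as.integer(floor(radius)))
  off <- .radiusMap(2 * h + 1)
  inside <- off$r <= radius
  ctr <- matrix(as.numeric(pk), ncol = 2)
  for (iter in 1:3) {
    for (i in seq_len(nrow(ctr))) {
      cy <- as.integer(round(ctr[i, 1])); cx <- as.integer(round(ctr[i, 2]))
      yy <- (cy - h):(cy + h); xx <- (cx - h):(cx + h)
      if (yy[1] < 1 || xx[1] < 1 || yy[length(yy)] > nrow(inv) ||
          xx[length(xx)] > ncol(inv)) next
      win <- inv[yy, xx]
      w <- pmax(win - median(win), 0) * inside
      sw <- sum(w)
      if (sw <= 0) next
      ctr[i, 1] <- cy + sum(w * off$dy) / sw
      ctr[i, 2] <- cx + sum(w * off$dx) / sw
    }
  }
  ctr
}

#' Estimate the whole-frame shift of a timepoint against the t0 frame
#'
#' Integer-pixel global translation maximizing the circular
#' cross-correlation (computed by FFT) between the reference brightfield
#' frame and the frame at time t. Stage drift is mechanical and global, so
#' a single shift per timepoint registers every microwell crop.
#'
#' @param ref the t0 brightfield frame (2-D matrix).
#' @param frame the frame to register against `ref`.
#' @param minPeakZ floor on the correlation-peak z-score; below it a
#'   warning is issued and (0, 0) returned.
#' @return integer `c(dy, dx)` such that `frame` content sits at
#'   `ref` position + (dy, dx).
#' @seealso [registerStack()] to fill a [MicrowellGrid-class] for all
#'   timepoints.
#' @export
registerTimepoint <- function(ref, frame, minPeakZ = 5) {
  stopifnot(is.matrix(ref), identical(dim(ref), dim(frame)))
  a <- ref - mean(ref); b <- frame - mean(frame)
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE))
  z <- (max(cc) - mean(cc)) / sd(cc)
  if (!is.finite(z) || z < minPeakZ) {
    warning("registration correlation peak below floor; assuming zero shift")
    return(c(dy = 0L, dx = 0L))
  }
  ij <- which(cc == max(cc), arr.ind = TRUE)[1, ] - 1L
  dy <- ij[1]; dx <- ij[2]
  if (dy > nrow(ref) / 2) dy <- dy - nrow(ref)
  if (dx > ncol(ref) / 2) dx <- dx - ncol(ref)
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Register every timepoint of a stack onto a grid
#'
#' @param grid a [MicrowellGrid-class] detected on the t0 frame.
#' @param stack the [FrameStack-class] the grid was detected in.
#' @param channel brightfield channel name or index.
#' @return the grid with its `shifts` slot filled for all T timepoints
#'   (t0 = (0, 0)); microwell IDs are untouched — registration never
#'   re-identifies.
#' @export
registerStack <- function(grid, stack, channel = "BF") {
  nT <- dim(stack)[1]
  ref <- getFrame(stack, 1, channel)
  shifts <- matrix(0L, nT, 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in seq_len(nT)[-1])
    shifts[t, ] <- registerTimepoint(ref, getFrame(stack, t, channel))
  grid@shifts <- shifts
  validObject(grid)
  grid
}

#' Crop one microwell from a stack
#'
#' Square crop of side `ceiling(pitch)` pixels centered on the microwell's
#' t0 center plus the registered shift at timepoint `t`.
#'
#' @param stack a [FrameStack-class].
#' @param grid a [MicrowellGrid-class] with shifts for `t`.
#' @param id microwell id.
#' @param t timepoint index (1-based).
#' @param channel channel name or index.
#' @return numeric square matrix.
#' @export
cropMicrowell <- function(stack, grid, id, t, channel = "BF") {
  i <- match(id, grid@info$id)
  if (is.na(i)) stop("unknown microwell id: ", id)
  if (t < 1 || t > nrow(grid@shifts)) stop("no registered shift for t = ", t)
  frame <- getFrame(stack, t, channel)
  side <- as.integer(ceiling(grid@pitchPx))
  h <- (side - 1L) %/% 2L
  cy <- as.integer(round(grid@info$y[i] + grid@shifts[t, 1]))
  cx <- as.integer(round(grid@info$x[i] + grid@shifts[t, 2]))
  yy <- (cy - h):(cy - h + side - 1L)
  xx <- (cx - h):(cx - h + side - 1L)
  if (yy[1] < 1 || xx[1] < 1 || yy[side] > nrow(frame) ||
      xx[side] > ncol(frame))
    stop("crop for microwell ", id, " exceeds the frame")
  frame[yy, xx]
}

#' Picker-accessibility mask
#'
#' The picker tip cannot reach microwells near the well perimeter. The well
#' footprint is taken as the bounding circle of the detected centers and a
#' microwell is accessible iff its center lies inside the concentric circle
#' enclosing `accessibleAreaFraction` of the footprint area (radius fraction
#' `sqrt(fraction)`, e.g. ~0.866 for the central 75% of the area).
#'
#' @param grid a [MicrowellGrid-class].
#' @param layout a [plateLayout()] supplying `accessibleAreaFraction`.
#' @return logical vector, one flag per microwell (in `microwells(grid)`
#'   order).
#' @export
accessibleMask <- function(grid, layout) {
  f <- layout$accessibleAreaFraction
  ctr <- c(mean(grid@info$y), mean(grid@info$x))
  d <- sqrt((grid@info$y - ctr[1])^2 + (grid@info$x - ctr[2])^2)
  d <= max(d) * sqrt(f)
}
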