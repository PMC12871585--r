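#' Write a FrameStack as an OME-NGFF (zarr) store
#'
#' Serializes the stack to a zarr v2 directory store with OME-NGFF 0.4
#' multiscales metadata. Axis order on disk is exactly TCZYX; chunks are one
#' uncompressed little-endian float64 plane per (t, c, z), so the round trip
#' through [openStack()] is value-identical.
#'
#' @param stack a [FrameStack-class] with in-memory data.
#' @param path directory to create (removed and rewritten if it exists).
#' @return `invisible(path)`.
#' @seealso [openStack()]
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "FrameStack"))
  if (is.null(stack@data))
    stop("stack has no in-memory data to write")
  if (dir.exists(path)) unlink(path, recursive = TRUE)
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create store at ", path)
  d <- stack@shape
  adir <- file.path(path, "0")
  dir.create(adir)
  .zarrWriteJSON(list(zarr_format = 2L), file.path(path, ".zgroup"))
  s <- stack@pixelSizeUm
  attrs <- list(
    multiscales = list(list(
      version = "0.4",
      name = "conewell",
      axes = .ngffAxes(),
      datasets = list(list(
        path = "0",
        coordinateTransformations = list(list(
          type = "scale", scale = c(1, 1, 1, s, s))))))),
    omero = list(channels = lapply(stack@channels,
                                   function(ch) list(label = ch))),
    conewell = list(channel_names = stack@channels,
                    timestamps_hours = stack@timesHours,
                    pixel_size_um = s))
  .zarrWriteJSON(attrs, file.path(path, ".zattrs"))
  .zarrWriteJSON(list(
    zarr_format = 2L, shape = d, chunks = c(1L, 1L, 1L, d[4], d[5]),
    dtype = "<f8", compressor = NULL, fill_value = 0,
    filters = NULL, order = "C", dimension_separator = "."),
    file.path(adir, ".zarray"))
  for (t in seq_len(d[1])) for (cc in seq_len(d[2])) for (z in seq_len(d[3]))
    .zarrWritePlane(stack@data[t, cc, z, , ],
                    file.path(adir, .zarrChunkFile(t - 1, cc - 1, z - 1)))
  invisible(path)
}

#' Open an OME-NGFF (zarr) store as a lazy FrameStack
#'
#' Reads only the store metadata; pixel planes are loaded on demand by
#' [getFrame()]. The store must declare axes in exactly TCZYX order; any
#' other order is an error (never a silent transpose).
#'
#' @param path directory of a zarr group written by [writeStack()] (or any
#'   compliant writer using uncompressed f8 chunks, one plane per chunk).
#' @param intervalHours fallback imaging interval used (with a warning) when
#'   the store carries no timestamps.
#' @return a [FrameStack-class] with `data = NULL` (store-backed).
#' @export
openStack <- function(path, intervalHours = 1) {
  if (!dir.exists(path)) stop("no such store: ", path)
  attrs <- .zarrReadJSON(file.path(path, ".zattrs"))
  ax <- attrs$multiscales$axes[[1]]
  axNames <- if (is.data.frame(ax)) ax$name else
    vapply(ax, function(a) a$name, "")
  if (!identical(toupper(paste(axNames, collapse = "")), "TCZYX"))
    stop("axis order is '", paste(axNames, collapse = ""),
         "'; expected \"TCZYX\"")
  za <- .zarrReadJSON(file.path(path, "0", ".zarray"))
  shape <- as.integer(za$shape)
  if (length(shape) != 5)
    stop("malformed zarr store: array is not 5-dimensional (TCZYX)")
  if (!identical(za$dtype, "<f8"))
    stop("unsupported dtype '", za$dtype, "' (expected <f8)")
  if (!is.null(za$compressor))
    stop("compressed zarr chunks are not supported by this reader")
  cw <- attrs$conewell
  channels <- if (!is.null(cw$channel_names)) as.character(cw$channel_names)
    else paste0("C", seq_len(shape[2]))
  if (!is.null(cw$timestamps_hours)) {
    times <- as.numeric(cw$timestamps_hours)
  } else {
    warning("store carries no timestamps; assuming index * ",
            intervalHours, " h")
    times <- (seq_len(shape[1]) - 1) * intervalHours
  }
  px <- if (!is.null(cw$pixel_size_um)) as.numeric(cw$pixel_size_um) else {
    sc <- attrs$multiscales$datasets[[1]]$coordinateTransformations[[1]]$scale
    if (is.null(sc)) 1 else as.numeric(sc[[length(sc)]])
  }
  new("FrameStack", data = NULL, path = path, shape = shape,
      channels = channels, timesHours = times, pixelSizeUm = px,
      dtype = "<f8")
}

#' Extract one 2-D frame from a FrameStack
#'
#' @param stack a [FrameStack-class].
#' @param t timepoint index (1-based) or a time in hours when `hours = TRUE`.
#' @param channel channel name or 1-based index.
#' @param z focal plane (1-based); `"max"` requests a max projection over Z.
#' @return numeric `Y x X` matrix.
#' @export
getFrame <- function(stack, t, channel = 1L, z = 1L) {
  stopifnot(is(stack, "FrameStack"))
  if (is.character(channel)) {
    ci <- match(channel, stack@channels)
    if (is.na(ci)) stop("unknown channel '", channel, "'; available: ",
                        paste(stack@channels, collapse = ", "))
  } else ci <- as.integer(channel)
  t <- as.integer(t)
  if (t < 1 || t > stack@shape[1]) stop("timepoint index out of range")
  if (ci < 1 || ci > stack@shape[2]) stop("channel index out of range")
  zi <- if (identical(z, "max")) seq_len(stack@shape[3]) else as.integer(z)
  if (any(zi < 1) || any(zi > stack@shape[3])) stop("z index out of range")
  planes <- lapply(zi, function(zz) {
    if (!is.null(stack@data)) stack@data[t, ci, zz, , ]
    else .zarrReadPlane(
      file.path(stack@path, "0", .zarrChunkFile(t - 1, ci - 1, zz - 1)),
      stack@shape[4], stack@shape[5])
  })
  if (length(planes) == 1) planes[[1]] else Reduce(pmax, planes)
}

## ---------------------------------------------------------------------------
## Feature tables: the long-format CSV every stage appends to.
## ---------------------------------------------------------------------------

.featureKey <- c("well", "microwell_id", "timepoint")

#' Write / read the long-format feature table
#'
#' The feature table is the flat record every pipeline stage appends to: one
#' row per (well, microwell_id, timepoint) carrying counts, intensities, ring
#' signal, symmetry, growth metrics and gate memberships. Stored as plain CSV
#' for inspectability; the round trip is value-identical for all columns.
#'
#' @param table data.frame with at least the key columns `well`,
#'   `microwell_id`, `timepoint`; the key must be unique.
#' @param path CSV file path.
#' @return `readFeatureTable()` returns the data.frame;
#'   `writeFeatureTable()` returns `invisible(path)`.
#' @export
writeFeatureTable <- function(table, path) {
  .checkFeatureTable(table)
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  .checkFeatureTable(tab)
  tab
}

.checkFeatureTable <- function(tab) {
  miss <- setdiff(.featureKey, names(tab))
  if (length(miss))
    stop("feature table lacks key column(s): ", paste(miss, collapse = ", "))
  key <- do.call(paste, c(tab[.featureKey], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (well, microwell_id, timepoint) keys in feature table")
  invisible(TRUE)
}

#' Write / read the scene ground-truth record
#'
#' Ground truth is written as a long CSV (one row per microwell-timepoint:
#' the per-microwell metadata joined with the true count trajectory) plus a
#' JSON sidecar holding the times, the applied drift and the loading total.
#'
#' @param truth a [SceneTruth-class].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return `readSceneTruth()` returns a [SceneTruth-class];
#'   `writeSceneTruth()` returns `invisible(path)`.
#' @export
writeSceneTruth <- function(truth, path) {
  stopifnot(is(truth, "SceneTruth"))
  mw <- truth@microwells
  nT <- ncol(truth@counts)
  long <- mw[rep(seq_len(nrow(mw)), each = nT), ]
  long$timepoint <- rep(seq_len(nT) - 1L, nrow(mw))
  long$hours <- rep(truth@timesHours, nrow(mw))
  long$count <- as.integer(t(truth@counts))
  write.csv(long, path, row.names = FALSE)
  .zarrWriteJSON(list(times_hours = truth@timesHours,
                      drift = unname(apply(truth@drift, 1, c,
                                           simplify = FALSE)),
                      n_cells_loaded = truth@nCellsLoaded),
                 paste0(path, ".meta.json"))
  invisible(path)
}

#' @rdname writeSceneTruth
#' @export
readSceneTruth <- function(path) {
  long <- read.csv(path, colClasses = c(marker_class = "character",
                                        secretion_label = "character"))
  meta <- .zarrReadJSON(paste0(path, ".meta.json"))
  times <- as.numeric(meta$times_hours)
  nT <- length(times)
  mw <- long[long$timepoint == 0L,
             setdiff(names(long), c("timepoint", "hours", "count"))]
  rownames(mw) <- NULL
  counts <- matrix(as.integer(long$count), ncol = nT, byrow = TRUE)
  drift <- if (is.matrix(meta$drift)) meta$drift else
    do.call(rbind, lapply(meta$drift, as.numeric))
  new("SceneTruth", microwells = mw, counts = counts, timesHours = times,
      drift = drift, nCellsLoaded = as.integer(meta$n_cells_loaded))
}
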