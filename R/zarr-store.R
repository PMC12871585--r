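## Minimal zarr v2 directory store, enough to hold OME-NGFF image data:
## uncompressed C-order chunks, little-endian float64, one chunk per
## (t, c, z) plane. No R zarr implementation exists on CRAN/Bioconductor,
## so the on-disk format is written directly; the layout follows the zarr
## v2 spec (.zgroup / .zattrs / .zarray JSON plus raw chunk files) and is
## readable by any compliant implementation.

.zarrWriteJSON <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), path)
}

.zarrReadJSON <- function(path) {
  if (!file.exists(path))
    stop("malformed zarr store: missing ", basename(path), call. = FALSE)
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
}

## chunk file name for plane (t, c, z) with 0-based indices
.zarrChunkFile <- function(t0, c0, z0) sprintf("%d.%d.%d.0.0", t0, c0, z0)

## write one Y x X plane (R column-major matrix) as a C-order f8 chunk
.zarrWritePlane <- function(mat, file) {
  con <- file(file, "wb")
  on.exit(close(con))
  ## C order: X varies fastest -> transpose before flattening
  writeBin(as.numeric(t(mat)), con, size = 8, endian = "little")
}

.zarrReadPlane <- function(file, ny, nx) {
  if (!file.exists(file))
    stop("zarr chunk missing: ", basename(file), call. = FALSE)
  con <- file(file, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = ny * nx, size = 8, endian = "little")
  if (length(v) != ny * nx)
    stop("zarr chunk truncated: ", basename(file), call. = FALSE)
  matrix(v, nrow = ny, ncol = nx, byrow = TRUE)
}

.ngffAxes <- function() {
  list(
    list(name = "t", type = "time", unit = "hour"),
    list(name = "c", type = "channel"),
    list(name = "z", type = "space", unit = "micrometer"),
    list(name = "y", type = "space", unit = "micrometer"),
    list(name = "x", type = "space", unit = "micrometer"))
}
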