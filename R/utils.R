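#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (0.5 -> 1), matching the convention used when reporting gate
#' percentages. Base [round()] uses banker's rounding, which would turn
#' 34.5 into 34.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up (in magnitude).
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## integer-count validation shared by the loading/occupancy code
.checkCount <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  if (x < min)
    stop(sprintf("'%s' must be >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.odd <- function(x) {
  x <- as.integer(round(x))
  if (x %% 2L == 0L) x + 1L else x
}

## distance-from-center map for a square crop; center is the geometric
## center of the pixel grid ((n+1)/2 in 1-based coordinates)
.radiusMap <- function(nr, nc = nr) {
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  dy <- matrix(seq_len(nr) - cy, nr, nc)
  dx <- matrix(seq_len(nc) - cx, nr, nc, byrow = TRUE)
  list(r = sqrt(dy^2 + dx^2), dy = dy, dx = dx)
}
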