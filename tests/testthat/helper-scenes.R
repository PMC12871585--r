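## Shared fixture builders: every fixture is generated in code at test time.

## small noiseless empty scene (geometry only)
emptyScene <- function(rows = 10, cols = 10, seed = 3, ...) {
  renderScene(sceneConfig(gridRows = rows, gridCols = cols,
                          nTimepoints = 1, loadingDensity = 0,
                          seed = seed, ...))
}

## square crop with a flat background plus a uniform ring confined to an
## annulus -- built by explicit pixel distances, independent of the
## package's annulus machinery
oracleRingCrop <- function(side, rin, rout, background = 0, amplitude = 0) {
  ctr <- (side + 1) / 2
  crop <- matrix(background, side, side)
  for (y in seq_len(side)) for (x in seq_len(side)) {
    r <- sqrt((y - ctr)^2 + (x - ctr)^2)
    if (r >= rin && r <= rout) crop[y, x] <- crop[y, x] + amplitude
  }
  crop
}

## one-sided arc: ring pixels restricted to an angular wedge
oracleArcCrop <- function(side, rin, rout, amplitude, angFrom, angTo,
                          background = 0) {
  ctr <- (side + 1) / 2
  crop <- matrix(background, side, side)
  for (y in seq_len(side)) for (x in seq_len(side)) {
    r <- sqrt((y - ctr)^2 + (x - ctr)^2)
    a <- (atan2(y - ctr, x - ctr) + pi) %% (2 * pi)
    if (r >= rin && r <= rout && a >= angFrom && a <= angTo)
      crop[y, x] <- crop[y, x] + amplitude
  }
  crop
}

## random long-format feature fixture for gating tests
randomFeatureTable <- function(n = 1000, nT = 3, seed = 1) {
  set.seed(seed)
  df <- expand.grid(microwell_id = seq_len(n), timepoint = 0:(nT - 1))
  df$hours <- df$timepoint * 4
  df$count <- rpois(nrow(df), 1.2)
  df$gfp <- round(runif(nrow(df), 0, 100), 2)
  df$r <- rep(round(rnorm(n, 0.5, 0.5), 3), nT)
  df[order(df$microwell_id, df$timepoint), ]
}
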