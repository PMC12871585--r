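#' Fit the clonal division rate of a count trajectory
#'
#' Least-squares slope of `log2(count)` against time in days over the
#' timepoints with at least one cell, so the slope is directly the growth
#' rate in cell divisions per day. Positive rates indicate growing
#' populations, negative rates cell death. Zero-count timepoints are
#' excluded (log undefined); trajectories with fewer than two usable points
#' get status `"insufficient_points"`.
#'
#' @param counts integer vector of per-timepoint cell counts.
#' @param timesHours acquisition times in hours.
#' @return list: `r` (divisions/day; `NA` when not estimable), `residual`
#'   (RMSE of the fit in log2 units), `nPointsUsed`, `status`
#'   (`"ok"` or `"insufficient_points"`), `death` (`TRUE` when the fitted
#'   rate is negative).
#' @examples
#' fitDivisionRate(c(1, 2, 4, 8), c(0, 24, 48, 72))$r  # exactly 1
#' @export
fitDivisionRate <- function(counts, timesHours) {
  stopifnot(length(counts) == length(timesHours))
  use <- which(counts >= 1)
  if (length(use) < 2)
    return(list(r = NA_real_, residual = NA_real_,
                nPointsUsed = length(use),
                status = "insufficient_points", death = NA))
  y <- log2(counts[use])
  t <- timesHours[use] / 24
  tm <- t - mean(t)
  r <- sum(tm * y) / sum(tm^2)
  fit <- mean(y) + r * tm
  list(r = r, residual = sqrt(mean((y - fit)^2)),
       nPointsUsed = length(use), status = "ok", death = r < 0)
}

#' Normalized mean cell count
#'
#' Mean cell count over all timepoints (t0 included) divided by the count
#' at the initial timepoint. Values above 1 indicate growth, below 1 cell
#' death. Less sensitive than the exponential fit to an erroneous count at
#' any single timepoint, but also less sensitive to hypergrowth because
#' early timepoints weigh it down; the two estimators are gated jointly by
#' [classifyProliferative()].
#'
#' @param counts integer vector of per-timepoint counts.
#' @param includeT0 whether the t0 term enters the mean (default TRUE).
#' @return dimensionless g >= 0, or `NA` when `counts[1] == 0`.
#' @examples
#' normalizedMeanCount(c(1, 2, 4))  # 7/3
#' @export
normalizedMeanCount <- function(counts, includeT0 = TRUE) {
  if (length(counts) < 1 || counts[1] == 0) return(NA_real_)
  v <- if (includeT0) counts else counts[-1]
  mean(v) / counts[1]
}

#' Dual-parameter proliferation gate
#'
#' A microwell is called proliferative iff both estimators agree:
#' fitted rate `r >= rMin` and normalized mean count `g >= gMin`. Requiring
#' both suppresses artifacts to which a single estimator is susceptible
#' (imaging debris inflating the fit, early-timepoint dominance damping g).
#' Undefined estimates classify `FALSE`.
#'
#' @param r,g numeric vectors from [fitDivisionRate()] /
#'   [normalizedMeanCount()].
#' @param rMin,gMin gate thresholds (defaults 0.25 divisions/day and 1.2;
#'   both are analysis choices to be tuned per experiment and are recorded
#'   in the pipeline provenance).
#' @return logical vector; `attr(, "reason")` gives `"undefined_estimate"`
#'   where an input was `NA`.
#' @export
classifyProliferative <- function(r, g, rMin = 0.25, gMin = 1.2) {
  bad <- is.na(r) | is.na(g)
  out <- !bad & r >= rMin & g >= gMin
  reason <- rep(NA_character_, length(out))
  reason[bad] <- "undefined_estimate"
  attr(out, "reason") <- reason
  out
}

#' Fraction of single-cell microwells whose occupant divided at least once
#'
#' Viable clones are defined as founder cells that divided at least once:
#' the numerator counts single-cell microwells whose trajectory ever
#' reaches 2 cells, the denominator all single-cell microwells.
#'
#' @param counts integer matrix `[n_microwells, T]` of trajectories.
#' @param occupancy integer vector of t0 occupancies.
#' @return scalar fraction in `[0, 1]`.
#' @export
viableCloneFraction <- function(counts, occupancy) {
  stopifnot(nrow(counts) == length(occupancy))
  single <- occupancy == 1
  if (!any(single)) stop("no single-cell microwells in denominator")
  mean(apply(counts[single, , drop = FALSE], 1, max) >= 2)
}

#' Growth estimates for a whole scene
#'
#' Convenience wrapper applying [fitDivisionRate()] and
#' [normalizedMeanCount()] to every row of a trajectory matrix.
#'
#' @param counts integer matrix `[n_microwells, T]`.
#' @param timesHours acquisition times, hours.
#' @param ids microwell ids (default row index).
#' @return data.frame: `microwell_id`, `r`, `g`, `residual`,
#'   `n_points_used`, `status`.
#' @export
growthEstimates <- function(counts, timesHours, ids = seq_len(nrow(counts))) {
  fits <- apply(counts, 1, fitDivisionRate, timesHours = timesHours)
  data.frame(
    microwell_id = ids,
    r = vapply(fits, `[[`, numeric(1), "r"),
    g = apply(counts, 1, normalizedMeanCount),
    residual = vapply(fits, `[[`, numeric(1), "residual"),
    n_points_used = vapply(fits, `[[`, numeric(1), "nPointsUsed"),
    status = vapply(fits, `[[`, character(1), "status"))
}
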