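#' Poisson occupancy probability
#'
#' Probability that a microwell receives exactly `k` cells under stochastic
#' loading at mean density lambda cells/microwell.
#'
#' @param lambda mean cells per microwell (>= 0).
#' @param k cell count (non-negative integer, vectorized).
#' @return `dpois(k, lambda)`.
#' @examples
#' occupancyPmf(1, 1)  # exp(-1)
#' @export
occupancyPmf <- function(lambda, k) {
  stopifnot(lambda >= 0, all(k >= 0), all(k == round(k)))
  dpois(k, lambda)
}

#' Truncated occupancy model table
#'
#' PMF over k = 0..kMax with the Poisson tail mass folded into the last
#' bin, so the table sums to 1 exactly (within 1e-9).
#'
#' @param lambda mean cells per microwell.
#' @param nMicrowells number of microwells (carried for expected counts).
#' @param kMax truncation (default `max(20, ceiling(lambda +
#'   10 * sqrt(lambda)))`).
#' @return list of class `"OccupancyModel"`: `lambda`, `nMicrowells`,
#'   `k`, `pmf`, `expected` (= `nMicrowells * pmf`).
#' @export
occupancyModel <- function(lambda, nMicrowells,
                           kMax = max(20, ceiling(lambda +
                                                    10 * sqrt(lambda)))) {
  stopifnot(lambda >= 0, nMicrowells >= 1)
  k <- 0:kMax
  pmf <- dpois(k, lambda)
  pmf[length(pmf)] <- pmf[length(pmf)] + stats::ppois(kMax, lambda,
                                                      lower.tail = FALSE)
  structure(list(lambda = lambda, nMicrowells = nMicrowells, k = k,
                 pmf = pmf, expected = nMicrowells * pmf),
            class = "OccupancyModel")
}

#' Expected number of single-occupancy microwells
#'
#' Under Poisson loading with lambda = nCells / nMicrowells, the expected
#' single count is `nMicrowells * lambda * exp(-lambda)` — maximized when
#' the number of loaded cells equals the number of microwells (lambda = 1).
#'
#' @param nCells cells loaded.
#' @param nMicrowells microwells available.
#' @return expected count of microwells containing exactly one cell.
#' @examples
#' expectedSingles(4000, 4000)  # 4000 * exp(-1)
#' @export
expectedSingles <- function(nCells, nMicrowells) {
  stopifnot(nCells >= 0, nMicrowells >= 1)
  lambda <- nCells / nMicrowells
  nMicrowells * lambda * exp(-lambda)
}

#' Antigen-library enrichment table
#'
#' Compares the relative abundance of each library member in the bulk pool
#' (bulk sequencing of the original library) with its frequency among the
#' sequences recovered from picked microwells. Frequencies are normalized
#' within each column; fold enrichment is their ratio. Members absent from
#' the recovered pool get fold 0; members absent from the bulk get the
#' `Inf` sentinel with a warning (library dropouts are real, not
#' exceptional).
#'
#' @param bulkCounts,recoveredCounts named non-negative count vectors over
#'   the same member universe.
#' @return data.frame: `member`, `bulk_count`, `bulk_freq`,
#'   `recovered_count`, `recovered_freq`, `fold_enrichment`.
#' @examples
#' enrichmentTable(c(A = 50, B = 50), c(A = 9, B = 1))
#' @export
enrichmentTable <- function(bulkCounts, recoveredCounts) {
  if (length(bulkCounts) == 0 || length(recoveredCounts) == 0)
    stop("empty count table")
  if (is.null(names(bulkCounts)) || is.null(names(recoveredCounts)))
    stop("count vectors must be named by library member")
  members <- names(bulkCounts)
  if (!setequal(members, names(recoveredCounts)))
    stop("bulk and recovered tables cover different member universes")
  rec <- recoveredCounts[members]
  if (any(bulkCounts < 0) || any(rec < 0)) stop("counts must be >= 0")
  if (sum(bulkCounts) == 0 || sum(rec) == 0)
    stop("count totals must be positive")
  bf <- bulkCounts / sum(bulkCounts)
  rf <- rec / sum(rec)
  fold <- ifelse(bf > 0, rf / bf, ifelse(rf > 0, Inf, 0))
  if (any(is.infinite(fold)))
    warning("member(s) absent from bulk but recovered: fold set to Inf")
  data.frame(member = members, bulk_count = as.numeric(bulkCounts),
             bulk_freq = as.numeric(bf),
             recovered_count = as.numeric(rec),
             recovered_freq = as.numeric(rf),
             fold_enrichment = as.numeric(fold), row.names = NULL)
}

#' Per-microwell dominant-antigen call
#'
#' For each microwell's read-count vector, the member holding the highest
#' read fraction is called if that fraction reaches `minFraction`;
#' otherwise (including exact ties and all-zero rows) the call is
#' `"ambiguous"`.
#'
#' @param reads matrix or data.frame of read counts, microwells in rows and
#'   library members in columns.
#' @param minFraction minimum dominant read fraction (default 0.5).
#' @return data.frame: `microwell`, `call`, `fraction`, `zero_reads`.
#' @export
dominantAntigen <- function(reads, minFraction = 0.5) {
  reads <- as.matrix(reads)
  if (any(reads < 0)) stop("read counts must be >= 0")
  members <- colnames(reads)
  if (is.null(members)) members <- paste0("member", seq_len(ncol(reads)))
  calls <- apply(reads, 1, function(v) {
    tot <- sum(v)
    if (tot == 0) return(c("ambiguous", NA, TRUE))
    fr <- v / tot
    top <- max(fr)
    if (top < minFraction || sum(fr == top) > 1)
      return(c("ambiguous", top, FALSE))
    c(members[which.max(fr)], top, FALSE)
  })
  data.frame(microwell = seq_len(nrow(reads)), call = calls[1, ],
             fraction = as.numeric(calls[2, ]),
             zero_reads = as.logical(calls[3, ]), row.names = NULL)
}

#' Expected 1:1 co-culture yield of a sequential-loading screen
#'
#' Two cell types loaded sequentially: the expected number of microwells
#' holding exactly one of each is the product of the plate scale and the
#' two single-occupancy probabilities.
#'
#' @param nWells wells used.
#' @param microwellsPerWell imaged microwells per well.
#' @param pSingleA probability a microwell holds exactly one cell of the
#'   first type.
#' @param pSingleBGivenA probability it additionally holds exactly one of
#'   the second type.
#' @return expected 1:1 co-culture count.
#' @export
screeningYield <- function(nWells, microwellsPerWell, pSingleA,
                           pSingleBGivenA) {
  stopifnot(pSingleA >= 0, pSingleA <= 1,
            pSingleBGivenA >= 0, pSingleBGivenA <= 1)
  nWells * microwellsPerWell * pSingleA * pSingleBGivenA
}
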