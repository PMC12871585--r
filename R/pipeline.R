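#' Run the full analysis pipeline on a stack
#'
#' Orchestrates the computational stages in order: lattice detection on the
#' t0 brightfield frame, per-timepoint registration, per-microwell cell
#' counting and fluorescence quantification, growth estimation, secretion
#' quantification and calling (when a cytokine channel is present),
#' hierarchical gating, and pick-list export. Artifacts are written to
#' `outDir` (append-only: a stage never mutates another stage's outputs)
#' together with a JSON provenance record capturing the package version,
#' every threshold used, and the seed — so a re-run with an identical
#' configuration is byte-identical.
#'
#' @param stack a [FrameStack-class] or path to an OME-NGFF store.
#' @param layout a [plateLayout()].
#' @param outDir output directory (created if missing).
#' @param well well label recorded in the feature table.
#' @param gateTree optional [gateNode()] tree; default selects single-cell
#'   microwells and gates them on the dual proliferation parameters.
#' @param markerRules optional list of [markerRule()]s.
#' @param secretionChannel cytokine channel name, used when present in the
#'   stack.
#' @param sThreshold absolute secretion threshold, or `NULL` to skip
#'   calling when no control data are available.
#' @param rMin,gMin proliferation gate thresholds.
#' @param nBlanks blank controls to insert in the pick list.
#' @param seed seed for blank placement.
#' @return invisible list of the main artifacts: `grid`, `features`,
#'   `gates`, `picklist` (paths in `attr(, "paths")`).
#' @export
runPipeline <- function(stack, layout = plateLayout(), outDir,
                        well = "A1", gateTree = NULL, markerRules = NULL,
                        secretionChannel = "IFNg", sThreshold = NULL,
                        rMin = 0.25, gMin = 1.2, nBlanks = 0L, seed = 1L) {
  if (is.character(stack)) {
    if (!file.exists(stack)) stop("input stack not found: ", stack)
    stack <- openStack(stack)
  }
  stopifnot(is(stack, "FrameStack"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  nT <- dim(stack)[1]

  ## detect + register ------------------------------------------------------
  grid <- detectGrid(getFrame(stack, 1, "BF"), layout)
  grid <- registerStack(grid, stack, "BF")
  accessible(grid) <- accessibleMask(grid, layout)
  write.csv(microwells(grid), file.path(outDir, "grid.csv"),
            row.names = FALSE)
  .zarrWriteJSON(list(shifts = unname(apply(grid@shifts, 1, c,
                                            simplify = FALSE)),
                      pitch_px = grid@pitchPx,
                      theta_deg = grid@thetaDeg),
                 file.path(outDir, "registration.json"))

  ## quantify ---------------------------------------------------------------
  ids <- microwells(grid)$id
  fluorCh <- setdiff(channelNames(stack), "BF")
  rows <- vector("list", nT)
  for (t in seq_len(nT)) {
    cnt <- integer(length(ids)); crowded <- logical(length(ids))
    labCounts <- NULL
    for (j in seq_along(ids)) {
      crop <- cropMicrowell(stack, grid, ids[j], t, "BF")
      cells <- countCells(crop, pixelSizeUm = pixelSize(stack))
      cnt[j] <- nrow(cells)
      crowded[j] <- isTRUE(attr(cells, "crowded"))
      if (!is.null(markerRules) && nrow(cells)) {
        crops <- lapply(setNames(fluorCh, fluorCh), function(ch)
          cropMicrowell(stack, grid, ids[j], t, ch))
        cells <- classifyCells(cellIntensities(cells, crops), markerRules)
        lc <- vapply(markerRules, function(r) sum(cells[[r$label]]),
                     integer(1))
        if (is.null(labCounts))
          labCounts <- matrix(0L, length(ids), length(markerRules),
                              dimnames = list(NULL, vapply(markerRules,
                                `[[`, "", "label")))
        labCounts[j, ] <- lc
      }
    }
    df <- data.frame(well = well, microwell_id = ids, timepoint = t - 1L,
                     hours = timesHours(stack)[t], count = cnt,
                     crowded = crowded)
    if (!is.null(labCounts)) df <- cbind(df, as.data.frame(labCounts))
    rows[[t]] <- df
  }
  features <- do.call(rbind, rows)

  ## growth -----------------------------------------------------------------
  cmat <- matrix(features$count[order(features$microwell_id,
                                      features$timepoint)],
                 nrow = length(ids), byrow = TRUE)
  est <- growthEstimates(cmat, timesHours(stack), ids = sort(ids))
  est$proliferative <- as.logical(classifyProliferative(est$r, est$g,
                                                        rMin, gMin))
  features <- merge(features, est, by = "microwell_id", sort = FALSE)
  features <- features[order(features$microwell_id, features$timepoint), ]

  ## secretion --------------------------------------------------------------
  calls <- NULL
  if (secretionChannel %in% channelNames(stack)) {
    sig <- quantifySecretion(stack, grid, secretionChannel)
    features <- merge(features, sig[c("microwell_id", "timepoint",
                                      "I", "S", "sym")],
                      by = c("microwell_id", "timepoint"), sort = FALSE)
    if (!is.null(sThreshold)) {
      calls <- callPositive(sig, sThreshold)
      features <- merge(features,
                        calls[c("microwell_id", "positive",
                                "first_positive_t")],
                        by = "microwell_id", sort = FALSE)
    }
    write.csv(sig, file.path(outDir, "secretion.csv"), row.names = FALSE)
  }
  features <- features[order(features$microwell_id, features$timepoint), ]
  rownames(features) <- NULL
  writeFeatureTable(features, file.path(outDir, "features.csv"))

  ## gate -------------------------------------------------------------------
  if (is.null(gateTree))
    gateTree <- gateNode("all", "", list(
      gateNode("single_cell", "count@t0 == 1", list(
        gateNode("proliferative",
                 sprintf("r@last >= %g AND g@last >= %g", rMin, gMin))))))
  gates <- applyGateTree(features, gateTree)
  gsum <- gateSummary(gates)
  write.csv(gsum, file.path(outDir, "gates.csv"), row.names = FALSE)

  ## picklist ---------------------------------------------------------------
  leaf <- gsum$path[nrow(gsum)]
  sel <- .leafMembers(gates)
  sel <- sel[sel %in% microwells(grid)$id[accessible(grid)]]
  picklist <- NULL
  if (length(sel)) {
    emptyIds <- microwells(grid)$id[
      features$count[features$timepoint == 0][
        match(microwells(grid)$id,
              features$microwell_id[features$timepoint == 0])] == 0]
    nb <- min(nBlanks, length(intersect(
      emptyIds, microwells(grid)$id[accessible(grid)])))
    picklist <- buildPickList(sel, grid, nBlanks = nb, seed = seed,
                              emptyIds = emptyIds, well = well)
    writePickList(picklist, file.path(outDir, "picklist.csv"))
  }

  ## provenance -------------------------------------------------------------
  .zarrWriteJSON(list(
    package = "conewell",
    version = as.character(utils::packageVersion("conewell")),
    seed = seed, well = well,
    thresholds = list(r_min = rMin, g_min = gMin,
                      s_threshold = sThreshold,
                      sym_threshold = 0.5,
                      accessible_area_fraction =
                        layout$accessibleAreaFraction,
                      size_gate_um = c(5, 20)),
    stages = c("detect", "register", "quantify", "growth",
               if (secretionChannel %in% channelNames(stack)) "secretion",
               "gate", if (!is.null(picklist)) "picklist")),
    file.path(outDir, "provenance.json"))

  invisible(list(grid = grid, features = features, gates = gates,
                 picklist = picklist))
}

## members of the deepest first-path leaf
.leafMembers <- function(node) {
  while (length(node@children)) node <- node@children[[1]]
  node@memberIds
}
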