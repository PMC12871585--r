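#' @rdname FrameStack-class
#' @param object,x a FrameStack or MicrowellGrid.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname FrameStack-class
#' @export
setMethod("channelNames", "FrameStack", function(x) x@channels)

#' @rdname FrameStack-class
#' @export
setGeneric("timesHours", function(x) standardGeneric("timesHours"))

#' @rdname FrameStack-class
#' @export
setMethod("timesHours", "FrameStack", function(x) x@timesHours)

#' @rdname FrameStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname FrameStack-class
#' @export
setMethod("pixelSize", "FrameStack", function(x) x@pixelSizeUm)

#' @rdname MicrowellGrid-class
#' @export
setMethod("pixelSize", "MicrowellGrid", function(x) x@pixelSizeUm)

#' @rdname FrameStack-class
#' @export
setMethod("dim", "FrameStack", function(x) x@shape)

setMethod("show", "FrameStack", function(object) {
  d <- object@shape
  cat("FrameStack (TCZYX):", paste(d, collapse = " x "), "\n")
  cat("  channels:", paste(object@channels, collapse = ", "), "\n")
  cat("  times [h]:", paste(signif(object@timesHours, 4), collapse = ", "),
      "\n")
  cat("  pixel size:", object@pixelSizeUm, "um;",
      if (is.na(object@path)) "in memory" else paste("store:", object@path),
      "\n")
})

#' Microwell table of a grid
#'
#' @param x a [MicrowellGrid-class].
#' @return data.frame with one row per microwell (`id`, `row`, `col`, `y`,
#'   `x`, `score`, `accessible`).
#' @export
setGeneric("microwells", function(x) standardGeneric("microwells"))

#' @rdname microwells
#' @export
setMethod("microwells", "MicrowellGrid", function(x) x@info)

#' @rdname microwells
#' @export
setMethod("microwells", "SceneTruth", function(x) x@microwells)

#' Registration shifts of a grid
#'
#' @param x a [MicrowellGrid-class].
#' @return numeric matrix `[T, 2]` of per-timepoint (dy, dx) shifts in px.
#' @export
setGeneric("gridShifts", function(x) standardGeneric("gridShifts"))

#' @rdname gridShifts
#' @export
setMethod("gridShifts", "MicrowellGrid", function(x) x@shifts)

#' Accessibility flags of a grid
#'
#' @param x a [MicrowellGrid-class].
#' @param value logical vector, one flag per microwell.
#' @return `accessible()` returns the logical flag vector.
#' @export
setGeneric("accessible", function(x) standardGeneric("accessible"))

#' @rdname accessible
#' @export
setMethod("accessible", "MicrowellGrid", function(x) x@info$accessible)

#' @rdname accessible
#' @export
setGeneric("accessible<-", function(x, value) standardGeneric("accessible<-"))

#' @rdname accessible
#' @export
setMethod("accessible<-", "MicrowellGrid", function(x, value) {
  stopifnot(is.logical(value), length(value) == nrow(x@info))
  x@info$accessible <- value
  validObject(x)
  x
})

setMethod("show", "MicrowellGrid", function(object) {
  cat("MicrowellGrid:", nrow(object@info), "microwells,",
      sum(object@info$accessible), "accessible\n")
  cat("  pitch:", signif(object@pitchPx, 5), "px; rotation:",
      signif(object@thetaDeg, 3), "deg;",
      nrow(object@shifts), "timepoint shift(s)\n")
})

setMethod("show", "SceneTruth", function(object) {
  cat("SceneTruth:", nrow(object@microwells), "microwells,",
      ncol(object@counts), "timepoints,",
      object@nCellsLoaded, "cells loaded\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat("SceneConfig:", object@gridRows, "x", object@gridCols, object@lattice,
      "lattice, pitch", object@pitchUm, "um @", object@pixelSizeUm,
      "um/px\n")
  cat("  ", object@nTimepoints, " timepoints every ", object@intervalHours,
      " h; channels: ", paste(object@channels, collapse = ", "),
      "; seed ", object@seed, "\n", sep = "")
})

setMethod("show", "GateNode", function(object) {
  .showGate <- function(node, depth) {
    lab <- if (is.na(node@count)) "(not evaluated)"
      else sprintf("n=%d (%.3g%% of parent)", node@count,
                   node@fractionOfParent)
    cat(strrep("  ", depth), node@name,
        if (nzchar(node@predicate)) paste0(" [", node@predicate, "]") else "",
        " ", lab, "\n", sep = "")
    for (ch in node@children) .showGate(ch, depth + 1)
  }
  .showGate(object, 0)
})
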