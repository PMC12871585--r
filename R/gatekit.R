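## Predicate grammar: clauses joined by " AND ", each clause
##   <feature>@<selector> <cmp> <value>
## with selectors
##   t0, t1, ...     timepoint index (t0 = first acquisition)
##   first, last     first/last timepoint present for the microwell
##   any(t>=H)       exists a timepoint with hours >= H satisfying the clause
##   any(t<=H)       likewise with hours <= H
## comparators ==, !=, >=, <=, >, < and numeric or TRUE/FALSE values.
## Disjunctions are expressed as sibling gates.

.clauseRe <- paste0("^\\s*([A-Za-z_][A-Za-z0-9_.]*)@([A-Za-z0-9()<>=.]+)",
                    "\\s*(==|!=|>=|<=|>|<)\\s*",
                    "(-?[0-9.eE+]+|TRUE|FALSE)\\s*$")

.parseClause <- function(clause) {
  m <- regmatches(clause, regexec(.clauseRe, clause))[[1]]
  if (length(m) == 0)
    stop("cannot parse gate clause: '", clause, "'")
  val <- if (m[5] %in% c("TRUE", "FALSE")) as.logical(m[5]) else
    as.numeric(m[5])
  list(feature = m[2], selector = m[3], cmp = m[4], value = val)
}

.applyCmp <- function(v, cmp, value) {
  switch(cmp,
         "==" = v == value, "!=" = v != value, ">=" = v >= value,
         "<=" = v <= value, ">" = v > value, "<" = v < value)
}

## evaluate one clause -> logical per microwell id (in `ids` order)
.evalClause <- function(clause, ft, ids) {
  cl <- .parseClause(clause)
  if (!cl$feature %in% names(ft))
    stop("gate predicate references unknown feature '", cl$feature, "'")
  sel <- cl$selector
  sp <- split(seq_len(nrow(ft)), ft$microwell_id)
  rowsOf <- sp[as.character(ids)]
  if (any(vapply(rowsOf, is.null, logical(1))))
    stop("feature table lacks rows for some member microwells")
  pickVal <- function(ix) {
    tp <- ft$timepoint[ix]
    if (grepl("^t[0-9]+$", sel)) {
      want <- as.integer(sub("^t", "", sel))
      j <- ix[tp == want]
      if (length(j) == 0)
        stop("gate selector '@", sel, "' has no matching timepoint")
      ft[[cl$feature]][j[1]]
    } else if (sel == "first") {
      ft[[cl$feature]][ix[which.min(tp)]]
    } else if (sel == "last") {
      ft[[cl$feature]][ix[which.max(tp)]]
    } else NA
  }
  if (grepl("^any\\(t(>=|<=)", sel)) {
    op <- sub("^any\\(t(>=|<=).*", "\\1", sel)
    h <- as.numeric(sub("^any\\(t(>=|<=)([0-9.]+)h?\\)$", "\\2", sel))
    if (is.na(h)) stop("cannot parse gate selector '@", sel, "'")
    vapply(rowsOf, function(ix) {
      keep <- if (op == ">=") ft$hours[ix] >= h else ft$hours[ix] <= h
      any(.applyCmp(ft[[cl$feature]][ix[keep]], cl$cmp, cl$value),
          na.rm = TRUE)
    }, logical(1))
  } else {
    v <- vapply(rowsOf, pickVal, ft[[cl$feature]][1])
    res <- .applyCmp(v, cl$cmp, cl$value)
    res & !is.na(res)
  }
}

.evalPredicate <- function(predicate, ft, ids) {
  if (!nzchar(trimws(predicate))) return(rep(TRUE, length(ids)))
  clauses <- strsplit(predicate, "\\s+AND\\s+")[[1]]
  Reduce(`&`, lapply(clauses, .evalClause, ft = ft, ids = ids))
}

#' Evaluate a hierarchical gate tree against a feature table
#'
#' Top-down evaluation: the root members are all microwells in the table
#' satisfying the root predicate (an empty predicate means all imaged
#' microwells), and every child's members are exactly the parent members
#' satisfying the child's predicate. Counts and fractions of parent are
#' populated on every node.
#'
#' @param featureTable long-format data.frame with columns `microwell_id`,
#'   `timepoint` (0-based), `hours`, plus the features referenced by the
#'   predicates.
#' @param tree root [GateNode-class] (see [gateNode()]).
#' @return the tree with `memberIds`, `count`, `parentCount` and
#'   `fractionOfParent` filled in on every node.
#' @examples
#' ft <- data.frame(microwell_id = 1:4, timepoint = 0, hours = 0,
#'                  count = c(1, 1, 2, 0))
#' tr <- applyGateTree(ft, gateNode("all", "",
#'         list(gateNode("singles", "count@t0 == 1"))))
#' tr@children[[1]]@count  # 2
#' @export
applyGateTree <- function(featureTable, tree) {
  stopifnot(is(tree, "GateNode"))
  need <- c("microwell_id", "timepoint")
  if (!all(need %in% names(featureTable)))
    stop("feature table needs columns ", paste(need, collapse = ", "))
  if (!"hours" %in% names(featureTable))
    featureTable$hours <- featureTable$timepoint
  allIds <- sort(unique(featureTable$microwell_id))
  .evalNode <- function(node, parentIds, parentCount) {
    keep <- .evalPredicate(node@predicate, featureTable, parentIds)
    node@memberIds <- as.integer(parentIds[keep])
    node@count <- length(node@memberIds)
    node@parentCount <- as.integer(parentCount)
    node@fractionOfParent <- if (parentCount > 0)
      100 * node@count / parentCount else NA_real_
    node@children <- lapply(node@children, .evalNode,
                            parentIds = node@memberIds,
                            parentCount = node@count)
    node
  }
  .evalNode(tree, allIds, length(allIds))
}

#' Gate percentage with half-up rounding
#'
#' `100 * count / parentCount`, rounded half away from zero to the stated
#' precision — the convention under which 47,597 of 137,758 prints as 35%
#' and 107 of 16,070 as 0.7%.
#'
#' @param x an evaluated [GateNode-class], or a numeric member count.
#' @param parent parent member count (ignored when `x` is a GateNode).
#' @param digits decimal places of the printed percentage.
#' @return rounded percentage.
#' @examples
#' gateFraction(47597, 137758)      # 35
#' gateFraction(107, 16070, 1)      # 0.7
#' @export
gateFraction <- function(x, parent = NULL, digits = 0) {
  if (is(x, "GateNode")) {
    if (is.na(x@count)) stop("gate node has not been evaluated")
    count <- x@count; parent <- x@parentCount
  } else count <- x
  if (is.null(parent) || is.na(parent)) stop("parent count required")
  if (parent == 0) stop("zero parent population")
  roundHalfUp(100 * count / parent, digits)
}

#' Collect all nodes of a gate tree
#'
#' @param tree an evaluated [GateNode-class].
#' @param path internal (gate path prefix).
#' @return data.frame: `gate`, `path`, `count`, `parent_count`,
#'   `fraction_of_parent`.
#' @export
gateSummary <- function(tree, path = tree@name) {
  own <- data.frame(gate = tree@name, path = path, count = tree@count,
                    parent_count = tree@parentCount,
                    fraction_of_parent = tree@fractionOfParent)
  kids <- lapply(tree@children, function(ch)
    gateSummary(ch, paste(path, ch@name, sep = "/")))
  do.call(rbind, c(list(own), kids))
}

#' Build a robotic pick list
#'
#' Orders the selected microwells (optionally interleaving labels in
#' alternating fashion, e.g. GFP+, mCherry+, GFP+, ...), inserts
#' blank-control entries — empty accessible microwells at seeded-random
#' positions in the picking order — and assigns deposition-plate wells
#' sequentially. Stage coordinates are the t0 center plus the last
#' registered shift, converted to micrometers. Every entry must be
#' picker-accessible; inaccessible selections are an error, never silently
#' dropped.
#'
#' @param selectedIds microwell ids to pick.
#' @param grid a registered [MicrowellGrid-class] with accessibility flags
#'   set (see [accessibleMask()]).
#' @param depositionLayout list with `rows` and `cols` of the deposition
#'   plate (default 8 x 12 = 96 wells).
#' @param nBlanks number of blank controls to insert.
#' @param seed seed for the blank positions.
#' @param labels optional per-selection labels driving the interleave and
#'   recorded as the gate path.
#' @param emptyIds ids of empty microwells eligible as blanks (required
#'   when `nBlanks > 0`).
#' @return data.frame of class `"PickList"`: `pick_order`, `well`,
#'   `microwell_id`, `y_um`, `x_um`, `deposition_well`, `gate_path`,
#'   `is_blank`.
#' @export
buildPickList <- function(selectedIds, grid, depositionLayout =
                            list(rows = 8L, cols = 12L),
                          nBlanks = 0L, seed = 1L, labels = NULL,
                          emptyIds = integer(), well = "A1") {
  info <- grid@info
  sel <- match(selectedIds, info$id)
  if (anyNA(sel)) stop("unknown microwell id(s): ",
                       paste(selectedIds[is.na(sel)], collapse = ", "))
  if (!all(info$accessible[sel]))
    stop("selection contains picker-inaccessible microwell(s): ",
         paste(selectedIds[!info$accessible[sel]], collapse = ", "))
  nBlanks <- .checkCount(nBlanks, "nBlanks", min = 0)
  capacity <- depositionLayout$rows * depositionLayout$cols
  if (length(selectedIds) + nBlanks > capacity)
    stop("deposition capacity exceeded: ", length(selectedIds) + nBlanks,
         " entries for ", capacity, " wells")

  ## interleave labels round-robin (alternating picking order)
  ord <- seq_along(selectedIds)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(selectedIds))
    groups <- split(ord, labels)
    ord <- integer(0)
    while (any(lengths(groups) > 0)) {
      for (g in names(groups)) {
        if (length(groups[[g]])) {
          ord <- c(ord, groups[[g]][1])
          groups[[g]] <- groups[[g]][-1]
        }
      }
    }
  }
  ids <- selectedIds[ord]
  paths <- if (is.null(labels)) rep("selection", length(ids)) else
    as.character(labels[ord])
  blank <- rep(FALSE, length(ids))

  if (nBlanks > 0) {
    emptyIdx <- match(emptyIds, info$id)
    emptyIdx <- emptyIdx[!is.na(emptyIdx) & info$accessible[emptyIdx] &
                           !info$id[emptyIdx] %in% ids]
    if (length(emptyIdx) < nBlanks)
      stop("not enough empty accessible microwells for ", nBlanks,
           " blank controls")
    set.seed(seed)
    blanks <- info$id[sample(emptyIdx, nBlanks)]
    pos <- sort(sample.int(length(ids) + nBlanks, nBlanks))
    full <- integer(length(ids) + nBlanks)
    isb <- logical(length(full))
    isb[pos] <- TRUE
    full[pos] <- blanks
    full[!isb] <- ids
    fpaths <- character(length(full))
    fpaths[isb] <- "blank_control"
    fpaths[!isb] <- paths
    ids <- full; blank <- isb; paths <- fpaths
  }

  idx <- match(ids, info$id)
  lastShift <- grid@shifts[nrow(grid@shifts), ]
  dep <- paste0(LETTERS[((seq_along(ids) - 1) %/% depositionLayout$cols) + 1],
                ((seq_along(ids) - 1) %% depositionLayout$cols) + 1)
  out <- data.frame(
    pick_order = seq_along(ids), well = well, microwell_id = ids,
    y_um = (info$y[idx] + lastShift[1]) * grid@pixelSizeUm,
    x_um = (info$x[idx] + lastShift[2]) * grid@pixelSizeUm,
    deposition_well = dep, gate_path = paths, is_blank = blank)
  class(out) <- c("PickList", "data.frame")
  out
}

#' Write a pick list as CSV
#'
#' @param picklist a [buildPickList()] result.
#' @param path CSV path.
#' @return `invisible(path)`.
#' @export
writePickList <- function(picklist, path) {
  write.csv(as.data.frame(picklist), path, row.names = FALSE)
  invisible(path)
}

#' Expected hit rate of an equally distributed antigen library
#'
#' With `librarySize` equally abundant members of which `cognateCount` are
#' cognate, the expected fraction of 1:1 co-cultures that activate is
#' simply `100 * cognateCount / librarySize` percent — e.g. 1% for one
#' cognate member in a 100-member library.
#'
#' @param librarySize number of library members (> 0).
#' @param cognateCount number of cognate members (1..librarySize).
#' @return expected percentage.
#' @examples
#' expectedLibraryHitRate(100, 1)  # 1
#' @export
expectedLibraryHitRate <- function(librarySize, cognateCount) {
  librarySize <- .checkCount(librarySize, "librarySize", min = 1)
  cognateCount <- .checkCount(cognateCount, "cognateCount", min = 1)
  if (cognateCount > librarySize)
    stop("cognateCount cannot exceed librarySize")
  100 * cognateCount / librarySize
}
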