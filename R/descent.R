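#' Coupled hypothesis blocks
#'
#' A hypothesis block couples one node from the X cluster tree with one
#' node from the Y cluster tree; its cells are the implied rectangle of
#' feature pairs.
#'
#' @param x_node,y_node nodes of two `cluster_tree`s (see [build_tree()]).
#' @return Object of class `hypothesis_block` with the two nodes and their
#'   index sets.
#' @export
hypothesis_block <- function(x_node, y_node) {
  structure(list(x_node = x_node, y_node = y_node,
                 x_set = x_node$set, y_set = y_node$set),
            class = "hypothesis_block")
}

block_sets <- function(block) {
  if (inherits(block, "hypothesis_block")) {
    list(x = block$x_set, y = block$y_set)
  } else {
    list(x = block$x_set, y = block$y_set)
  }
}

#' Fraction of block cells failing the global BH threshold
#'
#' The fraction of cells in the block's rectangle with `p > k_bh`.  When
#' the rejection set is empty the fraction is 1 for any nonempty block.
#'
#' @param block a [hypothesis_block()] (or any list with `x_set`/`y_set`).
#' @param P p-value matrix over all X x Y pairs.
#' @param ctx an `fdr_context` from [bh_threshold()].
#' @return Real in `[0, 1]`.
#' @export
block_fail_fraction <- function(block, P, ctx) {
  s <- block_sets(block)
  cells <- P[s$x, s$y, drop = FALSE]
  if (length(cells) == 0L) stop("empty block")
  if (ctx$n_reject == 0L) return(1)
  1 - sum(cells <= ctx$k_bh) / length(cells)
}

#' Block significance under the false-negative tolerance
#'
#' A block is significant iff its fail fraction is at most `fnt`.  For a
#' 1x1 block this reduces to `p <= k_bh`.
#'
#' @inheritParams block_fail_fraction
#' @param fnt false-negative tolerance in `[0, 1]`.
#' @return Logical.
#' @export
block_significant <- function(block, P, ctx, fnt = 0.2) {
  block_fail_fraction(block, P, ctx) <= fnt
}

#' Binary Gini impurity
#'
#' `1 - p1^2 - p0^2` for a vector of binary labels (here: per-cell BH
#' rejection indicators).
#'
#' @param labels logical or 0/1 vector.
#' @return Real in `[0, 0.5]`.
#' @export
gini_impurity <- function(labels) {
  if (length(labels) == 0L) stop("empty label set")
  p1 <- mean(as.logical(labels))
  1 - p1^2 - (1 - p1)^2
}

# Gini gain of cutting the rectangle (xs x ys) along one side's children,
# computed from the logical rejection matrix R.
gain_for_split <- function(R, xs, ys, side, left_set, right_set) {
  cells <- R[xs, ys, drop = FALSE]
  n <- length(cells)
  parent <- gini_impurity(cells)
  if (side == "X") {
    c1 <- R[left_set, ys, drop = FALSE]
    c2 <- R[right_set, ys, drop = FALSE]
  } else {
    c1 <- R[xs, left_set, drop = FALSE]
    c2 <- R[xs, right_set, drop = FALSE]
  }
  parent - (length(c1) / n) * gini_impurity(c1) -
    (length(c2) / n) * gini_impurity(c2)
}

#' Gini gain of splitting a block along one tree
#'
#' Children are the chosen side's two subtrees crossed with the other
#' side's full set; child impurities are weighted by cell count.
#'
#' @inheritParams block_fail_fraction
#' @param side `"X"` or `"Y"`; that side's node must be internal.
#' @return Nonnegative real gain.
#' @export
split_gain <- function(block, side, P, ctx) {
  side <- match.arg(side, c("X", "Y"))
  node <- if (side == "X") block$x_node else block$y_node
  if (is.null(node) || isTRUE(node$leaf)) {
    stop("cannot split a leaf on side ", side)
  }
  R <- reject_matrix(P, ctx)
  gain_for_split(R, block$x_set, block$y_set, side,
                 node$left$set, node$right$set)
}

#' Choose the descent direction for a failed block
#'
#' Returns the side with the strictly higher Gini gain, `"BOTH"` on an
#' exact tie when both sides are internal, or the only internal side when
#' the other is a leaf.
#'
#' @inheritParams block_fail_fraction
#' @return `"X"`, `"Y"` or `"BOTH"`.
#' @export
choose_split <- function(block, P, ctx) {
  x_int <- !isTRUE(block$x_node$leaf)
  y_int <- !isTRUE(block$y_node$leaf)
  if (!x_int && !y_int) stop("both sides are leaves; nothing to split")
  if (!y_int) return("X")
  if (!x_int) return("Y")
  gx <- split_gain(block, "X", P, ctx)
  gy <- split_gain(block, "Y", P, ctx)
  if (gx > gy) "X" else if (gy > gx) "Y" else "BOTH"
}

new_report_block <- function(x_set, y_set, fail_fraction) {
  list(x_set = x_set, y_set = y_set, fail_fraction = fail_fraction,
       best_p = NA_real_, best_q = NA_real_, rank = NA_integer_)
}

#' Hierarchical descent through the coupled trees
#'
#' Starts at the pair of roots.  A block whose fail fraction is at most
#' `fnt` is reported and its branch stops (maximality).  Otherwise the
#' block is cut along the side chosen by [choose_split()] (`BOTH` yields
#' the four cross-product children) and the recursion continues; a 1x1
#' block failing the threshold is discarded.  Branch rectangles containing
#' no rejected cell are pruned: no descendant can pass unless `fnt >= 1`,
#' in which case the block itself already passed.
#'
#' @param x_tree,y_tree `cluster_tree`s over the rows/columns of `P`.
#' @param P p-value matrix (`n_x` x `n_y`).
#' @param ctx `fdr_context` computed over all of `P`.
#' @param fnt false-negative tolerance.
#' @return Unranked `block_report`; pass through [rank_blocks()] to order
#'   and annotate it.
#' @export
descend <- function(x_tree, y_tree, P, ctx, fnt = 0.2) {
  stopifnot(length(x_tree$labels) == nrow(P),
            length(y_tree$labels) == ncol(P))
  R <- reject_matrix(P, ctx)
  blocks <- list()
  seen <- new.env(hash = TRUE, parent = emptyenv())
  recurse <- function(xn, yn) {
    key <- paste0(xn$id, ":", yn$id)
    if (!is.null(seen[[key]])) return(invisible(NULL))
    seen[[key]] <- TRUE
    cells <- R[xn$set, yn$set, drop = FALSE]
    nrej <- sum(cells)
    ff <- if (ctx$n_reject == 0L) 1 else 1 - nrej / length(cells)
    if (ff <= fnt) {
      blocks[[length(blocks) + 1L]] <<- new_report_block(xn$set, yn$set, ff)
      return(invisible(NULL))
    }
    if (nrej == 0L) return(invisible(NULL))       # nothing below can pass
    if (xn$leaf && yn$leaf) return(invisible(NULL)) # failed 1x1: discard
    side <- choose_split(hypothesis_block(xn, yn), P, ctx)
    if (side == "X") {
      recurse(xn$left, yn)
      recurse(xn$right, yn)
    } else if (side == "Y") {
      recurse(xn, yn$left)
      recurse(xn, yn$right)
    } else {
      recurse(xn$left, yn$left)
      recurse(xn$left, yn$right)
      recurse(xn$right, yn$left)
      recurse(xn$right, yn$right)
    }
    invisible(NULL)
  }
  recurse(x_tree$root, y_tree$root)
  structure(list(blocks = blocks,
                 x_ids = x_tree$labels, y_ids = y_tree$labels),
            class = "block_report")
}

#' Rank reported blocks by significance
#'
#' Sorts blocks by their best (minimum) member p-value; ties go to the
#' larger cell count, then to lexicographic feature IDs.  Fills `best_p`,
#' `best_q` (minimum member BH q-value) and ranks 1..K.
#'
#' @param report a `block_report` from [descend()].
#' @param P,Q p-value and q-value matrices over all pairs.
#' @return The ranked `block_report`.
#' @export
rank_blocks <- function(report, P, Q) {
  if (length(report$blocks) == 0L) return(report)
  info <- lapply(report$blocks, function(b) {
    cells_p <- P[b$x_set, b$y_set, drop = FALSE]
    cells_q <- Q[b$x_set, b$y_set, drop = FALSE]
    b$best_p <- min(cells_p)
    b$best_q <- min(cells_q)
    b
  })
  key_ids <- vapply(info, function(b) {
    paste(c(sort(report$x_ids[b$x_set]), sort(report$y_ids[b$y_set])),
          collapse = ";")
  }, character(1L))
  sizes <- vapply(info, function(b) length(b$x_set) * length(b$y_set),
                  numeric(1L))
  bp <- vapply(info, function(b) b$best_p, numeric(1L))
  ord <- order(bp, -sizes, key_ids)
  info <- info[ord]
  for (k in seq_along(info)) info[[k]]$rank <- k
  report$blocks <- info
  report
}

#' @export
print.block_report <- function(x, ...) {
  k <- length(x$blocks)
  cat("block_report: ", k, " significant block(s)\n", sep = "")
  for (b in head(x$blocks, 10L)) {
    cat(sprintf("  #%s  %dx%d  best_p=%.3g  fail=%.2f  [%s] ~ [%s]\n",
                ifelse(is.na(b$rank), "?", b$rank),
                length(b$x_set), length(b$y_set), b$best_p, b$fail_fraction,
                paste(head(x$x_ids[b$x_set], 4L), collapse = ","),
                paste(head(x$y_ids[b$y_set], 4L), collapse = ",")))
  }
  if (k > 10L) cat("  ...\n")
  invisible(x)
}

#' Significant-block table
#'
#' @param x a ranked `block_report`
#' @param ... unused
#' @return `data.frame` with one row per block: rank, `;`-joined X and Y
#'   feature IDs, best p, best q, and block size in cells.
#' @export
as.data.frame.block_report <- function(x, ...) {
  if (length(x$blocks) == 0L) {
    return(data.frame(rank = integer(), X_features = character(),
                      Y_features = character(), best_p = numeric(),
                      best_q = numeric(), block_size = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(x$blocks, function(b) {
    data.frame(rank = b$rank,
               X_features = paste(x$x_ids[b$x_set], collapse = ";"),
               Y_features = paste(x$y_ids[b$y_set], collapse = ";"),
               best_p = b$best_p, best_q = b$best_q,
               block_size = length(b$x_set) * length(b$y_set),
               stringsAsFactors = FALSE)
  }))
}
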