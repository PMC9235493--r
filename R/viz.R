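signed_measure <- function(measure) measure %in% c("spearman", "pearson")

# Restrict the dendrogram leaf order to the features appearing in any
# reported block; each block's features stay contiguous because blocks are
# tree nodes.
shown_order <- function(tree, blocks, which_side) {
  feats <- sort(unique(unlist(lapply(blocks, `[[`,
                                     paste0(which_side, "_set")))))
  ord <- tree_leaf_order(tree)
  ord[ord %in% feats]
}

#' Hallagram: block-outlined association heatmap
#'
#' Heatmap of pairwise statistics restricted to the features that
#' participate in reported blocks, ordered by each dataset's dendrogram.
#' Cells passing the global BH threshold are dotted; the top
#' `max_blocks` blocks are outlined in black and labeled with their rank,
#' lower-ranked blocks are boxed in gray without labels.
#'
#' @param result an `halla_result` from [halla()].
#' @param file output image path (`.pdf` or `.png`); `NULL` to skip
#'   writing.
#' @param max_blocks number of rank-labeled blocks (default from the run
#'   configuration).
#' @return Invisibly, a list with the `ggplot` object (`plot`) and a
#'   `spec` describing shown features, outlines and dotted cells.
#' @export
hallagram <- function(result, file = NULL,
                      max_blocks = result$config$max_blocks_shown) {
  blocks <- result$report$blocks
  if (length(blocks) == 0L) {
    p <- ggplot2::ggplot() +
      ggplot2::annotate("text", x = 0, y = 0,
                        label = "No significant blocks") +
      ggplot2::theme_void()
    if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 3)
    return(invisible(list(plot = p,
                          spec = list(x_features = character(),
                                      y_features = character(),
                                      outlines = NULL, n_dots = 0L))))
  }
  xo <- shown_order(result$x_tree, blocks, "x")
  yo <- shown_order(result$y_tree, blocks, "y")
  xpos <- stats::setNames(seq_along(xo), xo)
  ypos <- stats::setNames(seq_along(yo), yo)

  S <- result$results$S
  P <- result$results$P
  R <- reject_matrix(P, result$ctx)
  grid <- expand.grid(xi = xo, yi = yo)
  tiles <- data.frame(
    xpos_ = xpos[as.character(grid$xi)], ypos_ = ypos[as.character(grid$yi)],
    stat = S[cbind(grid$xi, grid$yi)], dot = R[cbind(grid$xi, grid$yi)])

  outlines <- do.call(rbind, lapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    data.frame(rank = b$rank,
               xmin = min(xpos[as.character(b$x_set)]) - 0.5,
               xmax = max(xpos[as.character(b$x_set)]) + 0.5,
               ymin = min(ypos[as.character(b$y_set)]) - 0.5,
               ymax = max(ypos[as.character(b$y_set)]) + 0.5,
               top = k <= max_blocks)
  }))

  p <- ggplot2::ggplot(tiles, ggplot2::aes(x = ypos_, y = xpos_)) +
    ggplot2::geom_tile(ggplot2::aes(fill = stat)) +
    ggplot2::geom_point(data = tiles[tiles$dot, , drop = FALSE],
                        size = 0.8, colour = "white") +
    ggplot2::geom_rect(
      data = outlines, inherit.aes = FALSE,
      ggplot2::aes(xmin = ymin, xmax = ymax, ymin = xmin, ymax = xmax),
      fill = NA, linewidth = ifelse(outlines$top, 0.7, 0.4),
      colour = ifelse(outlines$top, "black", "grey55")) +
    ggplot2::geom_text(
      data = outlines[outlines$top, , drop = FALSE], inherit.aes = FALSE,
      ggplot2::aes(x = (ymin + ymax) / 2, y = (xmin + xmax) / 2,
                   label = rank), size = 3) +
    ggplot2::scale_x_continuous(breaks = seq_along(yo),
                                labels = colnames(P)[yo], expand = c(0, 0)) +
    ggplot2::scale_y_reverse(breaks = seq_along(xo),
                             labels = rownames(P)[xo], expand = c(0, 0)) +
    ggplot2::labs(x = "Y features", y = "X features",
                  fill = result$results$measure) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  p <- if (signed_measure(result$results$measure)) {
    p + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                      high = "#B2182B", limits = c(-1, 1))
  } else {
    p + ggplot2::scale_fill_gradient(low = "white", high = "#B2182B")
  }
  if (length(xo) > 60L || length(yo) > 60L) {
    p <- p + ggplot2::theme(axis.text = ggplot2::element_blank())
  }
  if (!is.null(file)) {
    ggplot2::ggsave(file, p,
                    width = min(2 + 0.14 * length(yo), 12),
                    height = min(2 + 0.14 * length(xo), 12))
  }
  invisible(list(plot = p,
                 spec = list(x_features = rownames(P)[xo],
                             y_features = colnames(P)[yo],
                             outlines = outlines,
                             n_dots = sum(tiles$dot))))
}

#' Clustermap: full association heatmap with marginal dendrograms
#'
#' Shows every feature of both datasets in dendrogram order, the two
#' average-linkage trees in the margins, and the reported blocks outlined.
#'
#' @param result an `halla_result`.
#' @param file output PDF path.
#' @return Invisibly, a list with the row/column leaf orders and block
#'   outline rectangles (in leaf-order coordinates).
#' @export
clustermap <- function(result, file) {
  S <- result$results$S
  xo <- tree_leaf_order(result$x_tree)
  yo <- tree_leaf_order(result$y_tree)
  xpos <- order(xo)  # feature index -> display position
  ypos <- order(yo)
  blocks <- result$report$blocks
  rects <- if (length(blocks)) {
    do.call(rbind, lapply(blocks, function(b) {
      data.frame(xmin = min(xpos[b$x_set]) - 0.5,
                 xmax = max(xpos[b$x_set]) + 0.5,
                 ymin = min(ypos[b$y_set]) - 0.5,
                 ymax = max(ypos[b$y_set]) + 0.5)
    }))
  } else {
    NULL
  }

  pdf(file, width = 9, height = 9)
  on.exit(dev.off())
  op <- par(no.readonly = TRUE)
  on.exit(par(op), add = TRUE, after = FALSE)
  layout(matrix(c(0, 2, 1, 3), 2, 2), widths = c(1, 4), heights = c(1, 4))
  # top: Y dendrogram
  if (!is.null(result$y_tree$hclust)) {
    par(mar = c(0, 0.5, 1, 0.5))
    plot(as.dendrogram(result$y_tree$hclust), leaflab = "none",
         axes = FALSE, xaxs = "i")
  } else {
    par(mar = c(0, 0.5, 1, 0.5))
    plot.new()
  }
  # left: X dendrogram
  if (!is.null(result$x_tree$hclust)) {
    par(mar = c(2, 1, 0.5, 0))
    plot(as.dendrogram(result$x_tree$hclust), horiz = TRUE,
         leaflab = "none", axes = FALSE, yaxs = "i")
  } else {
    par(mar = c(2, 1, 0.5, 0))
    plot.new()
  }
  # main heatmap: columns = Y features, rows = X features
  par(mar = c(2, 0.5, 0.5, 0.5))
  M <- S[xo, yo, drop = FALSE]
  lim <- if (signed_measure(result$results$measure)) c(-1, 1) else
    range(0, M)
  cols <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  image(x = seq_len(ncol(M)), y = seq_len(nrow(M)), z = t(M)[, rev(seq_len(nrow(M))), drop = FALSE],
        zlim = lim, col = cols, axes = FALSE, xlab = "", ylab = "",
        useRaster = FALSE)
  if (!is.null(rects)) {
    nr <- nrow(M)
    rect(rects$ymin, nr + 1 - rects$xmax, rects$ymax, nr + 1 - rects$xmin,
         border = "black", lwd = 1.2)
  }
  invisible(list(x_order = xo, y_order = yo, rects = rects))
}

feature_values_for_plot <- function(t, i) {
  v <- t$values[i, ]
  if (t$kinds[i] == "categorical") {
    factor(t$levels[[feature_ids(t)[i]]][v],
           levels = t$levels[[feature_ids(t)[i]]])
  } else {
    v
  }
}

#' Per-block diagnostic panels
#'
#' One panel per cell of the block: scatterplots for continuous pairs,
#' grouped box plots when one member is categorical, and a mosaic plot
#' when both are.  Panel titles carry the cell's statistic, p and q.
#'
#' @param result an `halla_result`.
#' @param rank rank of the block to plot.
#' @param file output PDF path.
#' @return Invisibly, the number of panels drawn.
#' @export
block_diagnostic <- function(result, rank = 1, file) {
  blocks <- result$report$blocks
  stopifnot(rank >= 1, rank <= length(blocks))
  b <- blocks[[rank]]
  nx <- length(b$x_set)
  ny <- length(b$y_set)
  pdf(file, width = 2.4 * ny + 1, height = 2.4 * nx + 1)
  on.exit(dev.off())
  op <- par(no.readonly = TRUE)
  on.exit(par(op), add = TRUE, after = FALSE)
  par(mfrow = c(nx, ny), mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  for (i in b$x_set) {
    for (j in b$y_set) {
      xv <- feature_values_for_plot(result$x, i)
      yv <- feature_values_for_plot(result$y, j)
      ttl <- sprintf("%s ~ %s\ns=%.2f p=%.2g q=%.2g",
                     feature_ids(result$x)[i], feature_ids(result$y)[j],
                     result$results$S[i, j], result$results$P[i, j],
                     result$results$Q[i, j])
      if (is.factor(xv) && is.factor(yv)) {
        plot(xv, yv, main = ttl, cex.main = 0.7, xlab = "", ylab = "")
      } else if (is.factor(yv)) {
        plot(yv, xv, main = ttl, cex.main = 0.7, xlab = "", ylab = "")
      } else if (is.factor(xv)) {
        plot(xv, yv, main = ttl, cex.main = 0.7, xlab = "", ylab = "")
      } else {
        plot(xv, yv, pch = 19, cex = 0.6, main = ttl, cex.main = 0.7,
             xlab = "", ylab = "")
      }
    }
  }
  invisible(nx * ny)
}

utils::globalVariables(c("xpos_", "ypos_", "stat", "xmin", "xmax",
                         "ymin", "ymax"))
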