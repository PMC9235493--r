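#' Analysis configuration
#'
#' @param measure pairwise association measure: `"spearman"` (default),
#'   `"pearson"`, `"mi"`, `"nmi"`, `"xicor"` or `"dcor"`.
#' @param alpha nominal FDR level for the global BH threshold.
#' @param fnt false-negative tolerance: the allowed fraction of a block's
#'   member pairs that may fail BH rejection.
#' @param n_permutations permutations for permutation-tested measures.
#' @param seed RNG seed governing every stochastic component.
#' @param variance_frequency_threshold mode-frequency cutoff for the
#'   low-variance filter (1 removes only constant features).
#' @param max_blocks_shown number of top blocks outlined in the hallagram.
#' @param bins_override optional fixed bin count for discretization
#'   (default: cube-root rule).
#' @return Named list of class `halla_config`.
#' @export
halla_config <- function(measure = "spearman", alpha = 0.05, fnt = 0.2,
                         n_permutations = 1000, seed = 1,
                         variance_frequency_threshold = 1.0,
                         max_blocks_shown = 30, bins_override = NULL) {
  measure <- match.arg(measure,
                       c("spearman", "pearson", "mi", "nmi", "xicor", "dcor"))
  stopifnot(alpha > 0, alpha < 1, fnt >= 0, fnt <= 1, n_permutations >= 1,
            variance_frequency_threshold > 0,
            variance_frequency_threshold <= 1, max_blocks_shown >= 1)
  structure(list(measure = measure, alpha = alpha, fnt = fnt,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 variance_frequency_threshold = variance_frequency_threshold,
                 max_blocks_shown = as.integer(max_blocks_shown),
                 bins_override = bins_override),
            class = "halla_config")
}

#' Hierarchical block-association analysis of two aligned tables
#'
#' The in-memory engine: variance filter, full pairwise testing, global BH
#' threshold, per-dataset average-linkage trees, Gini-guided descent, and
#' block ranking.
#'
#' @param x,y [feature_table] objects sharing the same samples (they are
#'   aligned with [align_tables()] first).
#' @param config an [halla_config()].
#' @return Object of class `halla_result`: the filtered tables, the
#'   `pairwise_results`, the `fdr_context`, both `cluster_tree`s, the
#'   ranked `block_report` and the configuration.
#' @export
halla <- function(x, y, config = halla_config()) {
  al <- align_tables(x, y)
  x <- filter_low_variance(al$x, config$variance_frequency_threshold)
  y <- filter_low_variance(al$y, config$variance_frequency_threshold)
  res <- pairwise_matrix(x, y, config)
  ctx <- bh_threshold(as.vector(res$P), config$alpha)
  tree_measure <- config$measure
  xt <- build_tree(association_distance(x, tree_measure,
                                        n_bins = config$bins_override))
  yt <- build_tree(association_distance(y, tree_measure,
                                        n_bins = config$bins_override))
  report <- rank_blocks(descend(xt, yt, res$P, ctx, config$fnt),
                        res$P, res$Q)
  structure(list(x = x, y = y, results = res, ctx = ctx,
                 x_tree = xt, y_tree = yt, report = report,
                 config = config),
            class = "halla_result")
}

#' @export
print.halla_result <- function(x, ...) {
  cat("halla_result (", x$config$measure, ", alpha ", x$config$alpha,
      ", FNT ", x$config$fnt, ")\n", sep = "")
  print(x$ctx)
  print(x$report)
  invisible(x)
}

#' Pairwise association table
#'
#' @param result an `halla_result`.
#' @return `data.frame` with one row per X x Y feature pair: `X_feature`,
#'   `Y_feature`, `statistic`, `p_value`, `q_value`.
#' @export
association_table <- function(result) {
  res <- result$results
  grid <- expand.grid(x = seq_len(nrow(res$P)), y = seq_len(ncol(res$P)))
  grid <- grid[order(grid$x, grid$y), ]
  data.frame(X_feature = rownames(res$P)[grid$x],
             Y_feature = colnames(res$P)[grid$y],
             statistic = res$S[cbind(grid$x, grid$y)],
             p_value = res$P[cbind(grid$x, grid$y)],
             q_value = res$Q[cbind(grid$x, grid$y)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' End-to-end file-based run
#'
#' Reads two TSV feature tables, runs [halla()], and writes
#' `all_associations.tsv`, `sig_clusters.tsv`, `hallagram.pdf` (and
#' `.png` where a PNG device is available), `x_tree.nwk`/`y_tree.nwk`,
#' and `run_log.txt` with every resolved parameter, the derived bin
#' count and the global BH threshold.
#'
#' @param x_path,y_path paths to TSV feature tables.
#' @param out_dir output directory (created if missing).
#' @param config an [halla_config()].
#' @param plots set `FALSE` to skip image output.
#' @return The `halla_result`, invisibly.
#' @export
halla_run <- function(x_path, y_path, out_dir, config = halla_config(),
                      plots = TRUE) {
  x <- read_feature_table(x_path)
  y <- read_feature_table(y_path)
  result <- halla(x, y, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  write.table(association_table(result),
              file.path(out_dir, "all_associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(result$report),
              file.path(out_dir, "sig_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("ape", quietly = TRUE)) {
    tree_newick(result$x_tree, file.path(out_dir, "x_tree.nwk"))
    tree_newick(result$y_tree, file.path(out_dir, "y_tree.nwk"))
  }
  cfg <- result$config
  log_lines <- c(
    paste0("x_path: ", x_path),
    paste0("y_path: ", y_path),
    paste0("measure: ", cfg$measure),
    paste0("alpha: ", cfg$alpha),
    paste0("fnt: ", cfg$fnt),
    paste0("n_permutations: ", cfg$n_permutations),
    paste0("seed: ", cfg$seed),
    paste0("variance_frequency_threshold: ",
           cfg$variance_frequency_threshold),
    paste0("max_blocks_shown: ", cfg$max_blocks_shown),
    paste0("bins: ", if (is.null(cfg$bins_override))
      default_bin_count(n_samples(result$x)) else cfg$bins_override),
    paste0("n_tests: ", result$ctx$m),
    paste0("k_bh: ", format(result$ctx$k_bh, digits = 15)),
    paste0("n_rejections: ", result$ctx$n_reject),
    paste0("n_blocks: ", length(result$report$blocks)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  if (plots) {
    hallagram(result, file.path(out_dir, "hallagram.pdf"))
    ok <- tryCatch({
      hallagram(result, file.path(out_dir, "hallagram.png"))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) message("PNG device unavailable; wrote hallagram.pdf only")
  }
  invisible(result)
}
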