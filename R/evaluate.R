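#' Expand a block report to feature pairs
#'
#' Union of the cells of all reported blocks; blocks are disjoint
#' rectangles, so this is a plain union.
#'
#' @param report a `block_report`.
#' @return Two-column integer matrix of (x index, y index) pairs.
#' @export
expand_to_pairs <- function(report) {
  if (length(report$blocks) == 0L) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  do.call(rbind, lapply(report$blocks, function(b) {
    as.matrix(expand.grid(x = b$x_set, y = b$y_set))
  }))
}

pair_keys <- function(pairs, n_x) {
  if (nrow(pairs) == 0L) return(integer())
  (pairs[, 2L] - 1L) * n_x + pairs[, 1L]
}

#' Score reported pairs against the planted truth
#'
#' Pairwise-level power and false discovery rate.  An empty report scores
#' power 0 and FDR 0 (0/0 := 0).
#'
#' @param pairs two-column matrix of reported (x, y) index pairs (e.g.
#'   from [expand_to_pairs()] or [alla_baseline()]).
#' @param truth a `synthetic_truth`.
#' @return List with `power`, `fdr`, `n_true_pairs`, `n_reported_pairs`,
#'   `n_true_positives`.
#' @export
score_pairs <- function(pairs, truth) {
  tp_keys <- pair_keys(truth_pairs(truth), truth$n_x)
  rp_keys <- pair_keys(pairs, truth$n_x)
  tp <- sum(rp_keys %in% tp_keys)
  n_true <- length(tp_keys)
  n_rep <- length(rp_keys)
  list(power = if (n_true == 0L) 0 else tp / n_true,
       fdr = (n_rep - tp) / max(n_rep, 1L),
       n_true_pairs = n_true, n_reported_pairs = n_rep,
       n_true_positives = tp)
}

#' All-against-all BH baseline
#'
#' The naive competitor: every pair whose p-value passes the global BH
#' threshold at `alpha`.
#'
#' @param P p-value matrix.
#' @param alpha nominal FDR level.
#' @return Two-column integer matrix of rejected (x, y) pairs.
#' @export
alla_baseline <- function(P, alpha = 0.05) {
  ctx <- bh_threshold(as.vector(P), alpha)
  R <- reject_matrix(P, ctx)
  idx <- which(R, arr.ind = TRUE)
  dimnames(idx) <- list(NULL, c("x", "y"))
  idx
}

#' Run the hierarchical-vs-AllA simulation benchmark
#'
#' For each replicate and each (assoc_type, measure) combination, one
#' paired dataset is generated and its pairwise p-value matrix and cluster
#' trees are computed once; each (alpha, fnt) condition then reuses them
#' for both the hierarchical descent and the AllA baseline.
#'
#' @param grid condition grid from [benchmark_config()] (columns
#'   `assoc_type`, `measure`, `alpha`, `fnt`).
#' @param n_reps replicates per condition.
#' @param n_x,n_y,n_samples dataset shape.
#' @param n_blocks,size_range,strength,coherence,noise_sd generator knobs
#'   (see [random_block_specs()] and [generate_paired()]).
#' @param n_permutations permutations for permutation-tested measures.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return `data.frame` with one row per (replicate, condition, method):
#'   `replicate`, `assoc_type`, `measure`, `alpha`, `fnt`, `method`
#'   (`"hierarchical"`/`"alla"`), `power`, `fdr`, `n_reported`, `n_true`.
#' @export
run_benchmark <- function(grid = benchmark_config("fig2"), n_reps = 50,
                          n_x = 200, n_y = 200, n_samples = 50,
                          n_blocks = 5, size_range = 4:9, strength = 0.85,
                          coherence = 0.6, noise_sd = 0,
                          n_permutations = 200, seed = 1) {
  combos <- unique(grid[, c("assoc_type", "measure")])
  rows <- vector("list", 0L)
  for (rep_i in seq_len(n_reps)) {
    for (ci in seq_len(nrow(combos))) {
      atype <- combos$assoc_type[ci]
      meas <- combos$measure[ci]
      gseed <- derive_seed(seed, rep_i, ci)
      blocks <- random_block_specs(n_blocks, size_range, atype, strength,
                                   coherence, seed = gseed)
      gen <- generate_paired(n_x, n_y, n_samples, blocks,
                             noise_sd = noise_sd, seed = gseed)
      cfg <- halla_config(measure = meas, n_permutations = n_permutations,
                          seed = gseed)
      res <- pairwise_matrix(gen$x, gen$y, cfg)
      xt <- build_tree(association_distance(gen$x, meas))
      yt <- build_tree(association_distance(gen$y, meas))
      sub <- grid[grid$assoc_type == atype & grid$measure == meas, ]
      for (gi in seq_len(nrow(sub))) {
        alpha <- sub$alpha[gi]
        fnt <- sub$fnt[gi]
        ctx <- bh_threshold(as.vector(res$P), alpha)
        rep_blocks <- descend(xt, yt, res$P, ctx, fnt)
        hb <- score_pairs(expand_to_pairs(rep_blocks), gen$truth)
        ab <- score_pairs(alla_baseline(res$P, alpha), gen$truth)
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, assoc_type = atype, measure = meas,
          alpha = alpha, fnt = fnt,
          method = c("hierarchical", "alla"),
          power = c(hb$power, ab$power),
          fdr = c(hb$fdr, ab$fdr),
          n_reported = c(hb$n_reported_pairs, ab$n_reported_pairs),
          n_true = hb$n_true_pairs,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark results
#'
#' @param results output of [run_benchmark()].
#' @return `data.frame` of per-condition, per-method means of power and
#'   FDR with Monte-Carlo standard errors.
#' @export
summarize_benchmark <- function(results) {
  f <- interaction(results$assoc_type, results$measure, results$alpha,
                   results$fnt, results$method, drop = TRUE)
  parts <- split(results, f)
  do.call(rbind, lapply(parts, function(d) {
    n <- nrow(d)
    data.frame(assoc_type = d$assoc_type[1L], measure = d$measure[1L],
               alpha = d$alpha[1L], fnt = d$fnt[1L], method = d$method[1L],
               n_reps = n,
               power = mean(d$power), power_se = sd(d$power) / sqrt(n),
               fdr = mean(d$fdr), fdr_se = sd(d$fdr) / sqrt(n),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
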