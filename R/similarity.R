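#' Pairwise association measures
#'
#' Each `*_assoc` function tests the association between one pair of
#' feature vectors on their complete cases and returns a list with
#' `statistic`, `p_value` and `n_used`.  Vectors shorter than 5 complete
#' pairs (or degenerate, e.g. constant) yield `statistic = 0`, `p = 1` with
#' a warning rather than an error, so a single bad pair cannot abort a run.
#'
#' @param x,y numeric vectors of equal length.
#' @name assoc
NULL

assoc_result <- function(statistic, p_value, n_used) {
  list(statistic = unname(statistic), p_value = unname(min(max(p_value, 0), 1)),
       n_used = as.integer(n_used))
}

degenerate_result <- function(n_used, why) {
  warning("association undefined (", why, "); returning statistic 0, p 1")
  assoc_result(0, 1, n_used)
}

complete_pairs <- function(x, y) {
  ok <- !(is.na(x) | is.na(y))
  list(x = x[ok], y = y[ok], n = sum(ok))
}

# Correlation t-test p-value shared by the Spearman and Pearson tests.
cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' @rdname assoc
#' @export
spearman_assoc <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  if (sd(cp$x) == 0 || sd(cp$y) == 0) {
    return(degenerate_result(cp$n, "constant vector"))
  }
  r <- cor(rank(cp$x), rank(cp$y))
  assoc_result(r, cor_t_pvalue(r, cp$n), cp$n)
}

#' @rdname assoc
#' @export
pearson_assoc <- function(x, y) {
  cp <- complete_pairs(x, y)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  if (sd(cp$x) == 0 || sd(cp$y) == 0) {
    return(degenerate_result(cp$n, "constant vector"))
  }
  r <- cor(cp$x, cp$y)
  assoc_result(r, cor_t_pvalue(r, cp$n), cp$n)
}

# Plug-in mutual information (nats) of two label vectors.
mutual_information <- function(xd, yd) {
  tab <- table(xd, yd)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
}

entropy_nats <- function(d) {
  p <- table(d) / length(d)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' @rdname assoc
#' @param xd,yd integer bin-label vectors (already discretized).
#' @param n_perm number of permutations for the p-value.
#' @param seed RNG seed for the permutation stream.
#' @export
mi_assoc <- function(xd, yd, n_perm = 1000, seed = 1) {
  cp <- complete_pairs(xd, yd)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  if (length(unique(cp$x)) < 2L || length(unique(cp$y)) < 2L) {
    return(assoc_result(0, 1, cp$n))
  }
  mi <- mutual_information(cp$x, cp$y)
  p <- permutation_pvalue(mutual_information, cp$x, cp$y, n_perm, seed)
  assoc_result(mi, p, cp$n)
}

#' @rdname assoc
#' @export
nmi_assoc <- function(xd, yd, n_perm = 1000, seed = 1) {
  cp <- complete_pairs(xd, yd)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  hx <- entropy_nats(cp$x)
  hy <- entropy_nats(cp$y)
  if (hx == 0 || hy == 0) return(assoc_result(0, 1, cp$n))
  nmi_stat <- function(a, b) mutual_information(a, b) / sqrt(hx * hy)
  stat <- nmi_stat(cp$x, cp$y)
  p <- permutation_pvalue(nmi_stat, cp$x, cp$y, n_perm, seed)
  assoc_result(stat, p, cp$n)
}

# Chatterjee's xi with the general tie-aware formula; measures how well y
# is a function of x (asymmetric).  Ties in x are broken at random.
xi_statistic <- function(x, y, seed = 1) {
  n <- length(x)
  ord <- if (anyDuplicated(x)) {
    with_seed(seed, order(x, runif(n)))
  } else {
    order(x)
  }
  ys <- y[ord]
  r <- vapply(ys, function(v) sum(ys <= v), numeric(1L))
  l <- vapply(ys, function(v) sum(ys >= v), numeric(1L))
  denom <- 2 * sum(l * (n - l))
  if (denom == 0) return(NA_real_)
  1 - n * sum(abs(diff(r))) / denom
}

#' @rdname assoc
#' @export
xicor_assoc <- function(x, y, seed = 1) {
  cp <- complete_pairs(x, y)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  xi <- xi_statistic(cp$x, cp$y, seed = seed)
  if (is.na(xi)) return(degenerate_result(cp$n, "constant y"))
  # one-sided asymptotic null: sqrt(n) * xi ~ N(0, 2/5)
  p <- pnorm(sqrt(cp$n) * xi / sqrt(2 / 5), lower.tail = FALSE)
  assoc_result(xi, p, cp$n)
}

# Sample distance correlation via double-centered distance matrices.
dcor_statistic <- function(x, y) {
  dc <- function(v) {
    a <- as.matrix(dist(v))
    a - outer(rowMeans(a), colMeans(a), "+") + mean(a)
  }
  A <- dc(x)
  B <- dc(y)
  dcov2 <- max(mean(A * B), 0)
  dvx <- mean(A * A)
  dvy <- mean(B * B)
  if (dvx == 0 || dvy == 0) return(NA_real_)
  sqrt(dcov2 / sqrt(dvx * dvy))
}

#' @rdname assoc
#' @export
dcor_assoc <- function(x, y, n_perm = 1000, seed = 1) {
  cp <- complete_pairs(x, y)
  if (cp$n < 5L) return(degenerate_result(cp$n, "fewer than 5 complete pairs"))
  stat <- dcor_statistic(cp$x, cp$y)
  if (is.na(stat)) return(degenerate_result(cp$n, "constant vector"))
  p <- permutation_pvalue(dcor_statistic, cp$x, cp$y, n_perm, seed)
  assoc_result(stat, p, cp$n)
}

#' Permutation p-value
#'
#' Add-one permutation estimator on the absolute statistic:
#' `p = (1 + #\{|stat(x, perm(y))| >= |stat(x, y)|\}) / (1 + n_perm)`.
#' Only `y` is permuted; the stream is deterministic under `seed`.
#'
#' @param stat_fn function of `(x, y)` returning a scalar statistic.
#' @param x,y data vectors.
#' @param n_perm positive number of permutations.
#' @param seed RNG seed.
#' @return p-value in `[1/(n_perm+1), 1]`.
#' @export
permutation_pvalue <- function(stat_fn, x, y, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  obs <- abs(stat_fn(x, y))
  n <- length(y)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(b) {
      abs(stat_fn(x, y[sample.int(n)])) >= obs - 1e-12
    }, logical(1L)))
  })
  (1 + hits) / (1 + n_perm)
}

# ---- full pairwise matrix -------------------------------------------------

measure_needs_continuous <- function(measure) {
  measure %in% c("spearman", "pearson", "xicor", "dcor")
}

# Vectorized Spearman/Pearson over complete data: one rank transform per
# row, then a single cross-correlation matrix product.
fast_cor_matrices <- function(X, Y, method) {
  if (method == "spearman") {
    X <- t(apply(X, 1L, rank))
    Y <- t(apply(Y, 1L, rank))
  }
  n <- ncol(X)
  S <- suppressWarnings(cor(t(X), t(Y)))
  bad <- !is.finite(S)
  S[bad] <- 0
  T2 <- S * sqrt((n - 2) / pmax(1 - S^2, .Machine$double.eps))
  P <- 2 * pt(abs(T2), df = n - 2, lower.tail = FALSE)
  P[S^2 >= 1] <- 0
  P[bad] <- 1
  if (any(bad)) warning(sum(bad), " constant-feature pair(s) set to p = 1")
  list(S = S, P = P)
}

#' Full pairwise association matrix
#'
#' Tests every X-feature x Y-feature pair with the configured measure and
#' fills q-values by Benjamini-Hochberg over all `n_x * n_y` p-values.
#'
#' @param x,y aligned [feature_table] objects (identical sample order).
#' @param config an [halla_config()] list.
#' @return Object of class `pairwise_results` with matrices `S`
#'   (statistics), `P` (p-values), `Q` (BH q-values), `N` (complete-case
#'   counts) and the measure name.
#' @export
pairwise_matrix <- function(x, y, config = halla_config()) {
  stopifnot(identical(sample_ids(x), sample_ids(y)))
  measure <- match.arg(config$measure,
                       c("spearman", "pearson", "mi", "nmi", "xicor", "dcor"))
  nx <- n_features(x)
  ny <- n_features(y)
  n <- n_samples(x)
  if (measure_needs_continuous(measure) &&
      (any(x$kinds == "categorical") || any(y$kinds == "categorical"))) {
    stop("measure '", measure, "' requires continuous features; ",
         "use measure 'mi' or 'nmi' for categorical data")
  }

  S <- matrix(0, nx, ny, dimnames = list(feature_ids(x), feature_ids(y)))
  P <- matrix(1, nx, ny, dimnames = dimnames(S))
  N <- matrix(n, nx, ny, dimnames = dimnames(S))

  if (measure %in% c("spearman", "pearson") &&
      !anyNA(x$values) && !anyNA(y$values)) {
    sp <- fast_cor_matrices(x$values, y$values, measure)
    S <- sp$S
    P <- sp$P
    dimnames(S) <- dimnames(P) <- list(feature_ids(x), feature_ids(y))
  } else if (measure %in% c("mi", "nmi")) {
    nb <- if (is.null(config$bins_override)) default_bin_count(n) else
      config$bins_override
    xd <- discretize_table(x, nb)$labels
    yd <- discretize_table(y, nb)$labels
    fn <- if (measure == "mi") mi_assoc else nmi_assoc
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) {
        r <- fn(xd[i, ], yd[j, ], n_perm = config$n_permutations,
                seed = derive_seed(config$seed, i, j))
        S[i, j] <- r$statistic
        P[i, j] <- r$p_value
        N[i, j] <- r$n_used
      }
    }
  } else {
    for (i in seq_len(nx)) {
      for (j in seq_len(ny)) {
        r <- switch(measure,
          spearman = spearman_assoc(x$values[i, ], y$values[j, ]),
          pearson  = pearson_assoc(x$values[i, ], y$values[j, ]),
          xicor    = xicor_assoc(x$values[i, ], y$values[j, ],
                                 seed = derive_seed(config$seed, i, j)),
          dcor     = dcor_assoc(x$values[i, ], y$values[j, ],
                                n_perm = config$n_permutations,
                                seed = derive_seed(config$seed, i, j)))
        S[i, j] <- r$statistic
        P[i, j] <- r$p_value
        N[i, j] <- r$n_used
      }
    }
  }
  Q <- matrix(bh_qvalues(as.vector(P)), nx, ny, dimnames = dimnames(P))
  structure(list(S = S, P = P, Q = Q, N = N, measure = measure),
            class = "pairwise_results")
}

#' @export
print.pairwise_results <- function(x, ...) {
  cat("pairwise_results (", x$measure, "): ", nrow(x$P), " x ", ncol(x$P),
      " feature pairs; min p = ", format(min(x$P), digits = 3), "\n", sep = "")
  invisible(x)
}
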