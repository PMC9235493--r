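#' Remove low-variance features
#'
#' A feature is dropped when the relative frequency of its most common
#' non-missing value reaches `freq_threshold`.  At the default threshold of
#' 1 only features with no variability at all (constants) are removed.
#'
#' @param t a [feature_table]
#' @param freq_threshold real in (0, 1]; mode-frequency cutoff.
#' @return The filtered [feature_table].
#' @export
filter_low_variance <- function(t, freq_threshold = 1.0) {
  stopifnot(freq_threshold > 0, freq_threshold <= 1)
  keep <- vapply(seq_len(n_features(t)), function(i) {
    v <- t$values[i, ]
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(FALSE)
    max(tabulate(match(v, unique(v)))) / length(v) < freq_threshold
  }, logical(1L))
  if (!all(keep)) {
    message("removed ", sum(!keep), " low-variance feature(s): ",
            paste(feature_ids(t)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("all features removed by the variance filter")
  t$values <- t$values[keep, , drop = FALSE]
  t$kinds <- t$kinds[keep]
  t
}

#' Default bin count for discretization
#'
#' The cube-root-of-n rule: `max(2, round-half-up(n^(1/3)))`.
#'
#' @param n_samples sample count, at least 2.
#' @return A positive integer number of bins.
#' @export
default_bin_count <- function(n_samples) {
  stopifnot(length(n_samples) == 1L, n_samples >= 2)
  max(2L, as.integer(floor(n_samples^(1 / 3) + 0.5 + 1e-9)))
}

#' Equal-frequency discretization of one feature
#'
#' Splits the non-missing values into `n_bins` contiguous rank groups of
#' as-equal-as-possible size.  Identical values always share a bin, so ties
#' never straddle a boundary (this may merge bins); bin indices are ordered
#' by value and missing entries stay missing.  The assignment depends on
#' ranks only, hence is invariant to strictly monotone transforms.
#'
#' @param values numeric vector (may contain `NA`)
#' @param n_bins target number of bins.
#' @return Integer vector of 1-based bin indices (with `NA` preserved).
#' @export
discretize_feature <- function(values, n_bins) {
  stopifnot(n_bins >= 1)
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  v <- values[ok]
  if (length(v) == 0L) return(out)
  r <- rank(v, ties.method = "average")
  raw <- as.integer(ceiling(r * n_bins / length(v)))
  raw[raw < 1L] <- 1L
  # relabel to consecutive indices in value order (tie merging can skip bins)
  out[ok] <- match(raw, sort(unique(raw)))
  out
}

#' Discretize a whole table
#'
#' Continuous features are binned by [discretize_feature()] with
#' `n_bins` (default: [default_bin_count()] of the sample count);
#' categorical features pass through as their level codes.
#'
#' @param t a [feature_table]
#' @param n_bins optional bin-count override.
#' @return A list with `labels` (integer matrix, features x samples) and
#'   `n_bins` (per-feature bin count actually available).
#' @export
discretize_table <- function(t, n_bins = NULL) {
  if (is.null(n_bins)) n_bins <- default_bin_count(n_samples(t))
  labels <- matrix(NA_integer_, n_features(t), n_samples(t),
                   dimnames = dimnames(t$values))
  nb <- integer(n_features(t))
  for (i in seq_len(n_features(t))) {
    if (t$kinds[i] == "categorical") {
      labels[i, ] <- as.integer(t$values[i, ])
    } else {
      labels[i, ] <- discretize_feature(t$values[i, ], n_bins)
    }
    nb[i] <- length(unique(labels[i, !is.na(labels[i, ])]))
  }
  list(labels = labels, n_bins = nb)
}
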