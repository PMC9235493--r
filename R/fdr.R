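#' Global Benjamini-Hochberg threshold
#'
#' Sorts the m p-values and finds the largest `p_(i)` with
#' `p_(i) <= i * alpha / m`.  A pair "rejects" iff its p-value is at most
#' this threshold.  When no p-value qualifies the threshold is 0 and the
#' rejection set is empty (`n_reject = 0`).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param alpha nominal FDR level.
#' @return An object of class `fdr_context`: list with `k_bh`, `alpha`,
#'   `m` and `n_reject`.
#' @export
bh_threshold <- function(pvalues, alpha = 0.05) {
  p <- as.numeric(pvalues)
  if (length(p) < 1L) stop("need at least one p-value")
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  s <- sort(p)
  ok <- s <= seq_len(m) * alpha / m
  if (any(ok)) {
    k <- s[max(which(ok))]
    nr <- sum(p <= k)
  } else {
    k <- 0
    nr <- 0L
  }
  structure(list(k_bh = k, alpha = alpha, m = m, n_reject = as.integer(nr)),
            class = "fdr_context")
}

#' @export
print.fdr_context <- function(x, ...) {
  cat("fdr_context: alpha ", x$alpha, ", m = ", x$m, ", k_bh = ",
      format(x$k_bh, digits = 4), " (", x$n_reject, " rejections)\n",
      sep = "")
  invisible(x)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up q-values `q_(i) = min_{j >= i} m * p_(j) / j`, clipped
#' to 1 and returned in the input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

# Logical rejection matrix for a p-value matrix under a context.
reject_matrix <- function(P, ctx) {
  if (ctx$n_reject == 0L) {
    matrix(FALSE, nrow(P), ncol(P), dimnames = dimnames(P))
  } else {
    P <= ctx$k_bh
  }
}
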