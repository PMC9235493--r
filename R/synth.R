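#' Planted association block specification
#'
#' @param x_size,y_size number of features the block occupies in each
#'   dataset.
#' @param assoc_type functional form linking the block's Y features to its
#'   latent variable: one of `"linear"`, `"quadratic"`, `"logarithmic"`,
#'   `"sinusoidal"`, `"stepwise"`, `"parabolic"`, `"mixed"` (continuous X,
#'   categorical Y) or `"categorical"` (both categorical).
#' @param strength fraction of the Y-side latent's variance carried by the
#'   transformed X-side latent, in (0, 1]: the cross-dataset signal.
#' @param coherence within-block correlation of member features with their
#'   block latent's scale, in (0, 1]; member correlation is `coherence`
#'   itself.  Tight clusters (the multiomics norm, e.g. coexpressed genes)
#'   have high coherence.
#' @return Object of class `block_spec`.
#' @export
block_spec <- function(x_size, y_size, assoc_type = "linear",
                       strength = 0.85, coherence = 0.6) {
  assoc_type <- match.arg(assoc_type,
                          c("linear", "quadratic", "logarithmic",
                            "sinusoidal", "stepwise", "parabolic",
                            "mixed", "categorical"))
  stopifnot(x_size >= 1, y_size >= 1, strength > 0, strength <= 1,
            coherence > 0, coherence <= 1)
  structure(list(x_size = as.integer(x_size), y_size = as.integer(y_size),
                 assoc_type = assoc_type, strength = strength,
                 coherence = coherence),
            class = "block_spec")
}

#' Random block specifications
#'
#' Draws `n_blocks` block sizes uniformly from `size_range` for each side.
#'
#' @param n_blocks number of blocks.
#' @param size_range integer vector of admissible per-side sizes.
#' @param assoc_type,strength,coherence passed to [block_spec()].
#' @param seed RNG seed.
#' @return List of `block_spec`s.
#' @export
random_block_specs <- function(n_blocks = 5, size_range = 4:9,
                               assoc_type = "linear", strength = 0.85,
                               coherence = 0.6, seed = 1) {
  with_seed(seed, {
    lapply(seq_len(n_blocks), function(b) {
      block_spec(sample(size_range, 1L), sample(size_range, 1L),
                 assoc_type = assoc_type, strength = strength,
                 coherence = coherence)
    })
  })
}

# Link functions mapping a latent z to the Y-side signal.  All continuous
# forms are standardized downstream; the monotone forms (linear,
# logarithmic, stepwise) are detectable by rank correlation, the
# non-monotone ones (quadratic, sinusoidal, parabolic) are not.
link_function <- function(type) {
  switch(type,
    linear      = function(z) z,
    quadratic   = function(z) z^2,
    logarithmic = function(z) log(z - min(z) + 0.5),
    sinusoidal  = function(z) sin(2 * pi * z),
    stepwise    = function(z) findInterval(z, quantile(z, c(1, 2) / 3)),
    parabolic   = function(z) (z - quantile(z, 0.25))^2,
    stop("no continuous link for type '", type, "'")
  )
}

standardize <- function(v) {
  s <- sd(v)
  if (s == 0) return(v * 0)
  (v - mean(v)) / s
}

# Tertile labels ("a" < "b" < "c") of a continuous vector.
tertile_labels <- function(v) {
  c("a", "b", "c")[findInterval(v, quantile(v, c(1, 2) / 3)) + 1L]
}

#' Generate paired datasets with planted association blocks
#'
#' Each block gets a latent standard-normal variable `z` over the samples.
#' The block's Y-side latent is
#' `w = sqrt(strength) * std(f(z)) + sqrt(1 - strength) * noise` with `f`
#' the block's link function, so `strength` sets the cross-dataset signal.
#' Member features are noisy copies of their side's latent:
#' `sqrt(coherence) * latent + sqrt(1 - coherence) * noise`, so
#' `coherence` sets how tightly the block clusters within its dataset.
#' `mixed` blocks emit the Y side as categorical tertile labels of the
#' noisy member values; `categorical` blocks do so on both sides.  All
#' remaining features are independent standard normals.  Optional extra
#' measurement noise (`noise_sd`) is added to every continuous feature.
#'
#' @param n_x,n_y total features per dataset.
#' @param n_samples number of shared samples.
#' @param blocks list of [block_spec()]s; sizes must fit in `n_x`/`n_y`.
#' @param noise_sd additional independent Gaussian noise s.d. (default 0;
#'   the `strength` mixing already injects `1 - strength` noise variance).
#' @param seed RNG seed; output is bit-reproducible given the seed.
#' @return List with feature tables `x` and `y` and `truth`, a
#'   `synthetic_truth` object listing the planted rectangles.
#' @export
generate_paired <- function(n_x = 200, n_y = 200, n_samples = 50,
                            blocks = random_block_specs(seed = seed),
                            noise_sd = 0, seed = 1) {
  sx <- vapply(blocks, function(b) b$x_size, integer(1L))
  sy <- vapply(blocks, function(b) b$y_size, integer(1L))
  if (sum(sx) > n_x || sum(sy) > n_y) {
    stop("block sizes exceed the requested feature counts")
  }
  with_seed(derive_seed(seed, 7L), {
    X <- matrix(rnorm(n_x * n_samples), n_x, n_samples)
    Y <- matrix(rnorm(n_y * n_samples), n_y, n_samples)
    x_kinds <- rep("continuous", n_x)
    y_kinds <- rep("continuous", n_y)
    x_labels <- matrix(NA_character_, n_x, n_samples)
    y_labels <- matrix(NA_character_, n_y, n_samples)

    xi <- 0L
    yi <- 0L
    rects <- list()
    for (b in blocks) {
      z <- rnorm(n_samples)
      xs <- xi + seq_len(b$x_size)
      ys <- yi + seq_len(b$y_size)
      fy <- if (b$assoc_type %in% c("mixed", "categorical")) z else
        standardize(link_function(b$assoc_type)(z))
      w <- sqrt(b$strength) * fy + sqrt(1 - b$strength) * rnorm(n_samples)
      a <- sqrt(b$coherence)
      e <- sqrt(1 - b$coherence)
      mix_x <- vapply(xs, function(i) a * z + e * rnorm(n_samples),
                      numeric(n_samples))
      mix_y <- vapply(ys, function(j) a * w + e * rnorm(n_samples),
                      numeric(n_samples))
      if (b$assoc_type == "categorical") {
        for (k in seq_along(xs)) x_labels[xs[k], ] <- tertile_labels(mix_x[, k])
        x_kinds[xs] <- "categorical"
      } else {
        X[xs, ] <- t(mix_x)
      }
      if (b$assoc_type %in% c("mixed", "categorical")) {
        for (k in seq_along(ys)) y_labels[ys[k], ] <- tertile_labels(mix_y[, k])
        y_kinds[ys] <- "categorical"
      } else {
        Y[ys, ] <- t(mix_y)
      }
      rects[[length(rects) + 1L]] <- list(x_set = xs, y_set = ys,
                                          assoc_type = b$assoc_type)
      xi <- xi + b$x_size
      yi <- yi + b$y_size
    }
    if (noise_sd > 0) {
      X[x_kinds == "continuous", ] <- X[x_kinds == "continuous", ] +
        noise_sd * rnorm(sum(x_kinds == "continuous") * n_samples)
      Y[y_kinds == "continuous", ] <- Y[y_kinds == "continuous", ] +
        noise_sd * rnorm(sum(y_kinds == "continuous") * n_samples)
    }

    samp <- paste0("S", seq_len(n_samples))
    pack <- function(M, kinds, labels, prefix) {
      ids <- paste0(prefix, seq_len(nrow(M)))
      vals <- M
      levs <- list()
      for (i in which(kinds == "categorical")) {
        f <- factor(labels[i, ], levels = c("a", "b", "c"))
        vals[i, ] <- as.numeric(f)
        levs[[ids[i]]] <- base::levels(f)
      }
      dimnames(vals) <- list(ids, samp)
      feature_table(vals, kinds = kinds, levels = levs)
    }
    truth <- structure(list(rects = rects, n_x = n_x, n_y = n_y),
                       class = "synthetic_truth")
    list(x = pack(X, x_kinds, x_labels, "X"),
         y = pack(Y, y_kinds, y_labels, "Y"),
         truth = truth)
  })
}

#' True pair set of a synthetic truth
#'
#' @param truth a `synthetic_truth`
#' @return Two-column integer matrix of (x index, y index) true pairs.
#' @export
truth_pairs <- function(truth) {
  if (length(truth$rects) == 0L) {
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("x", "y"))))
  }
  do.call(rbind, lapply(truth$rects, function(r) {
    as.matrix(expand.grid(x = r$x_set, y = r$y_set))
  }))
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth: ", length(x$rects), " block(s), ",
      nrow(truth_pairs(x)), " true pairs in a ", x$n_x, " x ", x$n_y,
      " pair grid\n", sep = "")
  invisible(x)
}

#' Benchmark condition grids
#'
#' `"fig2"`: linear blocks, Spearman, the four target FDR levels crossed
#' with FNT 0.2, plus an FNT sweep at the 0.05 level.  `"fig3"`: the
#' association-type panel crossed with the permutation-free measures
#' (Spearman, Pearson, MI via its permutation test, XICOR); measures that
#' require continuous data are excluded for the mixed and categorical
#' types.
#'
#' @param variant `"fig2"` or `"fig3"`.
#' @return `data.frame` with columns `assoc_type`, `measure`, `alpha`,
#'   `fnt`.
#' @export
benchmark_config <- function(variant = c("fig2", "fig3")) {
  variant <- match.arg(variant)
  if (variant == "fig2") {
    g1 <- expand.grid(assoc_type = "linear", measure = "spearman",
                      alpha = c(0.05, 0.1, 0.25, 0.5), fnt = 0.2,
                      stringsAsFactors = FALSE)
    g2 <- expand.grid(assoc_type = "linear", measure = "spearman",
                      alpha = 0.05, fnt = c(0, 0.05, 0.1, 0.3, 0.5),
                      stringsAsFactors = FALSE)
    rbind(g1, g2)
  } else {
    g <- expand.grid(
      assoc_type = c("linear", "quadratic", "logarithmic", "sinusoidal",
                     "stepwise", "parabolic", "mixed", "categorical"),
      measure = c("spearman", "pearson", "mi", "xicor"),
      alpha = 0.05, fnt = 0.2, stringsAsFactors = FALSE)
    drop <- g$assoc_type %in% c("mixed", "categorical") & g$measure != "mi"
    g[!drop, , drop = FALSE]
  }
}
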