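#' Within-dataset association distance
#'
#' Converts the configured similarity measure into a feature-by-feature
#' dissimilarity: `1 - |s|` for the signed correlation measures (so
#' anticorrelated features cluster together) and `1 - s` for measures
#' already in `[0, 1]` (NMI, dCor, and xi symmetrized by the larger of the
#' two directions and clipped to `[0, 1]`).  Undefined similarities
#' (constant features) give distance 1; the diagonal is 0.
#'
#' @param t a [feature_table] with at least 2 features.
#' @param measure similarity measure name (see [halla_config()]).
#' @param n_bins bin-count override for the MI-based measures.
#' @return Symmetric dissimilarity matrix in `[0, 1]`.
#' @export
association_distance <- function(t, measure = "spearman", n_bins = NULL) {
  measure <- match.arg(measure,
                       c("spearman", "pearson", "mi", "nmi", "xicor", "dcor"))
  k <- n_features(t)
  stopifnot(k >= 2L)
  V <- t$values
  d <- matrix(1, k, k, dimnames = list(feature_ids(t), feature_ids(t)))

  if (measure %in% c("spearman", "pearson")) {
    if (any(t$kinds == "categorical")) {
      stop("measure '", measure, "' requires continuous features; ",
           "use measure 'mi' or 'nmi' for categorical data")
    }
    if (measure == "spearman") V <- t(apply(V, 1L, rank, na.last = "keep"))
    s <- suppressWarnings(cor(t(V), use = "pairwise.complete.obs"))
    s[!is.finite(s)] <- 0
    d <- 1 - pmin(abs(s), 1)
  } else if (measure %in% c("mi", "nmi")) {
    labs <- discretize_table(t, n_bins)$labels
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cp <- complete_pairs(labs[i, ], labs[j, ])
        hx <- entropy_nats(cp$x)
        hy <- entropy_nats(cp$y)
        s <- if (cp$n < 2L || hx == 0 || hy == 0) 0 else
          mutual_information(cp$x, cp$y) / sqrt(hx * hy)
        d[i, j] <- d[j, i] <- 1 - min(max(s, 0), 1)
      }
    }
  } else if (measure == "xicor") {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cp <- complete_pairs(V[i, ], V[j, ])
        s <- if (cp$n < 3L) NA else
          max(xi_statistic(cp$x, cp$y, seed = derive_seed(1, i, j)),
              xi_statistic(cp$y, cp$x, seed = derive_seed(1, j, i)))
        s <- if (is.na(s)) 0 else min(max(s, 0), 1)
        d[i, j] <- d[j, i] <- 1 - s
      }
    }
  } else { # dcor
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        cp <- complete_pairs(V[i, ], V[j, ])
        s <- if (cp$n < 2L) NA else dcor_statistic(cp$x, cp$y)
        d[i, j] <- d[j, i] <- 1 - min(max(ifelse(is.na(s), 0, s), 0), 1)
      }
    }
  }
  diag(d) <- 0
  d
}

# Convert an hclust object into a nested node structure carrying, at each
# node, the sorted leaf index set, the merge height, and a preorder id.
hclust_to_tree <- function(hc, labels) {
  counter <- new.env()
  counter$i <- 0L
  build <- function(k) {
    counter$i <- counter$i + 1L
    my_id <- counter$i
    if (k < 0L) {
      list(id = my_id, set = -k, height = 0, leaf = TRUE)
    } else {
      left <- build(hc$merge[k, 1L])
      right <- build(hc$merge[k, 2L])
      list(id = my_id, set = sort(c(left$set, right$set)),
           height = hc$height[k], leaf = FALSE, left = left, right = right)
    }
  }
  root <- if (is.null(hc)) {
    list(id = 1L, set = 1L, height = 0, leaf = TRUE)
  } else {
    build(nrow(hc$merge))
  }
  structure(list(root = root, hclust = hc, labels = labels),
            class = "cluster_tree")
}

#' Average-linkage cluster tree over features
#'
#' UPGMA tree from a dissimilarity matrix (via [stats::hclust()] with
#' `method = "average"`).
#'
#' @param d symmetric dissimilarity matrix with feature IDs as dimnames.
#' @return An object of class `cluster_tree`: the nested node structure
#'   (`root`), the underlying `hclust` object, and the leaf `labels`.
#' @export
build_tree <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("F", seq_len(nrow(d)))
  if (nrow(d) == 1L) return(hclust_to_tree(NULL, labels))
  hc <- hclust(as.dist(d), method = "average")
  hclust_to_tree(hc, labels)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat("cluster_tree: ", length(x$labels), " leaves",
      if (!is.null(x$hclust)) paste0(", root height ",
                                     format(max(x$hclust$height), digits = 4)),
      "\n", sep = "")
  invisible(x)
}

#' Leaf order of a cluster tree
#'
#' @param tree a `cluster_tree`
#' @return Integer vector: dendrogram leaf order (feature indices).
#' @export
tree_leaf_order <- function(tree) {
  if (is.null(tree$hclust)) return(seq_along(tree$labels))
  tree$hclust$order
}

#' Export a cluster tree in Newick format
#'
#' Leaf names are feature IDs; branch lengths are height deltas.
#'
#' @param tree a `cluster_tree`
#' @param file optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to file.
#' @export
tree_newick <- function(tree, file = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  if (is.null(tree$hclust)) {
    nwk <- paste0("(", tree$labels[1L], ");")
  } else {
    phy <- ape::as.phylo(tree$hclust)
    nwk <- ape::write.tree(phy)
  }
  if (is.null(file)) return(nwk)
  writeLines(nwk, file)
  invisible(nwk)
}
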