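# Independent reference implementations used as oracles.  These are kept
# deliberately naive (loops, direct transcription of definitions) and
# never share code with the package internals they check.

# Step-up BH by brute force: largest sorted p with p_(i) <= i*alpha/m.
brute_bh_threshold <- function(p, alpha) {
  m <- length(p)
  s <- sort(p)
  k <- 0
  for (i in seq_len(m)) {
    if (s[i] <= i * alpha / m) k <- s[i]
  }
  k
}

# BH q-values by brute force: running minimum of m*p_(j)/j from the top.
brute_bh_qvalues <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  run <- 1
  for (i in rev(seq_len(m))) {
    run <- min(run, m * p[o[i]] / i)
    q[o[i]] <- run
  }
  q
}

# Naive UPGMA returning the cophenetic distance matrix.
brute_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  cd <- matrix(0, n, n)
  dd <- d
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA)
    bestval <- Inf
    for (a in idx) {
      for (b in idx) {
        if (a < b && dd[a, b] < bestval) {
          bestval <- dd[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      cd[i, j] <- cd[j, i] <- bestval
    }
    merged <- c(clusters[[a]], clusters[[b]])
    # average linkage: size-weighted mean of the two cluster distances
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    for (k in idx) {
      if (k != a && k != b) {
        dd[a, k] <- dd[k, a] <- (na * dd[a, k] + nb * dd[b, k]) / (na + nb)
      }
    }
    clusters[[a]] <- merged
    active[b] <- FALSE
  }
  cd
}

# Direct transcription of the descent rules: no pruning, no memoization.
ref_descend <- function(xn, yn, P, k_bh, any_reject, fnt) {
  gini <- function(v) {
    p1 <- mean(v)
    1 - p1^2 - (1 - p1)^2
  }
  rec <- function(xn, yn) {
    cells <- P[xn$set, yn$set, drop = FALSE]
    rej <- if (any_reject) cells <= k_bh else
      matrix(FALSE, nrow(cells), ncol(cells))
    ff <- 1 - mean(rej)
    if (ff <= fnt) return(list(list(x = xn$set, y = yn$set)))
    if (xn$leaf && yn$leaf) return(list())
    gx <- if (!xn$leaf) {
      n <- length(rej)
      l <- (if (any_reject) P[xn$left$set, yn$set, drop = FALSE] <= k_bh
            else matrix(FALSE, length(xn$left$set), length(yn$set)))
      r <- (if (any_reject) P[xn$right$set, yn$set, drop = FALSE] <= k_bh
            else matrix(FALSE, length(xn$right$set), length(yn$set)))
      gini(rej) - (length(l) / n) * gini(l) - (length(r) / n) * gini(r)
    } else {
      -Inf
    }
    gy <- if (!yn$leaf) {
      n <- length(rej)
      l <- (if (any_reject) P[xn$set, yn$left$set, drop = FALSE] <= k_bh
            else matrix(FALSE, length(xn$set), length(yn$left$set)))
      r <- (if (any_reject) P[xn$set, yn$right$set, drop = FALSE] <= k_bh
            else matrix(FALSE, length(xn$set), length(yn$right$set)))
      gini(rej) - (length(l) / n) * gini(l) - (length(r) / n) * gini(r)
    } else {
      -Inf
    }
    if (gx > gy) {
      c(rec(xn$left, yn), rec(xn$right, yn))
    } else if (gy > gx) {
      c(rec(xn, yn$left), rec(xn, yn$right))
    } else {
      c(rec(xn$left, yn$left), rec(xn$left, yn$right),
        rec(xn$right, yn$left), rec(xn$right, yn$right))
    }
  }
  out <- rec(xn, yn)
  # deduplicate rectangles arising from convergent BOTH paths
  keys <- vapply(out, function(b) {
    paste(paste(b$x, collapse = ","), paste(b$y, collapse = ","), sep = "|")
  }, character(1))
  out[!duplicated(keys)]
}

# Canonical string form of a set of reported rectangles, for comparisons.
rect_keys <- function(blocks) {
  sort(vapply(blocks, function(b) {
    xs <- if (!is.null(b$x_set)) b$x_set else b$x
    ys <- if (!is.null(b$y_set)) b$y_set else b$y
    paste(paste(sort(xs), collapse = ","), paste(sort(ys), collapse = ","),
          sep = "|")
  }, character(1)))
}

# Random descent instance: a p-value matrix with a planted low-p patch and
# average-linkage trees over random dissimilarities.
random_instance <- function(nx, ny, seed) {
  set.seed(seed)
  P <- matrix(runif(nx * ny), nx, ny)
  low <- matrix(runif(nx * ny) < 0.3, nx, ny)
  P[low] <- P[low] * 0.004
  dx <- as.matrix(dist(matrix(runif(nx * 3), nx)))
  dy <- as.matrix(dist(matrix(runif(ny * 3), ny)))
  dimnames(P) <- list(paste0("x", seq_len(nx)), paste0("y", seq_len(ny)))
  rownames(dx) <- colnames(dx) <- rownames(P)
  rownames(dy) <- colnames(dy) <- colnames(P)
  list(P = P, xt = build_tree(dx), yt = build_tree(dy))
}

# Tiny feature table from a plain matrix.
ft <- function(M, kinds = NULL, prefix = "f") {
  if (is.null(rownames(M))) rownames(M) <- paste0(prefix, seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("s", seq_len(ncol(M)))
  feature_table(M, kinds = kinds)
}

write_tsv_fixture <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# All permutations of 1..n (n small).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (k in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = k)
    }
  }
  out
}
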