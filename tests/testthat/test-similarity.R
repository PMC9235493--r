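test_that("spearman statistic matches the closed rank formula and cor.test", {
  r <- spearman_assoc(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))
  expect_equal(r$statistic, cor(1:5, c(3, 1, 2, 5, 4), method = "spearman"))
  # the printed 3-point case (below the n>=5 floor) via the raw formula
  expect_equal(cor(1:3, c(3, 1, 2), method = "spearman"), -0.5)
  expect_equal(spearman_assoc(1:8, (1:8)^3)$statistic, 1)
  expect_equal(spearman_assoc(1:8, rev(1:8))$statistic, -1)
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(30)
    y <- rnorm(30)
    ours <- spearman_assoc(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(ours$statistic, unname(ref$estimate))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("pearson matches cor.test and is affine-invariant", {
  x <- c(0, 1, 2, 4, 7)
  expect_equal(pearson_assoc(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_assoc(x, -x)$statistic, -1)
  # frozen 3-point covariance example via the raw formula
  expect_equal(round(cor(c(0, 1, 2), c(0, 1, 4)), 4), 0.9608)
  set.seed(8)
  x <- rnorm(25); y <- rnorm(25)
  ref <- cor.test(x, y)
  ours <- pearson_assoc(x, y)
  expect_equal(ours$statistic, unname(ref$estimate))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("degenerate inputs give statistic 0, p 1 with a warning", {
  expect_warning(r <- spearman_assoc(rep(1, 10), rnorm(10)), "constant")
  expect_equal(c(r$statistic, r$p_value), c(0, 1))
  expect_warning(r2 <- pearson_assoc(1:3, c(1, 2, 3)), "complete pairs")
  expect_equal(r2$p_value, 1)
  expect_warning(r3 <- xicor_assoc(rnorm(10), rep(2, 10)), "constant")
  expect_equal(r3$statistic, 0)
})

test_that("mutual information closed forms hold", {
  x <- rep(c(1L, 2L), each = 10)
  expect_equal(mi_assoc(x, x, n_perm = 20)$statistic, log(2))
  # independent product table has zero MI
  a <- rep(c(1L, 2L), times = 10)
  b <- rep(c(1L, 1L, 2L, 2L), times = 5)
  expect_equal(mi_assoc(a, b, n_perm = 20)$statistic, 0)
  set.seed(3)
  u <- sample(1:3, 40, TRUE); v <- sample(1:3, 40, TRUE)
  expect_equal(mi_assoc(u, v, n_perm = 10, seed = 5)$statistic,
               mi_assoc(v, u, n_perm = 10, seed = 5)$statistic)
  expect_equal(mi_assoc(rep(1L, 10), sample(1:2, 10, TRUE), 10)$p_value, 1)
})

test_that("NMI is MI normalized into [0, 1]", {
  x <- rep(c(1L, 2L), each = 12)
  expect_equal(nmi_assoc(x, x, n_perm = 20)$statistic, 1)
  set.seed(4)
  for (i in 1:10) {
    u <- sample(1:4, 30, TRUE)
    v <- sample(1:4, 30, TRUE)
    s <- nmi_assoc(u, v, n_perm = 5)$statistic
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("xi equals (n-2)/(n+1) on monotone tie-free data and is asymmetric", {
  expect_equal(xicor_assoc(1:5, 1:5)$statistic, 0.5)   # (n-2)/(n+1) = 3/6
  for (n in c(6, 11, 30)) {
    x <- sort(rnorm(n))
    expect_equal(xicor_assoc(x, x^3 + 10)$statistic, (n - 2) / (n + 1))
  }
  # y a function of x but not vice versa: xi(x,y) >> xi(y,x)
  set.seed(11)
  x <- rnorm(200)
  y <- x^2
  expect_gt(xicor_assoc(x, y)$statistic, 0.5)
  expect_lt(xicor_assoc(y, x)$statistic, xicor_assoc(x, y)$statistic)
})

test_that("distance correlation detects exact dependence and is symmetric", {
  x <- rnorm(20)
  expect_equal(dcor_assoc(x, x, n_perm = 20)$statistic, 1)
  set.seed(5)
  u <- rnorm(15); v <- rnorm(15)
  a <- dcor_assoc(u, v, n_perm = 10, seed = 2)
  b <- dcor_assoc(v, u, n_perm = 10, seed = 2)
  expect_equal(a$statistic, b$statistic)
  expect_gte(a$statistic, 0)
})

test_that("permutation p-value matches exhaustive enumeration at n = 4", {
  x <- c(1L, 1L, 2L, 2L)
  y <- c(1L, 1L, 2L, 2L)
  stat_raw <- function(a, b) {
    tab <- table(a, b); n <- sum(tab); pij <- tab / n
    pi_ <- rowSums(pij); p_j <- colSums(pij); nz <- pij > 0
    sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  }
  obs <- stat_raw(x, y)
  expect_equal(obs, log(2))
  perms <- matrix(unlist(lapply(combinat_perms(4), function(p) y[p])),
                  ncol = 4, byrow = TRUE)
  stats <- apply(perms, 1, function(yy) stat_raw(x, yy))
  p_exact <- mean(abs(stats) >= abs(obs) - 1e-12)
  expect_equal(p_exact, 1 / 3)   # 8 of 24 orderings reproduce +/- log 2
  n_perm <- 4000
  p_hat <- permutation_pvalue(stat_raw, x, y, n_perm, seed = 9)
  expected <- (1 + n_perm * p_exact) / (1 + n_perm)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(p_hat - expected), 4 * se + 1e-9)
  expect_gte(p_hat, 1 / (n_perm + 1))
  expect_lte(p_hat, 1)
})

test_that("pairwise_matrix has the contract shape, q-values, and error path", {
  set.seed(21)
  x <- ft(matrix(rnorm(2 * 30), 2, 30))
  y <- ft(matrix(rnorm(3 * 30), 3, 30), prefix = "g")
  pr <- pairwise_matrix(x, y, halla_config())
  expect_equal(dim(pr$P), c(2L, 3L))
  expect_equal(dim(pr$S), dim(pr$Q))
  expect_equal(as.vector(pr$Q), bh_qvalues(as.vector(pr$P)))

  cat_t <- feature_table(matrix(rep(c(1, 2), 15), 1, 30),
                         kinds = "categorical")
  colnames(cat_t$values) <- colnames(x$values)
  expect_error(pairwise_matrix(x, cat_t, halla_config("spearman")), "mi")

  # planted identical feature pins the matrix minimum
  y2 <- y
  y2$values[2, ] <- x$values[1, ]
  pr2 <- pairwise_matrix(x, y2, halla_config())
  expect_equal(min(pr2$P), pr2$P[1, 2])
})

test_that("parametric p-values are near-uniform under independence", {
  set.seed(31)
  n <- 100
  x <- ft(matrix(rnorm(15 * n), 15, n))
  y <- ft(matrix(rnorm(15 * n), 15, n), prefix = "g")
  for (m in c("spearman", "pearson")) {
    pr <- pairwise_matrix(x, y, halla_config(m))
    ks <- suppressWarnings(ks.test(as.vector(pr$P), "punif"))
    expect_gt(ks$p.value, 0.001)
    expect_lt(abs(mean(pr$P < 0.05) - 0.05), 0.035)
  }
})

test_that("results are invariant to a joint sample permutation", {
  set.seed(12)
  M1 <- matrix(rnorm(3 * 24), 3, 24)
  M2 <- matrix(rnorm(3 * 24), 3, 24)
  perm <- sample(24)
  p1 <- pairwise_matrix(ft(M1), ft(M2, prefix = "g"), halla_config())
  p2 <- pairwise_matrix(ft(M1[, perm]), ft(M2[, perm], prefix = "g"),
                        halla_config())
  expect_equal(p1$S, p2$S, ignore_attr = TRUE)
  expect_equal(p1$P, p2$P, ignore_attr = TRUE)
})
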