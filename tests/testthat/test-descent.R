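make_ctx <- function(P, alpha = 0.05) bh_threshold(as.vector(P), alpha)

test_that("fail fraction counts cells above the global threshold", {
  inst <- random_instance(5, 5, 1)
  ctx <- make_ctx(inst$P)
  b <- hypothesis_block(inst$xt$root, inst$yt$root)
  ff <- block_fail_fraction(b, inst$P, ctx)
  expect_equal(ff, mean(inst$P > ctx$k_bh))
  # 10-cell block with 9 rejecting cells
  P <- matrix(c(rep(1e-6, 9), 0.9), 2, 5)
  dimnames(P) <- list(paste0("x", 1:2), paste0("y", 1:5))
  ctx2 <- make_ctx(P, 0.05)
  fake <- list(x_set = 1:2, y_set = 1:5)
  expect_equal(block_fail_fraction(fake, P, ctx2), 0.1)
  expect_true(block_significant(fake, P, ctx2, 0.2))
  expect_false(block_significant(fake, P, ctx2, 0.05))
  # empty rejection set: fraction 1 regardless of block
  ctx0 <- bh_threshold(rep(0.8, 25), 0.05)
  expect_equal(block_fail_fraction(fake, P, ctx0), 1)
})

test_that("gini impurity and split gain follow the worked examples", {
  expect_equal(gini_impurity(rep(TRUE, 6)), 0)
  expect_equal(gini_impurity(c(TRUE, FALSE)), 0.5)
  expect_equal(gini_impurity(c(TRUE, TRUE, TRUE, FALSE)), 0.375)
  expect_error(gini_impurity(logical(0)))

  # 2x2 parent with rejection rows (1,1)/(0,0): row split separates
  # perfectly (gain 0.5), column split gains nothing
  P <- matrix(c(1e-9, 0.9, 1e-9, 0.9), 2, 2)
  dimnames(P) <- list(c("x1", "x2"), c("y1", "y2"))
  ctx <- make_ctx(P, 0.05)
  xt <- build_tree(matrix(c(0, 1, 1, 0), 2, 2,
                          dimnames = list(c("x1", "x2"), c("x1", "x2"))))
  yt <- build_tree(matrix(c(0, 1, 1, 0), 2, 2,
                          dimnames = list(c("y1", "y2"), c("y1", "y2"))))
  b <- hypothesis_block(xt$root, yt$root)
  expect_equal(split_gain(b, "X", P, ctx), 0.5)
  expect_equal(split_gain(b, "Y", P, ctx), 0)
  expect_equal(choose_split(b, P, ctx), "X")
  expect_error(split_gain(hypothesis_block(xt$root$left, yt$root$left),
                          "X", P, ctx), "leaf")
  expect_error(choose_split(hypothesis_block(xt$root$left, yt$root$left),
                            P, ctx), "leaves")
  # forced side when one node is a leaf
  expect_equal(choose_split(hypothesis_block(xt$root$left, yt$root), P, ctx),
               "Y")
})

test_that("split gain is nonnegative and zero on pure parents", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instance(6, 6, 100 + i)
    ctx <- make_ctx(inst$P)
    b <- hypothesis_block(inst$xt$root, inst$yt$root)
    expect_gte(split_gain(b, "X", inst$P, ctx), -1e-12)
    expect_gte(split_gain(b, "Y", inst$P, ctx), -1e-12)
  }
  Pp <- matrix(1e-9, 4, 4,
               dimnames = list(paste0("x", 1:4), paste0("y", 1:4)))
  inst <- random_instance(4, 4, 3)
  ctx <- make_ctx(Pp, 0.05)
  b <- hypothesis_block(inst$xt$root, inst$yt$root)
  expect_equal(split_gain(b, "X", Pp, ctx), 0)
})

test_that("descent handles the trivial extremes", {
  inst <- random_instance(6, 5, 2)
  # every cell rejectable: the root is the single reported block
  P1 <- matrix(1e-8, 6, 5, dimnames = dimnames(inst$P))
  rep1 <- descend(inst$xt, inst$yt, P1, make_ctx(P1), 0.2)
  expect_length(rep1$blocks, 1L)
  expect_setequal(rep1$blocks[[1]]$x_set, 1:6)
  expect_setequal(rep1$blocks[[1]]$y_set, 1:5)
  # no cell rejectable: empty report
  P0 <- matrix(0.9, 6, 5, dimnames = dimnames(inst$P))
  rep0 <- descend(inst$xt, inst$yt, P0, make_ctx(P0), 0.2)
  expect_length(rep0$blocks, 0L)
})

test_that("with zero tolerance the reported cells equal the BH rejection set", {
  for (i in 1:200) {
    inst <- random_instance(8, 8, 1000 + i)
    ctx <- make_ctx(inst$P)
    rep <- descend(inst$xt, inst$yt, inst$P, ctx, fnt = 0)
    pairs <- expand_to_pairs(rep)
    got <- sort((pairs[, 2] - 1) * 8 + pairs[, 1])
    idx <- which(reject_set <- inst$P <= ctx$k_bh & ctx$n_reject > 0)
    expect_equal(got, idx)
  }
})

test_that("descent agrees with a direct-transcription reference recursion", {
  for (i in 1:100) {
    inst <- random_instance(10, 10, 5000 + i)
    fnt <- sample(c(0, 0.1, 0.2, 0.35, 0.5), 1)
    ctx <- make_ctx(inst$P, sample(c(0.05, 0.25), 1))
    ours <- descend(inst$xt, inst$yt, inst$P, ctx, fnt)
    ref <- ref_descend(inst$xt$root, inst$yt$root, inst$P, ctx$k_bh,
                       ctx$n_reject > 0, fnt)
    expect_equal(rect_keys(ours$blocks), rect_keys(ref))
  }
})

test_that("reported blocks are disjoint and cover every rejected cell once", {
  for (i in 1:60) {
    inst <- random_instance(9, 7, 300 + i)
    ctx <- make_ctx(inst$P)
    fnt <- sample(c(0, 0.2, 0.4), 1)
    rep <- descend(inst$xt, inst$yt, inst$P, ctx, fnt)
    pairs <- expand_to_pairs(rep)
    keys <- (pairs[, 2] - 1) * 9 + pairs[, 1]
    expect_equal(anyDuplicated(keys), 0L)            # disjoint rectangles
    rejected <- which(inst$P <= ctx$k_bh & ctx$n_reject > 0)
    expect_true(all(rejected %in% keys))             # coverage
  }
})

test_that("cells reported at zero tolerance stay covered at larger tolerance", {
  for (i in 1:40) {
    inst <- random_instance(8, 8, 700 + i)
    ctx <- make_ctx(inst$P)
    p0 <- expand_to_pairs(descend(inst$xt, inst$yt, inst$P, ctx, 0))
    p2 <- expand_to_pairs(descend(inst$xt, inst$yt, inst$P, ctx, 0.3))
    k0 <- (p0[, 2] - 1) * 8 + p0[, 1]
    k2 <- (p2[, 2] - 1) * 8 + p2[, 1]
    expect_true(all(k0 %in% k2))
  }
})

test_that("rank_blocks orders by best p, then size, then feature IDs", {
  inst <- random_instance(6, 6, 77)
  P <- matrix(0.9, 6, 6, dimnames = dimnames(inst$P))
  P[1:2, 1:2] <- 1e-4            # 4-cell block
  P[5, 5] <- 1e-4                # tied singleton
  P[6, 6] <- 1e-9                # best singleton
  report <- structure(list(
    blocks = list(
      list(x_set = 1:2, y_set = 1:2, fail_fraction = 0,
           best_p = NA, best_q = NA, rank = NA),
      list(x_set = 5L, y_set = 5L, fail_fraction = 0,
           best_p = NA, best_q = NA, rank = NA),
      list(x_set = 6L, y_set = 6L, fail_fraction = 0,
           best_p = NA, best_q = NA, rank = NA)),
    x_ids = rownames(P), y_ids = colnames(P)), class = "block_report")
  Q <- matrix(bh_qvalues(as.vector(P)), 6, 6, dimnames = dimnames(P))
  ranked <- rank_blocks(report, P, Q)
  expect_equal(vapply(ranked$blocks, `[[`, integer(1), "rank"), 1:3)
  expect_equal(ranked$blocks[[1]]$x_set, 6L)          # smallest p first
  expect_equal(ranked$blocks[[2]]$x_set, 1:2)         # tie: larger block
  expect_equal(ranked$blocks[[3]]$x_set, 5L)
  expect_equal(ranked$blocks[[1]]$best_p, 1e-9)
  expect_equal(ranked$blocks[[1]]$best_q, Q[6, 6])
})
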