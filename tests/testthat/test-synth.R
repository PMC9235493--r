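test_that("truth rectangles count pairs and respect requested sizes", {
  specs <- list(block_spec(2, 3), block_spec(4, 1))
  gen <- generate_paired(10, 10, 30, specs, seed = 1)
  expect_equal(nrow(truth_pairs(gen$truth)), 2 * 3 + 4 * 1)
  expect_equal(n_features(gen$x), 10L)
  expect_equal(n_samples(gen$x), 30L)
  sets <- lapply(gen$truth$rects, `[[`, "x_set")
  expect_equal(anyDuplicated(unlist(sets)), 0L)       # disjoint blocks
  expect_error(generate_paired(3, 3, 20, list(block_spec(4, 2)), seed = 1),
               "exceed")
})

test_that("generation is bit-reproducible under a seed", {
  g1 <- generate_paired(20, 20, 25, random_block_specs(2, 3:4, seed = 5),
                        seed = 5)
  g2 <- generate_paired(20, 20, 25, random_block_specs(2, 3:4, seed = 5),
                        seed = 5)
  expect_identical(g1$x$values, g2$x$values)
  expect_identical(g1$y$values, g2$y$values)
  expect_identical(g1$truth$rects, g2$truth$rects)
  g3 <- generate_paired(20, 20, 25, random_block_specs(2, 3:4, seed = 5),
                        seed = 6)
  expect_false(identical(g1$x$values, g3$x$values))
})

test_that("noise-free full-strength linear blocks are perfectly monotone", {
  specs <- list(block_spec(3, 3, "linear", strength = 1, coherence = 1))
  gen <- generate_paired(6, 6, 30, specs, seed = 2)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(abs(cor(gen$x$values[i, ], gen$y$values[j, ],
                         method = "spearman")), 1)
  }
})

test_that("monotone link types beat non-monotone ones under Spearman", {
  mean_abs_rho <- function(type) {
    vals <- numeric(0)
    for (s in 1:6) {
      gen <- generate_paired(8, 8, 60,
                             list(block_spec(4, 4, type, strength = 1,
                                             coherence = 0.9)),
                             seed = 400 + s)
      tp <- truth_pairs(gen$truth)
      vals <- c(vals, abs(vapply(seq_len(nrow(tp)), function(k) {
        cor(gen$x$values[tp[k, 1], ], gen$y$values[tp[k, 2], ],
            method = "spearman")
      }, numeric(1))))
    }
    mean(vals)
  }
  mono <- vapply(c("linear", "logarithmic", "stepwise"), mean_abs_rho,
                 numeric(1))
  nonmono <- vapply(c("quadratic", "sinusoidal", "parabolic"), mean_abs_rho,
                    numeric(1))
  expect_gt(min(mono), max(nonmono))
})

test_that("mixed and categorical blocks emit labeled categorical features", {
  gen <- generate_paired(6, 6, 40, list(block_spec(2, 2, "mixed")), seed = 9)
  expect_true(all(gen$x$kinds[1:2] == "continuous"))
  expect_true(all(gen$y$kinds[1:2] == "categorical"))
  expect_equal(gen$y$levels$Y1, c("a", "b", "c"))
  gen2 <- generate_paired(6, 6, 40, list(block_spec(2, 2, "categorical")),
                          seed = 9)
  expect_true(all(gen2$x$kinds[1:2] == "categorical"))
  # categorical block members associate: MI above its null quantile
  r <- mi_assoc(gen2$x$values[1, ], gen2$y$values[1, ], n_perm = 200,
                seed = 1)
  expect_lt(r$p_value, 0.05)
})

test_that("noise features carry no association signal", {
  set.seed(6)
  pvals <- numeric(0)
  for (s in 1:3) {
    gen <- generate_paired(12, 12, 50, list(block_spec(3, 3)), seed = 60 + s)
    pr <- pairwise_matrix(gen$x, gen$y, halla_config())
    null_p <- pr$P[4:12, 4:12]        # pairs outside the planted block
    pvals <- c(pvals, as.vector(null_p))
  }
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.035)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("benchmark grids match the published experiment design", {
  g2 <- benchmark_config("fig2")
  expect_setequal(unique(g2$alpha[g2$fnt == 0.2]), c(0.05, 0.1, 0.25, 0.5))
  expect_true(0.2 %in% g2$fnt)
  expect_true(all(g2$measure == "spearman"))
  g3 <- benchmark_config("fig3")
  expect_setequal(unique(g3$measure), c("spearman", "pearson", "mi", "xicor"))
  expect_false(any(c("dcor", "nmi") %in% g3$measure))
  cat_rows <- g3[g3$assoc_type %in% c("mixed", "categorical"), ]
  expect_true(all(cat_rows$measure == "mi"))
})
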