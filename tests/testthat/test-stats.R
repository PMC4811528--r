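test_that("count summaries reproduce the published night and region cells", {
  tb <- load_table1_fixture()
  n1 <- summarize_counts(tb, 1)
  expect_equal(n1$mean, 26.67, tolerance = 0.001)
  expect_equal(n1$sd, 10.94, tolerance = 0.001)
  expect_equal(n1$n, 12)
  # night 3 drops the excluded pair
  n3 <- summarize_counts(tb, 3)
  expect_equal(n3$mean, 58.27, tolerance = 0.001)
  expect_equal(n3$n, 11)
  # night 4 includes the male-bedding footnote songs
  n4 <- summarize_counts(tb, 4, include_mb = TRUE)
  expect_equal(n4$mean, 44.17, tolerance = 0.001)
  expect_equal(n4$n, 6)
  # night-1 contact corners under drop-zero
  cc <- summarize_counts(tb, 1, region = "CC", zero_policy = "drop_zero")
  expect_equal(cc$mean, 17.7, tolerance = 0.001)
  expect_equal(cc$sd, 9.66, tolerance = 0.001)
  expect_equal(cc$n, 10)
  # single pair: sd undefined
  one <- summarize_counts(tb[tb$pair == "MS_01", ], 1)
  expect_equal(one$mean, 33)
  expect_true(is.na(one$sd))
  expect_error(summarize_counts(tb, 9), "no pair-nights")
})

test_that("bonferroni thresholds match the published significance levels", {
  set.seed(1)
  g4 <- setNames(lapply(1:4, function(i) rnorm(10, i / 10)),
                 paste0("n", 1:4))
  res <- pairwise_wilcoxon(g4, alpha = 0.05) # 6 comparisons
  expect_equal(nrow(res), 6)
  expect_equal(unique(res$threshold), 0.05 / 6, tolerance = 1e-12)
  res3 <- pairwise_wilcoxon(g4[1:3], alpha = 0.05) # 3 comparisons
  expect_equal(unique(res3$threshold), 0.05 / 3, tolerance = 1e-12)
  # identical paired samples: p = 1, not significant
  same <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  rs <- pairwise_wilcoxon(same, paired = TRUE)
  expect_false(rs$significant)
  expect_error(pairwise_wilcoxon(list(a = 1:4, b = 1:5), paired = TRUE),
               "unequal")
})

test_that("trial consistency reproduces the published correlation", {
  tb <- load_table1_fixture()
  tc <- trial_consistency(tb)
  expect_equal(tc$n, 5)
  expect_equal(round(tc$r, 2), 0.97)
  expect_equal(round(tc$p, 3), 0.006)
  # exact linear relation
  fake <- tb[tb$pair %in% c("MS_03", "MS_04", "MS_05"), ]
  fake$rep_sum <- 2 * fake$sum
  expect_equal(trial_consistency(fake)$r, 1)
  expect_error(trial_consistency(tb[tb$pair %in% c("MS_03", "MS_04"), ]),
               "at least 3")
})

test_that("univariate euclidean pseudo-F equals the classical anova F", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(30)
    g <- sample(rep(c("a", "b", "c"), 10))
    pr <- permanova_restricted(matrix(x), g, n_perm = 9, seed = 1,
                               standardize = FALSE)
    Fa <- summary(stats::aov(x ~ g))[[1]]$`F value`[1]
    expect_equal(pr$pseudo_F, Fa, tolerance = 1e-10)
    expect_equal(pr$df_between, 2)
    expect_equal(pr$df_within, 27)
  }
})

test_that("multivariate pseudo-F matches the vegan oracle", {
  skip_if_not_installed("vegan")
  set.seed(19)
  X <- matrix(rnorm(60), ncol = 3)
  g <- rep(c("a", "b"), each = 10)
  pr <- permanova_restricted(X, g, n_perm = 99, seed = 3,
                             standardize = FALSE)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 99)
  expect_equal(pr$pseudo_F, ad$F[1], tolerance = 1e-8)
})

test_that("restricted permutations preserve block multisets and reproduce", {
  set.seed(10)
  X <- matrix(rnorm(24, rep(c(0, 1), each = 12)))
  g <- rep(rep(c("a", "b"), each = 2), 6)
  blocks <- rep(1:6, each = 4)
  r1 <- permanova_restricted(X, g, blocks, n_perm = 199, seed = 77)
  r2 <- permanova_restricted(X, g, blocks, n_perm = 199, seed = 77)
  expect_identical(r1$p, r2$p) # bit-exact given (seed, n_perm)
  expect_gte(r1$p, 1 / 200)
  expect_lte(r1$p, 1)
  # the per-draw multiset assertion lives inside the permutation loop;
  # a run completing without error certifies every draw
  expect_error(
    permanova_restricted(X, g, blocks = seq_len(24), n_perm = 9, seed = 1),
    "singleton")
})

test_that("permanova type-I error is nominal under the null", {
  set.seed(11)
  nsim <- 500
  rej <- 0
  for (i in seq_len(nsim)) {
    X <- matrix(rnorm(24))
    blocks <- rep(1:6, each = 4)
    g <- unlist(lapply(1:6, function(b) sample(rep(c("A", "B"), 2))))
    if (permanova_restricted(X, g, blocks, n_perm = 199, seed = i)$p <= 0.05)
      rej <- rej + 1
  }
  band <- stats::qbinom(c(0.025, 0.975), nsim, 0.05)
  expect_gte(rej, band[1])
  expect_lte(rej, band[2])
})

test_that("degenerate distance structure yields p = 1, flagged", {
  X <- matrix(rep(1, 12))
  g <- rep(c("a", "b"), 6)
  r <- permanova_restricted(X, g, n_perm = 9, seed = 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$pseudo_F))
  expect_equal(r$p, 1)
})

test_that("fisher lda matches the MASS oracle and normalizes the trace", {
  skip_if_not_installed("MASS")
  set.seed(4)
  X <- matrix(rnorm(240), ncol = 4)
  g <- rep(letters[1:3], each = 20)
  X[g == "b", 1] <- X[g == "b", 1] + 2
  X[g == "c", 2] <- X[g == "c", 2] + 1
  mine <- fisher_lda(X, g)
  oracle <- MASS::lda(X, g)
  expect_equal(mine$trace_proportions,
               oracle$svd^2 / sum(oracle$svd^2), tolerance = 1e-8)
  for (k in 1:2) {
    expect_equal(abs(cor(mine$loadings[, k], oracle$scaling[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(sum(mine$trace_proportions), 1, tolerance = 1e-12)
})

test_that("well-separated clouds put nearly all trace on LD1", {
  set.seed(6)
  X <- rbind(cbind(rnorm(50, 0), rnorm(50)), cbind(rnorm(50, 8), rnorm(50)))
  g <- rep(c("a", "b"), each = 50)
  r <- fisher_lda(X, g)
  expect_gt(r$trace_proportions[1], 0.99)
})

test_that("lda projections are scale-invariant and singularities warned", {
  set.seed(14)
  X <- matrix(rnorm(200), ncol = 4)
  g <- rep(c("a", "b"), each = 25)
  X[g == "b", ] <- X[g == "b", ] + 1
  r1 <- fisher_lda(X, g)
  X2 <- X; X2[, 3] <- X2[, 3] * 1000 # affine rescale of one feature
  r2 <- fisher_lda(X2, g)
  expect_equal(abs(cor(r1$projections[, 1], r2$projections[, 1])), 1,
               tolerance = 1e-6)
  # duplicated column: ridge regularization with warning
  expect_warning(r3 <- fisher_lda(cbind(X, X[, 1]), g), "singular")
  expect_equal(sum(r3$trace_proportions), 1, tolerance = 1e-8)
  # trace proportions sum to 1 on fuzzed input
  for (rep in 1:10) {
    Xf <- matrix(rnorm(40 * 3), ncol = 3)
    gf <- sample(c("u", "v", "w"), 40, replace = TRUE)
    expect_equal(sum(fisher_lda(Xf, gf)$trace_proportions), 1,
                 tolerance = 1e-10)
  }
})

test_that("chi-square handles hand-checked and degenerate tables", {
  r <- chisq_type_usage(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  # perfectly proportional rows: statistic 0
  r0 <- chisq_type_usage(rbind(c(10, 20, 30), c(20, 40, 60)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  # 2 regions x 13 merged types: df 12 as in the published test
  set.seed(3)
  tab <- matrix(rpois(26, 40) + 1, nrow = 2,
                dimnames = list(c("CC", "CR"), SYLLABLE_TYPES_MERGED))
  expect_equal(chisq_type_usage(tab)$df, 12)
  expect_warning(chisq_type_usage(rbind(c(0, 0), c(3, 4), c(5, 1))),
                 "all-zero")
})
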