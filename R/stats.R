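#' Summarize song counts across pairs
#'
#' Forms the per-pair values for one recording night (either the night
#' total over all regions or a single region) and returns their mean and
#' sample standard deviation, the aggregation behind the published
#' "mean ± sd" song-count cells. Excluded pair-nights are dropped. For
#' per-region summaries the `drop_zero` policy omits pairs that emitted no
#' song in that region-night (pairs without a vocalization in a context do
#' not contribute a zero to that context's statistics); night totals can
#' include the male-bedding counts via `include_mb`.
#'
#' @param counts a `"pair_night_counts"` data frame (from
#'   [tabulate_pair_night_counts()], [load_table1_fixture()] or
#'   [simulate_count_table()]).
#' @param night recording night to summarize.
#' @param region `"all"` for the night total, or one region column name.
#' @param zero_policy `"keep"` or `"drop_zero"` (per-region only).
#' @param include_mb add male-bedding counts into night totals.
#' @return A list of class `"summary_result"`: `mean`, `sd` (`NA` when
#'   `n == 1`), `n`, `grouping`.
#' @export
summarize_counts <- function(counts, night, region = "all",
                             zero_policy = c("keep", "drop_zero"),
                             include_mb = FALSE) {
  zero_policy <- match.arg(zero_policy)
  sel <- counts[counts$night == night & !counts$excluded, , drop = FALSE]
  if (nrow(sel) == 0) stop("no pair-nights selected for night ", night)
  if (identical(region, "all")) {
    vals <- rowSums(sel[, c("FR", "NR", "CC", "CR"), drop = FALSE])
    if (include_mb && "MB" %in% names(sel)) {
      vals <- vals + ifelse(is.na(sel$MB), 0, sel$MB)
    }
  } else {
    if (!region %in% names(sel)) stop("unknown region column: ", region)
    vals <- sel[[region]]
    if (zero_policy == "drop_zero") vals <- vals[!is.na(vals) & vals > 0]
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("empty selection after exclusions")
  structure(list(mean = mean(vals),
                 sd = if (length(vals) > 1) sd(vals) else NA_real_,
                 n = length(vals),
                 grouping = paste0("night ", night, ", region ", region,
                                   if (include_mb) " (+MB)" else "")),
            class = "summary_result")
}

#' @export
print.summary_result <- function(x, ...) {
  cat(sprintf("%s: %.2f +/- %s (n = %d)\n", x$grouping, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd), x$n))
  invisible(x)
}

#' Pairwise Wilcoxon tests with Bonferroni correction
#'
#' Runs a Wilcoxon test for every pair of groups — signed-rank when
#' `paired = TRUE`, rank-sum otherwise — and flags significance against
#' the Bonferroni-corrected level `alpha / m`. Exact p-values are used for
#' small samples without ties; otherwise the normal approximation with tie
#' correction applies (the `stats::wilcox.test` convention).
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @param paired paired comparisons; all groups must then share a length.
#' @param alpha family-wise significance level.
#' @param m number of comparisons for the correction; defaults to the
#'   number of pairwise tests actually run.
#' @return A data frame with one row per comparison: `group1`, `group2`,
#'   `p`, `threshold`, `significant`.
#' @export
pairwise_wilcoxon <- function(groups, paired = FALSE, alpha = 0.05,
                              m = NULL) {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  cmb <- combn(names(groups), 2)
  if (is.null(m)) m <- ncol(cmb)
  thr <- alpha / m
  res <- apply(cmb, 2, function(nm) {
    x <- groups[[nm[1]]]; y <- groups[[nm[2]]]
    if (paired && length(x) != length(y)) {
      stop("paired comparison of unequal-length groups: ",
           nm[1], " vs ", nm[2])
    }
    p <- suppressWarnings(wilcox.test(x, y, paired = paired)$p.value)
    # identical paired samples leave no non-zero differences; by
    # convention that is maximal evidence for the null
    if (is.na(p)) p <- 1
    data.frame(group1 = nm[1], group2 = nm[2], p = p,
               threshold = thr, significant = p < thr)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Trial consistency of repeated recording pairs
#'
#' Pearson correlation between a pair's total song count in the first
#' trial and in its repetition, summed over nights 1-3 (repetitions
#' followed the three-night protocol). Pairs without repetition data are
#' ignored; at least three repeated pairs are required.
#'
#' @param counts a `"pair_night_counts"` table carrying a `rep_sum` column
#'   with the per-night repetition totals.
#' @param nights nights entering the totals.
#' @return A list with `r`, `p`, `n`, and the per-pair `first` and
#'   `repetition` totals.
#' @export
trial_consistency <- function(counts, nights = 1:3) {
  if (!"rep_sum" %in% names(counts)) {
    stop("counts table has no repetition column 'rep_sum'")
  }
  sel <- counts[counts$night %in% nights, , drop = FALSE]
  rep_pairs <- unique(sel$pair[!is.na(sel$rep_sum)])
  if (length(rep_pairs) < 3) {
    stop("need at least 3 pairs with repetition data, got ",
         length(rep_pairs))
  }
  first <- vapply(rep_pairs, function(p) {
    g <- sel[sel$pair == p & !sel$excluded, , drop = FALSE]
    sum(rowSums(g[, c("FR", "NR", "CC", "CR"), drop = FALSE]), na.rm = TRUE)
  }, numeric(1))
  repetition <- vapply(rep_pairs, function(p) {
    sum(sel$rep_sum[sel$pair == p], na.rm = TRUE)
  }, numeric(1))
  ct <- cor.test(first, repetition, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(rep_pairs),
       first = first, repetition = repetition)
}

# squared Euclidean distance matrix on (optionally z-scored) features
standardized_dist2 <- function(X, distance, standardize) {
  X <- as.matrix(X)
  if (standardize && ncol(X) > 0) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- scale(X, center = TRUE, scale = s)
  }
  if (distance == "euclidean") {
    as.matrix(dist(X))^2
  } else {
    # Gower: range-normalized mean absolute difference per feature
    rg <- apply(X, 2, function(col) diff(range(col)))
    rg[rg == 0] <- 1
    Xn <- sweep(X, 2, rg, "/")
    d <- matrix(0, nrow(X), nrow(X))
    for (j in seq_len(ncol(Xn))) {
      d <- d + abs(outer(Xn[, j], Xn[, j], "-"))
    }
    (d / ncol(Xn))^2
  }
}

# distance-based pseudo-F: among-group vs residual partition of the total
# sum of squared inter-point distances (Huygens decomposition); the
# within-group block sums go through rowsum() so a permutation costs one
# pass over the matrix, not one per group
pseudo_f_stat <- function(D2, groups) {
  n <- nrow(D2)
  gf <- factor(groups)
  a <- nlevels(gf)
  ng <- tabulate(gf)
  ss_total <- sum(D2) / (2 * n)
  M <- rowsum(D2, gf, reorder = TRUE)        # a x n row-block sums
  GG <- rowsum(t(M), gf, reorder = TRUE)     # a x a block totals
  ss_within <- sum(diag(GG) / (2 * ng))
  ss_among <- ss_total - ss_within
  df1 <- a - 1
  df2 <- n - a
  if (ss_within <= 1e-12 || df2 <= 0) {
    return(list(F = NA_real_, df1 = df1, df2 = df2, degenerate = TRUE))
  }
  list(F = (ss_among / df1) / (ss_within / df2), df1 = df1, df2 = df2,
       degenerate = FALSE)
}

#' PERMANOVA with permutations restricted within blocks
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Euclidean on z-scored features by default). The pseudo-F statistic
#' partitions the total sum of squared distances into among-group and
#' residual components; its null distribution is obtained by permuting the
#' group labels independently within each block (here: within each female
#' dyad), which respects the repeated-measures structure. The p-value is
#' `(number of permuted F >= observed F + 1) / (n_perm + 1)`.
#'
#' @param X observation-by-feature matrix or data frame.
#' @param groups group label per row (>= 2 distinct values).
#' @param blocks block label per row; `NULL` means one common block
#'   (free permutation). Blocks with a single observation contribute no
#'   permutation; all-singleton blocks are an error.
#' @param n_perm number of permutations (study default 5000).
#' @param seed RNG seed recorded in the result; the global RNG state is
#'   saved and restored around the permutation loop, so the p-value is
#'   bit-reproducible given `(seed, n_perm)` without disturbing callers.
#' @param distance `"euclidean"` or `"gower"`.
#' @param standardize z-score the feature columns before computing
#'   distances (features mix ms, kHz and counts).
#' @return A list of class `"permanova_result"`: `pseudo_F`, `df_between`,
#'   `df_within`, `p`, `n_perm`, `seed`, `degenerate`.
#' @export
permanova_restricted <- function(X, groups, blocks = NULL, n_perm = 5000,
                                 seed = 1L,
                                 distance = c("euclidean", "gower"),
                                 standardize = TRUE) {
  distance <- match.arg(distance)
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(groups))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  if (is.null(blocks)) blocks <- rep("all", nrow(X))
  blocks <- as.character(blocks)
  stopifnot(length(blocks) == nrow(X))
  block_idx <- split(seq_len(nrow(X)), blocks)
  if (all(lengths(block_idx) < 2)) {
    stop("all blocks are singletons; no permutation is possible")
  }
  D2 <- standardized_dist2(X, distance, standardize)
  obs <- pseudo_f_stat(D2, groups)
  if (obs$degenerate || !is.finite(obs$F)) {
    return(structure(list(pseudo_F = NA_real_, df_between = obs$df1,
                          df_within = obs$df2, p = 1, n_perm = n_perm,
                          seed = seed, degenerate = TRUE),
                     class = "permanova_result"))
  }
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  n_ge <- 0L
  for (b in seq_len(n_perm)) {
    perm <- groups
    for (idx in block_idx) {
      if (length(idx) > 1) perm[idx] <- perm[sample(idx)]
    }
    # restriction invariant: each block keeps its own label multiset
    stopifnot(identical(sort(perm), sort(groups)))
    fp <- pseudo_f_stat(D2, perm)
    if (!fp$degenerate && fp$F >= obs$F - 1e-12) n_ge <- n_ge + 1L
  }
  structure(list(pseudo_F = obs$F, df_between = obs$df1,
                 df_within = obs$df2, p = (n_ge + 1) / (n_perm + 1),
                 n_perm = n_perm, seed = seed, degenerate = FALSE),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: F(%d) = %.4f, p = %.4g (%d permutations, seed %s)\n",
    x$df_between, x$pseudo_F, x$p, x$n_perm, format(x$seed)))
  invisible(x)
}

#' Fisher linear discriminant analysis with loadings
#'
#' Solves the generalized eigenproblem of the between-group versus
#' within-group scatter matrices. Returns the discriminant loadings per
#' feature (scaled so projections have unit pooled within-group variance),
#' the proportion of trace captured by each discriminant (eigenvalue
#' shares, summing to 1) and the projected observations. A singular
#' within-group scatter (e.g. a duplicated feature column) is
#' ridge-regularized with a warning.
#'
#' @param X observation-by-feature matrix/data frame, more rows than
#'   columns.
#' @param groups group label per row (>= 2 groups).
#' @param ridge regularization added to the within scatter when singular,
#'   as a fraction of its mean diagonal.
#' @return A list of class `"lda_result"`: `loadings` (feature x
#'   discriminant), `trace_proportions`, `projections`, `group_means`.
#' @export
fisher_lda <- function(X, groups, ridge = 1e-8) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(groups))
  g_levels <- unique(groups)
  if (length(g_levels) < 2) stop("need at least 2 groups")
  if (nrow(X) <= ncol(X)) stop("need more observations than features")
  n <- nrow(X); p <- ncol(X); a <- length(g_levels)
  grand <- colMeans(X)
  W <- matrix(0, p, p); B <- matrix(0, p, p)
  means <- matrix(0, a, p, dimnames = list(g_levels, colnames(X)))
  for (g in g_levels) {
    idx <- which(groups == g)
    mg <- colMeans(X[idx, , drop = FALSE])
    means[g, ] <- mg
    cen <- sweep(X[idx, , drop = FALSE], 2, mg)
    W <- W + crossprod(cen)
    B <- B + length(idx) * tcrossprod(mg - grand)
  }
  if (qr(W)$rank < p) {
    warning("within-group scatter is singular; applying ridge regularization")
    W <- W + ridge * mean(diag(W)) * diag(p)
  }
  m <- min(a - 1, p)
  e <- eigen(solve(W, B))
  ord <- order(Re(e$values), decreasing = TRUE)[seq_len(m)]
  vals <- pmax(Re(e$values[ord]), 0)
  vecs <- Re(e$vectors[, ord, drop = FALSE])
  # scale each discriminant to unit pooled within-group variance
  Wcov <- W / (n - a)
  for (k in seq_len(m)) {
    s <- sqrt(drop(t(vecs[, k]) %*% Wcov %*% vecs[, k]))
    if (s > 0) vecs[, k] <- vecs[, k] / s
  }
  dimnames(vecs) <- list(colnames(X), paste0("LD", seq_len(m)))
  proj <- sweep(X, 2, grand) %*% vecs
  structure(list(loadings = vecs,
                 trace_proportions = vals / sum(vals),
                 projections = proj,
                 group_means = means),
            class = "lda_result")
}

#' Chi-square test of syllable-type usage
#'
#' Pearson chi-square (no continuity correction) on a context-by-type
#' count matrix over the merged 13-label taxonomy. All-zero rows or
#' columns are dropped with a warning before testing.
#'
#' @param counts non-negative integer matrix, contexts in rows, merged
#'   syllable types in columns.
#' @return A list of class `"chisq_result"`: `statistic`, `df`, `p`.
#' @export
chisq_type_usage <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning("dropping ", sum(zr), " all-zero row(s) and ", sum(zc),
            " all-zero column(s) before the chi-square test")
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least a 2x2 table after dropping empty margins")
  }
  ht <- suppressWarnings(chisq.test(counts, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("X^2(%d) = %.2f, p = %.4g\n", x$df, x$statistic, x$p))
  invisible(x)
}
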