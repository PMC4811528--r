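#!/usr/bin/env Rscript
# Stage 5: the multivariate layer on the synthetic syllable table from
# stages 1-3: dyad-restricted PERMANOVA of syllable parameters across
# nights and between the two social regions, Fisher LDA with loadings and
# proportion of trace, and the chi-square test of merged syllable-type
# usage between contact corners (undirected) and contact region
# (directed). The published raw syllable tables are not available, so the
# numbers here describe the synthetic session; the table *structure*
# mirrors the study's.

library(usvsong)

session_dir <- "results/session"
syl <- read.csv(file.path(session_dir, "syllables.csv"))
songs <- read.csv(file.path(session_dir, "songs_annotated.csv"))
syl <- merge(syl, songs[, c("song_id", "region", "encounter")],
             by = "song_id")

feat_cols <- c("sylDur", "staFreq", "slope", "minFreq", "freqBand",
               "freqCOG", "jumps", "turns")

# a desk-sized subsample keeps the 5000-permutation tests in seconds
set.seed(2016)
if (nrow(syl) > 800) syl <- syl[sort(sample(nrow(syl), 800)), ]

cat("PERMANOVA of syllable parameters across nights (dyad-restricted):\n")
pn <- permanova_restricted(syl[, feat_cols], groups = syl$night,
                           blocks = syl$pair, n_perm = 5000, seed = 2016)
print(pn)

social <- syl[syl$region %in% c("CC", "CR", "CW"), ]
social$context <- ifelse(social$region == "CC", "undirected", "directed")
cat("\nPERMANOVA contact corners vs contact region:\n")
ps <- permanova_restricted(social[, feat_cols], groups = social$context,
                           blocks = social$pair, n_perm = 5000, seed = 2016)
print(ps)

cat("\nFisher LDA of syllable parameters by night:\n")
ld <- fisher_lda(syl[, feat_cols], syl$night)
loadings_tab <- round(ld$loadings, 3)
print(loadings_tab)
cat("proportion of trace:",
    paste(sprintf("%.3f", ld$trace_proportions), collapse = " "), "\n")

cat("\nchi-square of merged type usage, corners vs contact region:\n")
type_tab <- table(social$context, social$type_merged)
cx <- chisq_type_usage(as.matrix(type_tab))
print(cx)

dir.create("results", showWarnings = FALSE)
write.csv(as.data.frame(loadings_tab), "results/lda_loadings.csv")
write.csv(as.data.frame.matrix(type_tab), "results/type_usage.csv")
res_tab <- data.frame(
  test = c("permanova_nights", "permanova_social", "chisq_type_usage"),
  statistic = c(pn$pseudo_F, ps$pseudo_F, cx$statistic),
  df = c(pn$df_between, ps$df_between, cx$df),
  p = c(pn$p, ps$p, cx$p))
write.csv(res_tab, "results/multivariate_statistics.csv", row.names = FALSE)
cat("wrote results/{lda_loadings,type_usage,multivariate_statistics}.csv\n")
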