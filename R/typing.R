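#' Syllable-type labels
#'
#' The taxonomy holds 14 labels: three Simple types (SFL flat, SUP up,
#' SDN down), three Turn types (TUD up-down, TDU down-up, TRS multi),
#' seven Jump types (JEU/JED/JLU/JLD single jumps split by early/late
#' position and direction, J2UD/J2DU two-jump patterns, JPS multi-jump),
#' and the low-frequency type LFS for syllables whose mean frequency falls
#' below the 45 kHz split. For count statistics the two two-jump subtypes
#' merge into the single display label JMP, giving the 13-label display
#' taxonomy.
#'
#' @format Character vectors.
#' @name syllable_type_labels
NULL

#' @rdname syllable_type_labels
#' @export
SYLLABLE_TYPES <- c("SFL", "SUP", "SDN", "TUD", "TDU", "TRS",
                    "JEU", "JED", "JLU", "JLD", "J2UD", "J2DU", "JPS", "LFS")

#' @rdname syllable_type_labels
#' @export
SYLLABLE_TYPES_MERGED <- c("SFL", "SUP", "SDN", "TUD", "TDU", "TRS",
                           "JEU", "JED", "JLU", "JLD", "JMP", "JPS", "LFS")

#' Typing configuration
#'
#' @param split_khz low/high frequency split on the syllable's centre of
#'   gravity (kHz); syllables below it are low-frequency (LFS).
#' @param flat_threshold absolute slope (kHz/ms) below which a simple
#'   syllable counts as flat.
#' @param early_boundary jump-position fraction separating "early" from
#'   "late" single jumps.
#' @return A list of class `"typing_config"`.
#' @export
typing_config <- function(split_khz = 45, flat_threshold = 0.05,
                          early_boundary = 0.5) {
  stopifnot(split_khz > 0, flat_threshold >= 0,
            early_boundary > 0, early_boundary < 1)
  structure(list(split_khz = split_khz, flat_threshold = flat_threshold,
                 early_boundary = early_boundary),
            class = "typing_config")
}

#' Classify a syllable into the 14-type taxonomy
#'
#' Rule-based decision tree over the syllable parameters, in priority
#' order: (1) a centre of gravity below the 45 kHz split is low-frequency
#' (LFS) regardless of modulation; (2) syllables with frequency jumps are
#' Jump types — one jump splits by position (early/late relative to
#' `early_boundary`) and direction, two jumps by their direction pattern
#' (J2UD up-then-down, J2DU down-then-up; other two-jump patterns fall to
#' the closer archetype by first-jump direction), three or more jumps are
#' JPS; (3) jump-free syllables with turning points are Turn types — one
#' turn splits by pattern (TUD/TDU), two or more are TRS; (4) the rest are
#' Simple: flat (SFL) when the absolute slope is below `flat_threshold`,
#' otherwise up (SUP) or down (SDN) by slope sign. The tree is total:
#' every feature vector receives exactly one label.
#'
#' @param feat a `"syllable_features"` object from
#'   [compute_syllable_features()].
#' @param cfg a [typing_config()].
#' @return A single label from `SYLLABLE_TYPES`.
#' @export
classify_syllable <- function(feat, cfg = typing_config()) {
  if (feat$freqCOG < cfg$split_khz) return("LFS")
  if (feat$jumps >= 3) return("JPS")
  if (feat$jumps == 2) {
    return(if (feat$jump_list$direction[1] == "up") "J2UD" else "J2DU")
  }
  if (feat$jumps == 1) {
    early <- feat$jump_list$pos_fraction[1] < cfg$early_boundary
    up <- feat$jump_list$direction[1] == "up"
    return(if (early) {
      if (up) "JEU" else "JED"
    } else {
      if (up) "JLU" else "JLD"
    })
  }
  if (feat$turns >= 2) return("TRS")
  if (feat$turns == 1) {
    return(if (feat$turn_list$pattern[1] == "up-down") "TUD" else "TDU")
  }
  if (abs(feat$slope) < cfg$flat_threshold) return("SFL")
  if (feat$slope > 0) "SUP" else "SDN"
}

#' Merge rare jump subtypes for count statistics
#'
#' Chi-square tests cannot handle rare categories, so the two two-jump
#' subtypes (J2UD, J2DU) are combined into the single Two-Jump category
#' JMP; all other labels pass through unchanged. Totals are conserved.
#'
#' @param type_counts named numeric vector of non-negative per-type counts.
#' @return A named vector over the merged (display) taxonomy.
#' @export
merge_types_for_counts <- function(type_counts) {
  stopifnot(all(type_counts >= 0))
  labs <- names(type_counts)
  if (is.null(labs)) stop("type_counts must be a named vector")
  merged_names <- ifelse(labs %in% c("J2UD", "J2DU"), "JMP", labs)
  out <- tapply(as.numeric(type_counts), merged_names, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  keep_order <- intersect(SYLLABLE_TYPES_MERGED, names(res))
  res[c(keep_order, setdiff(names(res), keep_order))]
}
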