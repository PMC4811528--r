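---
title: "Methods: segmenting, typing and testing mouse USV songs"
author: "usvsong"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting, typing and testing mouse USV songs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvsong)
```

## The problem

Female house mice exchange ultrasonic vocalizations (USVs) — "songs" of
tonal syllables between roughly 30 and 110 kHz — and do so differently
depending on social context: whether they address a present partner
through a contact window (directed communication) or broadcast near
scent-marked corners with no partner in sight (undirected
communication). usvsong reconstructs the complete analysis chain of such
an encounter experiment: from spectrogram peak contours to segmented
songs, syllable parameters, a rule-based type taxonomy, behavioural
context labels, and the study-level statistics. The raw per-syllable
recordings of the original experiment are not publicly deposited; what
is published is the per-pair song count table, which ships here as a
fixture, together with a synthetic generator that produces recordings
with known ground truth for every other stage.

## Contours and the recording front end

Recordings are modelled after a 500 kHz, 16-bit whistle-triggered setup.
`extract_contour()` computes a short-time Fourier transform (256-sample
Hann window, 85 % overlap, zero-padded to 1024 points so the bin width is
0.488 kHz, i.e. at most the 0.49 kHz target) and keeps the in-band
(20–250 kHz) peak per frame — the "brightest pixel per FFT column" that
defines a peak-frequency contour. Two reconstructions deserve emphasis,
because the original workflow performed them with hardware or by hand:

* **Noise floor.** A frame is accepted only when its peak exceeds the
  median in-band level by 20 dB (configurable). The original extraction
  relied on hardware triggering and manual marking, for which no
  quantitative criterion is documented; the floor makes silence produce
  an empty trace and synthetic tones produce clean contours.
* **Manual correction.** The visual check-and-correct pass is replaced
  by an optional 3-frame running median on the contour, off by default.

`emulate_trigger()` reconstructs the recorder rules exactly as stated:
sounds in the 20–250 kHz band lasting at least 10 ms trigger an event
that opens 200 ms early and closes 1 s after the last whistle; whistles
closer than the 1 s hold merge. One addition is forced by causality: a
whistle arriving more than 1 s but less than 1.2 s after the previous
one would open a pre-trigger window inside the already-closed event, so
event starts are clipped at the previous event's end — the recorder
cannot rewind. `dedup_events()` resolves double recordings by the two
window-side microphones: of any temporally overlapping cross-channel
pair the longer event survives, with ties going to the lower channel id
so the operation is deterministic and idempotent.

## Segmentation

Syllables and songs are defined purely by silent gaps: a new syllable
starts where the inter-frame gap exceeds 10 ms, a new song where the
offset-to-onset gap exceeds 500 ms. Both comparisons are strictly
greater-than — the boundary case (a gap of exactly 10 or 500 ms) does
not split. The source description does not state the strictness; the
strict convention was chosen because it gives a deterministic boundary
and matches the phrasing of intervals *separating* units. Gaps are
measured offset-to-onset, not onset-to-onset. Segmentation is
conservative by construction (every frame lands in exactly one
syllable, every syllable in exactly one song) and is property-tested
against a brute-force gap scan.

## Syllable and song parameters

Per syllable: duration `sylDur` (ms); start frequency `staFreq` (first
frame); minimum frequency `minFreq`; bandwidth `freqBand` (max − min);
centre of gravity `freqCOG`; overall `slope` (kHz/ms); and the counts of
frequency `jumps` and `turns`. Per song: duration `soDur` (first onset
to last offset, excluding trailing silence), syllable count, and the
syllable rate, which is undefined for one-syllable songs — those are
excluded from any rate analysis, mirroring the study's RateData rule.

Choices where the source is silent, all configurable:

* **Jump threshold, 10 kHz.** "Sudden" frequency jumps are never
  quantified; 10 kHz between consecutive frames is far above the
  within-syllable frame-to-frame modulation of mouse USV (sub-kHz at
  these frame rates) and far below the 15–20 kHz jumps the taxonomy is
  about.
* **Turn detection.** A turning point is a sign change of the contour
  slope. Raw peak contours jitter by a bin width, so the contour is
  smoothed (5-frame moving average), cut at jump discontinuities (a jump
  is not a reversal), and a reversal counts only when both flanking
  monotone segments reach 0.1 kHz/ms and last 1 ms.
* **Slope.** Global least-squares fit of frequency on time, robust to
  jitter; an endpoint mode is available behind `slope_mode`.
* **freqCOG.** Amplitude-weighted mean frequency with linear-amplitude
  weights, falling back to the plain mean when amplitudes are absent.
  Whether the original centre of gravity was amplitude-weighted is not
  documented; the weighted form matches the spectrographic reading of
  "centre of gravity", and for the constant-amplitude synthetic
  contours the two coincide.

## The 14-type taxonomy

Classification is a total decision tree in fixed priority order:

1. `freqCOG` below 45 kHz → **LFS** (low-frequency syllable). The split
   value reflects the observed dichotomy of mean syllable frequency in
   nights with direct contact.
2. Any jumps → Jump types: one jump splits by position (early/late at
   50 % of duration) × direction into **JEU/JED/JLU/JLD**; two jumps by
   pattern into **J2UD/J2DU**; three or more → **JPS**.
3. No jumps, any turns → **TUD/TDU** by pattern, ≥ 2 turns → **TRS**.
4. Otherwise Simple: |slope| < 0.05 kHz/ms → **SFL**, else **SUP/SDN**.

Jumps outrank turns for mixed syllables, following the
jump/turn/simple hierarchy of the source taxonomy. The seven jump types
are realized as four single-jump types, two two-jump subtypes and the
multi-jump type; for count statistics `merge_types_for_counts()` folds
J2UD and J2DU into the single **JMP** display label, giving the 13-label
taxonomy used in the chi-square tests. The early/late boundary (50 %)
and the flat-slope threshold (0.05 kHz/ms) are reconstructions — the
precise discriminating definitions live in the authors' earlier work,
which is also not deposited — and both are exposed in
`typing_config()`.

## Context annotation

Occupancy tracks are half-open labelled intervals per animal, the
programmatic form of manual video scoring over six regions (food FR,
nest NR, contact region CR, contact window CW, contact corners CC, male
bedding MB). A song's region is read at its *onset* — songs can straddle
region changes and the onset is the deterministic anchor. Contact-window
songs additionally receive an encounter type from both animals'
positions: `face` (both at CW), `non_face` (partner elsewhere in CR),
`solitary` (partner elsewhere). For count tables CW rolls up into CR,
because the published count table has no CW column, while the encounter
analysis keeps the sub-zone.

## Statistics

* **Count summaries** (`summarize_counts()`): per-pair night totals or
  per-region values, mean ± sample sd. Two policies are explicit flags
  because the published summary cells require them: night totals add
  the male-bedding footnote songs (`include_mb`), reconciling the
  night-4 mean; per-region summaries drop pairs with zero songs in that
  region-night (`drop_zero`), reconciling the contact-corner cell's
  mean, sd and n exactly. Excluded pair-nights (the pair that opened
  the contact window) never contribute.
* **Wilcoxon post-hocs** (`pairwise_wilcoxon()`): signed-rank for
  paired, rank-sum otherwise, through `stats::wilcox.test`, with
  Bonferroni verdicts at `alpha/m` (0.05/6 = 0.0083 for the six night
  pairs, 0.05/3 = 0.016 for the three encounter pairs).
* **Trial consistency** (`trial_consistency()`): Pearson correlation of
  first-trial vs repetition totals over nights 1–3 only, since
  repetitions followed the three-night protocol.
* **Restricted-permutation PERMANOVA** (`permanova_restricted()`): the
  distance-based pseudo-F with group labels permuted independently
  *within each dyad*, respecting the repeated-measures design; p =
  (#{F\* ≥ F} + 1)/(n\_perm + 1) with 5000 permutations by default. The
  distance is Euclidean on z-scored features — the method's metric is
  not documented, and the features mix ms, kHz and counts, so
  standardization is the defensible default (a Gower option exists).
  Every permutation draw is asserted to preserve the within-block label
  multiset, and the p-value is bit-reproducible given `(seed, n_perm)`.
  For a univariate Euclidean problem the pseudo-F reduces to the
  classical one-way ANOVA F, which the tests verify to 1e-10, alongside
  a 500-simulation null calibration of the type-I error at α = 0.05.
* **Fisher LDA** (`fisher_lda()`): the within/between scatter
  eigenproblem, loadings scaled to unit pooled within-group variance
  (matching the convention of standard LDA implementations up to sign),
  trace proportions as eigenvalue shares. Singular within-scatter is
  ridge-regularized (1e-8 of the mean diagonal) with a warning.
* **Chi-square of type usage** (`chisq_type_usage()`): Pearson test
  without continuity correction on the merged 13-type table; all-zero
  margins are dropped with a warning. Two regions × 13 types gives the
  12 degrees of freedom of the published statistic.

Linear-mixed-model fitting of count data (night × region effects with
dyad as random factor) is deliberately out of scope; the count table is
exported in the long format such models consume.

## The synthetic generator

The generator covers three levels, all seeded and deterministic.

**Syllables.** One archetype per type: piecewise-linear contours whose
discriminating features sit at least three-fold from every decision
boundary (jumps 15–20 kHz vs the 10 kHz threshold, segment slopes
0.5–0.9 kHz/ms vs 0.05/0.1 thresholds, LFS base 35 kHz vs the 45 kHz
split). Noiseless rendering therefore classifies back to its own label —
verified for all 14 types over 50 replicates each — so round-trip
failures indicate pipeline defects, not boundary flakiness.

**Sessions.** Song counts are Poisson per pair × night × region with a
log-normal pair effect (log-sd 1), emulating the up-to-100-fold spread
between dyads the study reports. Baseline region intensities follow the
observed first-night means (FR 4, NR 4, CC 18, CR 3, CW 1 songs/night);
night factors encode the contact-window novelty surge (×4.5 in night 2,
the observed night-2/night-1 ratio) and a familiarization decay of 0.5
per later night. Directed songs (CR/CW) draw syllable types from a
mixture with a 40 % low-frequency share; undirected songs (CC and the
non-social regions) draw the complex high-frequency mixture — the
directed/undirected contrast the study describes. Inter-syllable gaps
are uniform on 15–400 ms and inter-song gaps exceed 600 ms, so
segmentation is exactly recoverable. Occupancy intervals co-locate each
song with its ground-truth region, and contact-window songs place the
partner according to a 60/20/20 solitary/non-face/face mixture.

**Count tables.** `simulate_count_table()` draws the counts alone, plus
repetition trials whose log pair effects correlate at 0.95 with the
first trial.

What the generator does *not* emulate: harmonics and amplitude
envelopes, overlapping vocalizations, microphone cross-talk beyond the
explicit dedup scenario, region-transition ambiguity during songs, and
any acoustic propagation. Passing round-trip tests therefore certify
the pipeline's internal consistency on clean contours — they do not
certify extraction accuracy on real, noisy spectrograms beyond the
tone/chirp bounds tested explicitly.

## Numerical and scale choices

Problem sizes were chosen so the complete workflow re-runs in minutes
on one core: the analysis scripts simulate 4 dyads × 3 nights (about a
thousand songs), the multivariate stage subsamples to 800 syllables for
its 5000-permutation tests, and the null-calibration test uses 500
simulations of 24 observations with 199 permutations. The pseudo-F
computation aggregates within-group distance blocks with `rowsum()`,
so one permutation costs a single pass over the distance matrix.
Degenerate inputs are handled by convention rather than error where the
study's data could plausibly produce them: identical rows across groups
give a flagged undefined F with p = 1; identical paired samples give
p = 1 in the Wilcoxon wrapper; empty traces segment to empty lists.

## Known limitations

* The published night-2 summary cell prints 119.20 while the count
  table's column computes to 119.17; the package reproduces the table,
  so `summarize_counts()` returns 119.17 for that cell.
* The jump/turn thresholds, early/late boundary and noise floor are
  reconstructions of undocumented values; conclusions that hinge on
  them should be checked across the configurable ranges.
* Numeric reproduction of the study's syllable-level parameter tables
  is impossible without the raw recordings; the pipeline produces
  tables of identical structure from synthetic data instead.
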