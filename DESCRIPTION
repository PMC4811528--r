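Package: usvsong
Title: Context-Dependent Analysis of Mouse Ultrasonic Vocalization Songs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ultrasonic vocalizations (USVs) of house
    mice recorded during staged female-female encounters. Extracts
    peak-frequency contours from spectrograms, emulates whistle-triggered
    recording and cross-channel deduplication, segments contours into
    syllables and songs by temporal gaps, computes syllable and song
    parameters (duration, frequencies, slope, frequency jumps and turning
    points), assigns each syllable to a 14-type rule-based taxonomy with a
    45 kHz low-frequency split, annotates songs with arena regions and
    encounter types from occupancy scoring, and implements the study-level
    statistics: count summaries with documented exclusions, Wilcoxon
    post-hoc tests with Bonferroni correction, trial-consistency
    correlation, PERMANOVA with permutations restricted within dyads,
    Fisher linear discriminant analysis, and chi-square tests of syllable
    type usage. Ships a synthetic-data generator with known ground truth
    and the published per-pair per-night song count table as a fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan,
    jsonlite
Config/testthat/edition: 3
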