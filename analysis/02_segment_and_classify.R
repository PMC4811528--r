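#!/usr/bin/env Rscript
# Stage 2: read the simulated contour export, segment it into syllables
# (gap > 10 ms) and songs (gap > 500 ms), compute the syllable and song
# parameters and assign each syllable its type. Event identifiers encode
# dyad and night (SP_xx_n<night>_s<song>), which we parse back out so the
# statistics stages can group by dyad.

library(usvsong)

session_dir <- "results/session"
events <- read_contour_table(file.path(session_dir, "contours.csv"))

# tag events with pair and night parsed from the generator's identifiers
for (i in seq_along(events)) {
  parts <- strsplit(events[[i]]$event_id, "_")[[1]]
  events[[i]]$pair <- paste(parts[1], parts[2], sep = "_")
  events[[i]]$night <- as.integer(sub("n", "", parts[3]))
}

tabs <- featurize_events(events, pipeline_config())
write.csv(tabs$syllable_table, file.path(session_dir, "syllables.csv"),
          row.names = FALSE)
write.csv(tabs$song_table, file.path(session_dir, "songs.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(session_dir, "ground_truth.csv"))
cat(sprintf("segmented %d songs / %d syllables (ground truth: %d / %d)\n",
            nrow(tabs$song_table), nrow(tabs$syllable_table),
            nrow(truth), sum(truth$n_syls)))
tt <- unlist(strsplit(truth$types[order(truth$event_id)], ";"))
st <- tabs$syllable_table[order(tabs$syllable_table$song_id,
                                tabs$syllable_table$syl_index), ]
cat(sprintf("syllable types recovered: %.1f%%\n", 100 * mean(st$type == tt)))
print(table(st$type_merged))
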