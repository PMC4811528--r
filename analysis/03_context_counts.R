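#!/usr/bin/env Rscript
# Stage 3: annotate every song with the arena region of its emitter and,
# for contact-window songs, the encounter type; then tabulate songs per
# dyad, night and region (contact-window songs rolling up into the
# contact region, as in the published count table).

library(usvsong)

session_dir <- "results/session"
songs <- read.csv(file.path(session_dir, "songs.csv"))
tracks <- read_occupancy_table(file.path(session_dir, "occupancy.csv"))

songs$region <- NA_character_
songs$encounter <- NA_character_
for (i in seq_len(nrow(songs))) {
  key <- paste0(songs$pair[i], "_n", songs$night[i])
  em <- tracks[[paste0(key, "_emitter")]]
  pa <- tracks[[paste0(key, "_partner")]]
  songs$region[i] <- locate_song(list(onset = songs$onset[i]), em)
  songs$encounter[i] <- classify_encounter(list(onset = songs$onset[i]),
                                           em, pa)
}
write.csv(songs, file.path(session_dir, "songs_annotated.csv"),
          row.names = FALSE)

counts <- tabulate_pair_night_counts(songs[, c("pair", "night", "region")])
write.csv(counts, file.path(session_dir, "counts.csv"), row.names = FALSE)

truth <- read.csv(file.path(session_dir, "ground_truth.csv"))
m <- merge(truth, songs, by = "event_id")
cat(sprintf("region recovery vs ground truth: %.1f%%\n",
            100 * mean(m$region.x == m$region.y)))
cat("songs per night (all dyads):\n")
print(tapply(rowSums(counts[, c("FR", "NR", "CC", "CR")]), counts$night, sum))
cat("encounter types at the contact window:\n")
print(table(songs$encounter[songs$encounter != "not_applicable"]))
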