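#!/usr/bin/env Rscript
# Stage 1: generate a synthetic encounter experiment with known ground
# truth. Four female dyads recorded over three nights; contour frames,
# occupancy scoring and the generating labels are written as CSV for the
# downstream stages. The session is deliberately desk-sized so the whole
# workflow reruns in seconds; the generator's night/region/type structure
# follows the defaults of scenario_config().

library(usvsong)

out_dir <- "results/session"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- scenario_config(n_pairs = 4, nights = 3,
                       short_protocol_pairs = integer(0),
                       pair_sd = 0.7, seed = 2016)
sim <- simulate_session(cfg)

write_contour_table(sim$events, file.path(out_dir, "contours.csv"))

occ <- do.call(rbind, lapply(names(sim$occupancy), function(key) {
  rbind(
    data.frame(animal_id = paste0(key, "_emitter"),
               sim$occupancy[[key]]$emitter[, c("start_ms", "end_ms", "region")]),
    data.frame(animal_id = paste0(key, "_partner"),
               sim$occupancy[[key]]$partner[, c("start_ms", "end_ms", "region")]))
}))
write.csv(occ, file.path(out_dir, "occupancy.csv"), row.names = FALSE)
write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
          row.names = FALSE)

cat(sprintf("simulated %d songs (%d syllables) across %d dyads x %d nights\n",
            nrow(sim$truth), sum(sim$truth$n_syls), cfg$n_pairs, cfg$nights))
cat(sprintf("wrote %s/{contours,occupancy,ground_truth}.csv\n", out_dir))
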