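#' Arena region labels
#'
#' Closed vocabulary of the scored arena regions: FR food region, NR nest
#' region, CR contact region, CW contact window (a sub-zone of the contact
#' region scored separately for encounter analysis), CC contact corners,
#' MB male bedding.
#'
#' @export
REGION_LABELS <- c("FR", "NR", "CR", "CW", "CC", "MB")

#' Encounter-type labels at the contact window
#'
#' `solitary`: one individual alone at the contact window; `non_face`: one
#' at the window, the other elsewhere in the contact region; `face`: both
#' individuals at the window.
#'
#' @export
ENCOUNTER_LABELS <- c("solitary", "non_face", "face")

#' Build an occupancy track
#'
#' Per-animal time intervals labelled with arena regions, the programmatic
#' form of manual video scoring. Intervals are half-open `[start, end)` and
#' must not overlap within an animal.
#'
#' @param animal_id identifier.
#' @param start_ms,end_ms interval bounds in ms.
#' @param region labels from `REGION_LABELS`.
#' @return A data frame of class `"occupancy_track"`.
#' @export
occupancy_track <- function(animal_id, start_ms, end_ms, region) {
  stopifnot(length(start_ms) == length(end_ms),
            length(region) == length(start_ms))
  if (!all(region %in% REGION_LABELS)) {
    stop("unknown region label(s): ",
         paste(setdiff(region, REGION_LABELS), collapse = ", "))
  }
  if (any(end_ms <= start_ms)) stop("occupancy intervals must have end > start")
  o <- order(start_ms)
  df <- data.frame(animal_id = animal_id, start_ms = start_ms[o],
                   end_ms = end_ms[o], region = region[o],
                   stringsAsFactors = FALSE)
  if (nrow(df) > 1 && any(df$start_ms[-1] < df$end_ms[-nrow(df)])) {
    stop("occupancy intervals overlap for animal ", animal_id[1])
  }
  class(df) <- c("occupancy_track", "data.frame")
  df
}

#' Read an occupancy CSV
#'
#' Header `animal_id,start_ms,end_ms,region`; returns one
#' [occupancy_track()] per animal.
#'
#' @param path file path.
#' @return Named list of occupancy tracks.
#' @export
read_occupancy_table <- function(path) {
  if (!file.exists(path)) stop("occupancy table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "start_ms", "end_ms", "region")
  if (!all(need %in% names(df))) {
    stop("occupancy table is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  lapply(split(df, df$animal_id), function(g) {
    occupancy_track(g$animal_id, g$start_ms, g$end_ms, g$region)
  })
}

# region of an animal at one time point under the half-open convention;
# NA when uncovered
region_at <- function(track, t) {
  hit <- which(track$start_ms <= t & t < track$end_ms)
  if (length(hit) == 0) return(NA_character_)
  track$region[hit[1]]
}

#' Locate the region a song was emitted in
#'
#' The song's region is the region of the occupancy interval containing its
#' onset (songs can straddle region changes; the onset is the deterministic
#' anchor). Intervals are half-open, so an onset exactly on a boundary
#' belongs to the later interval.
#'
#' @param song a `"usv_song"` (or any list with an `onset` in ms).
#' @param track the emitter's [occupancy_track()].
#' @return A region label.
#' @export
locate_song <- function(song, track) {
  r <- region_at(track, song$onset)
  if (is.na(r)) {
    stop("song onset at ", song$onset,
         " ms is not covered by the occupancy track")
  }
  r
}

#' Classify the encounter type of a contact-window song
#'
#' Applicable only when the emitter is at the contact window (CW) at song
#' onset: the encounter is `face` when the partner is also at CW,
#' `non_face` when the partner is elsewhere in the contact region (CR),
#' and `solitary` otherwise. For songs whose emitter is not at CW the
#' marker `"not_applicable"` is returned.
#'
#' @param song a `"usv_song"`.
#' @param emitter_track,partner_track occupancy tracks of the two animals.
#' @return One of `ENCOUNTER_LABELS` or `"not_applicable"`.
#' @export
classify_encounter <- function(song, emitter_track, partner_track) {
  em <- region_at(emitter_track, song$onset)
  pa <- region_at(partner_track, song$onset)
  if (is.na(em) || is.na(pa)) {
    stop("song onset at ", song$onset, " ms not covered by both tracks")
  }
  if (em != "CW") return("not_applicable")
  if (pa == "CW") "face" else if (pa == "CR") "non_face" else "solitary"
}

#' Tabulate song counts per pair, night and region
#'
#' Aggregates labelled songs into the per-pair per-night per-region count
#' table that anchors the count statistics. Contact-window songs roll up
#' into the contact region by default (the published count table carries
#' no CW column; the encounter analysis keeps CW separate). Exclusion
#' flags from `metadata` mark pair-nights whose counts must be dropped
#' from summaries.
#'
#' @param songs data frame with columns `pair`, `night`, `region` (one row
#'   per song).
#' @param metadata optional data frame with columns `pair`, `night`,
#'   `reason` flagging excluded pair-nights.
#' @param roll_up_cw merge CW counts into CR (default `TRUE`).
#' @return A data frame of class `"pair_night_counts"`: one row per
#'   pair-night with columns `pair`, `night`, one count column per region
#'   (`FR`, `NR`, `CC`, `CR`, `MB`), `excluded` and `reason`.
#' @export
tabulate_pair_night_counts <- function(songs, metadata = NULL,
                                       roll_up_cw = TRUE) {
  regions <- c("FR", "NR", "CC", "CR", "MB")
  if (nrow(songs) == 0) {
    out <- data.frame(pair = character(), night = integer())
    for (r in regions) out[[r]] <- numeric()
    out$excluded <- logical(); out$reason <- character()
    class(out) <- c("pair_night_counts", "data.frame")
    return(out)
  }
  if (any(is.na(songs$pair)) || any(is.na(songs$night))) {
    stop("every song needs a pair and night label")
  }
  if (!all(songs$region %in% REGION_LABELS)) {
    stop("unknown region label(s) in songs: ",
         paste(setdiff(songs$region, REGION_LABELS), collapse = ", "))
  }
  reg <- songs$region
  if (roll_up_cw) reg[reg == "CW"] <- "CR"
  tab <- table(pair = songs$pair, night = songs$night,
               region = factor(reg, levels = regions))
  grid <- expand.grid(pair = dimnames(tab)$pair,
                      night = as.integer(dimnames(tab)$night),
                      stringsAsFactors = FALSE)
  out <- grid
  for (r in regions) {
    out[[r]] <- mapply(function(p, n) tab[p, as.character(n), r],
                       grid$pair, grid$night)
  }
  out$excluded <- FALSE
  out$reason <- NA_character_
  if (!is.null(metadata) && nrow(metadata) > 0) {
    for (i in seq_len(nrow(metadata))) {
      hit <- out$pair == metadata$pair[i] & out$night == metadata$night[i]
      out$excluded[hit] <- TRUE
      out$reason[hit] <- metadata$reason[i]
    }
  }
  out <- out[order(out$pair, out$night), ]
  rownames(out) <- NULL
  class(out) <- c("pair_night_counts", "data.frame")
  out
}
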