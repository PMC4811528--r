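#' Syllable archetypes for the 14-type taxonomy
#'
#' One generative template per syllable type: a piecewise-linear frequency
#' contour specified by a base frequency, slope segments, and jump
#' positions/magnitudes. Parameters are chosen so that every
#' type-discriminating feature sits at least three-fold away from the
#' classifier's decision boundaries (jump magnitudes 15-20 kHz against a
#' 10 kHz threshold, segment slopes 0.5-0.9 kHz/ms against the 0.05 flat
#' and 0.1 turn-slope thresholds, low-frequency base 35 kHz against the
#' 45 kHz split), so a noiseless rendering classifies back to its own
#' label.
#'
#' @return Named list of archetype specs (class `"syllable_archetype"`),
#'   one per label in `SYLLABLE_TYPES`.
#' @export
syllable_archetypes <- function() {
  arch <- function(label, dur, f0, segments, jumps = NULL, jitter = 0) {
    structure(list(label = label, dur_ms = dur, f0 = f0,
                   segments = segments,
                   jumps = if (is.null(jumps))
                     data.frame(pos = numeric(0), delta = numeric(0))
                   else jumps,
                   jitter_sd = jitter),
              class = "syllable_archetype")
  }
  seg <- function(frac, slope) data.frame(frac = frac, slope = slope)
  jmp <- function(pos, delta) data.frame(pos = pos, delta = delta)
  flat <- seg(1, 0)
  list(
    SFL = arch("SFL", 40, 75, flat),
    SUP = arch("SUP", 40, 65, seg(1, 0.5)),
    SDN = arch("SDN", 40, 85, seg(1, -0.5)),
    TUD = arch("TUD", 40, 65, seg(c(0.5, 0.5), c(0.8, -0.8))),
    TDU = arch("TDU", 40, 82, seg(c(0.5, 0.5), c(-0.8, 0.8))),
    TRS = arch("TRS", 45, 68, seg(rep(1 / 3, 3), c(0.9, -0.9, 0.9))),
    JEU = arch("JEU", 40, 65, flat, jmp(0.25, 20)),
    JED = arch("JED", 40, 85, flat, jmp(0.25, -20)),
    JLU = arch("JLU", 40, 65, flat, jmp(0.75, 20)),
    JLD = arch("JLD", 40, 85, flat, jmp(0.75, -20)),
    J2UD = arch("J2UD", 40, 65, flat, jmp(c(1 / 3, 2 / 3), c(20, -20))),
    J2DU = arch("J2DU", 40, 85, flat, jmp(c(1 / 3, 2 / 3), c(-20, 20))),
    JPS = arch("JPS", 48, 60, flat, jmp(c(0.25, 0.5, 0.75), c(15, 15, -15))),
    LFS = arch("LFS", 30, 35, seg(1, -0.2))
  )
}

#' Render a syllable archetype as a contour trace
#'
#' Evaluates the archetype's piecewise-linear contour on a regular frame
#' grid, applies the jump offsets between the straddling frames, and adds
#' Gaussian frequency jitter. Uses the current R RNG, so wrapping the call
#' in `set.seed()` makes it reproducible.
#'
#' @param arch an archetype from [syllable_archetypes()].
#' @param frame_step_ms frame spacing in ms (defaults to the STFT hop of
#'   the default [spectro_config()], about 0.076 ms).
#' @param jitter_sd override of the archetype's frequency jitter sd (kHz).
#' @param t0 onset time of the rendered syllable, ms.
#' @param amp_db constant frame amplitude stamped on the trace.
#' @param channel_id,event_id identifiers for the trace.
#' @return A [contour_trace()].
#' @export
render_syllable <- function(arch, frame_step_ms = NULL, jitter_sd = NULL,
                            t0 = 0, amp_db = 60, channel_id = 1L,
                            event_id = "syn") {
  if (is.null(frame_step_ms)) {
    cfg <- spectro_config()
    frame_step_ms <- round((1 - cfg$overlap) * cfg$fft_len) /
      cfg$sample_rate * 1000
  }
  if (is.null(jitter_sd)) jitter_sd <- arch$jitter_sd
  tt <- seq(0, arch$dur_ms, by = frame_step_ms)
  if (length(tt) < 2) stop("syllable duration shorter than 2 frames")
  # integrate the slope segments
  seg_end <- cumsum(arch$segments$frac) * arch$dur_ms
  seg_start <- c(0, head(seg_end, -1))
  f_at_start <- arch$f0 +
    cumsum(c(0, head(arch$segments$slope * (seg_end - seg_start), -1)))
  ff <- vapply(tt, function(t) {
    k <- max(1, which(t >= seg_start - 1e-9)[sum(t >= seg_start - 1e-9)])
    f_at_start[k] + arch$segments$slope[k] * (t - seg_start[k])
  }, numeric(1))
  for (j in seq_len(nrow(arch$jumps))) {
    ff <- ff + ifelse(tt > arch$jumps$pos[j] * arch$dur_ms, arch$jumps$delta[j], 0)
  }
  if (jitter_sd > 0) ff <- ff + rnorm(length(ff), 0, jitter_sd)
  contour_trace(t0 + tt, pmax(ff, 1e-6), rep(amp_db, length(tt)),
                channel_id = channel_id, event_id = event_id,
                validate = FALSE)
}

#' Scenario configuration for session and count-table simulation
#'
#' Defaults emulate the structure of the encounter experiment: 12 female
#' dyads, four nights (the first half of the pairs stop after night 3,
#' matching the two experimental subsets), per-region baseline song
#' intensities close to the observed first-night means (FR 4, NR 4,
#' CC 18, CR 3, CW 1 songs/night), a strong novelty surge when the
#' contact window opens in night 2 (multiplier 4.5, the observed
#' night-2/night-1 ratio) decaying by about half per subsequent night
#' (familiarization, decay 0.5), and a log-normal pair effect (log-sd 1)
#' reproducing the up-to-100-fold spread between dyads. Directed songs
#' (contact region and window) draw syllable types with a high
#' low-frequency share; undirected songs (corners and the non-social
#' regions) draw the complex high-frequency mixture.
#'
#' @param n_pairs number of dyads.
#' @param nights number of recording nights.
#' @param short_protocol_pairs indices of pairs that stop one night early
#'   (the three-night subset).
#' @param intensity named per-region mean song counts per night at
#'   baseline.
#' @param pair_sd sd of the log-normal pair effect (log scale).
#' @param night2_mult multiplicative novelty surge in night 2.
#' @param decay per-night familiarization decay after night 2, in (0, 1].
#' @param mixture_directed,mixture_undirected named syllable-type
#'   probabilities for directed and undirected contexts.
#' @param encounter_probs probabilities of solitary / non-face / face
#'   partner placement for contact-window songs.
#' @param syls_per_song mean number of syllables per song (>= 1).
#' @param mb_intensity mean male-bedding song count in the final night.
#' @param rep_pairs indices of pairs receiving a repetition trial.
#' @param rep_correlation correlation of log pair effects between first
#'   trial and repetition.
#' @param jitter_sd frequency jitter sd (kHz) of rendered contours.
#' @param frame_step_ms frame spacing of rendered contours.
#' @param seed RNG seed.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_pairs = 12, nights = 4,
                            short_protocol_pairs = 1:6,
                            intensity = c(FR = 4, NR = 4, CC = 18,
                                          CR = 3, CW = 1),
                            pair_sd = 1, night2_mult = 4.5, decay = 0.5,
                            mixture_directed = c(LFS = 0.40, SDN = 0.20,
                                                 SFL = 0.15, SUP = 0.05,
                                                 TDU = 0.05, TUD = 0.05,
                                                 JED = 0.05, JEU = 0.05),
                            mixture_undirected = c(SUP = 0.15, SFL = 0.10,
                                                   SDN = 0.05, TUD = 0.10,
                                                   TDU = 0.10, TRS = 0.10,
                                                   JEU = 0.10, JED = 0.05,
                                                   JLU = 0.10, JLD = 0.05,
                                                   J2UD = 0.04, J2DU = 0.03,
                                                   JPS = 0.03),
                            encounter_probs = c(solitary = 0.6,
                                                non_face = 0.2, face = 0.2),
                            syls_per_song = 3,
                            mb_intensity = 0.5,
                            rep_pairs = c(3, 4, 5, 6, 10),
                            rep_correlation = 0.95,
                            jitter_sd = 0,
                            frame_step_ms = 0.5,
                            seed = 1L) {
  stopifnot(all(intensity >= 0), decay > 0, decay <= 1,
            night2_mult >= 0, syls_per_song >= 1,
            abs(sum(mixture_directed) - 1) < 1e-8,
            abs(sum(mixture_undirected) - 1) < 1e-8)
  structure(as.list(environment()), class = "scenario_config")
}

# night-level intensity factor: baseline in night 1 (window closed),
# novelty surge in night 2, geometric familiarization decay afterwards
night_factor <- function(night, cfg) {
  if (night <= 1) 1 else cfg$night2_mult * cfg$decay^(night - 2)
}

directed_region <- function(region) region %in% c("CR", "CW")

sample_mixture <- function(n, mixture) {
  sample(names(mixture), n, replace = TRUE, prob = mixture)
}

#' Simulate a full recording session with ground truth
#'
#' Generates, per dyad and night, Poisson song counts per region (with the
#' configured pair effect and night factors), renders each song as a
#' sequence of archetype syllables separated by 15-400 ms silences (inside
#' the 10-500 ms syllable/song window) and consecutive songs by more than
#' 500 ms, and lays down occupancy intervals so that each song's emitter
#' is in its ground-truth region at onset. Contact-window songs get a
#' partner placement drawn from `encounter_probs`.
#'
#' @param cfg a [scenario_config()].
#' @return A list with `events` (list of [recording_event()], one per
#'   song, each tagged with `pair` and `night`), `occupancy` (per
#'   pair-night, tracks for `emitter` and `partner`) and `truth` (data
#'   frame: one row per song with pair, night, region, encounter, song and
#'   syllable-type ground truth).
#' @export
simulate_session <- function(cfg = scenario_config()) {
  set.seed(cfg$seed)
  arch <- syllable_archetypes()
  pair_eff <- rlnorm(cfg$n_pairs, 0, cfg$pair_sd)
  events <- list()
  occupancy <- list()
  truth <- list()
  for (pi in seq_len(cfg$n_pairs)) {
    pair_id <- sprintf("SP_%02d", pi)
    last_night <- if (pi %in% cfg$short_protocol_pairs)
      min(cfg$nights, 3) else cfg$nights
    for (night in seq_len(last_night)) {
      n_by_region <- vapply(names(cfg$intensity), function(r) {
        rpois(1, cfg$intensity[[r]] * pair_eff[pi] * night_factor(night, cfg))
      }, numeric(1))
      n_songs <- sum(n_by_region)
      if (n_songs == 0) next
      regions <- sample(rep(names(cfg$intensity), n_by_region))
      t_cursor <- 1000
      em_iv <- list(); pa_iv <- list()
      for (si in seq_along(regions)) {
        region <- regions[si]
        n_syl <- 1 + rpois(1, cfg$syls_per_song - 1)
        mix <- if (directed_region(region)) cfg$mixture_directed
               else cfg$mixture_undirected
        types <- sample_mixture(n_syl, mix)
        frames <- list()
        t_syl <- t_cursor
        onsets <- numeric(n_syl)
        for (k in seq_len(n_syl)) {
          tr <- render_syllable(arch[[types[k]]],
                                frame_step_ms = cfg$frame_step_ms,
                                jitter_sd = cfg$jitter_sd, t0 = t_syl)
          frames[[k]] <- tr$frames
          onsets[k] <- t_syl
          t_syl <- max(tr$frames$time_ms) + runif(1, 15, 400)
        }
        fr <- do.call(rbind, frames)
        ev_id <- sprintf("%s_n%d_s%03d", pair_id, night, si)
        tr_all <- contour_trace(fr$time_ms, fr$freq_khz, fr$amp_db,
                                channel_id = 1L, event_id = ev_id,
                                validate = FALSE)
        ev <- recording_event(min(fr$time_ms) - 1, max(fr$time_ms) + 1,
                              list(tr_all), channel_id = 1L,
                              event_id = ev_id)
        ev$pair <- pair_id; ev$night <- night
        events[[ev_id]] <- ev
        encounter <- if (region == "CW") {
          sample(names(cfg$encounter_probs), 1, prob = cfg$encounter_probs)
        } else NA_character_
        partner_region <- if (is.na(encounter)) "NR"
          else switch(encounter, face = "CW", non_face = "CR",
                      solitary = "FR")
        iv_end <- max(fr$time_ms) + 5
        em_iv[[si]] <- data.frame(start = t_cursor - 5, end = iv_end,
                                  region = region)
        pa_iv[[si]] <- data.frame(start = t_cursor - 5, end = iv_end,
                                  region = partner_region)
        truth[[ev_id]] <- data.frame(
          event_id = ev_id, pair = pair_id, night = night, region = region,
          encounter = encounter, n_syls = n_syl,
          types = paste(types, collapse = ";"),
          onset = onsets[1], offset = max(fr$time_ms))
        t_cursor <- max(fr$time_ms) + 600 + runif(1, 0, 2000)
      }
      key <- paste0(pair_id, "_n", night)
      occupancy[[key]] <- list(
        emitter = occupancy_track(paste0(pair_id, "_a"),
                                  vapply(em_iv, `[[`, numeric(1), "start"),
                                  vapply(em_iv, `[[`, numeric(1), "end"),
                                  vapply(em_iv, `[[`, character(1), "region")),
        partner = occupancy_track(paste0(pair_id, "_b"),
                                  vapply(pa_iv, `[[`, numeric(1), "start"),
                                  vapply(pa_iv, `[[`, numeric(1), "end"),
                                  vapply(pa_iv, `[[`, character(1), "region")))
    }
  }
  truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
    data.frame(event_id = character(), pair = character(),
               night = integer(), region = character(),
               encounter = character(), n_syls = integer(),
               types = character(), onset = numeric(), offset = numeric())
  rownames(truth_df) <- NULL
  list(events = unname(events), occupancy = occupancy, truth = truth_df)
}

#' Simulate a pair-by-night song count table
#'
#' Draws the count table alone (no contours): Poisson counts per pair,
#' night and region with a log-normal pair effect, the night-2 novelty
#' multiplier and familiarization decay, male-bedding counts in the final
#' night, and — for the configured repetition pairs — a second-trial count
#' whose log pair effect correlates with the first trial's at
#' `rep_correlation`.
#'
#' @param cfg a [scenario_config()].
#' @return A `"pair_night_counts"` data frame with columns `pair`,
#'   `group`, `night`, `FR`, `NR`, `CC`, `CR`, `MB`, `sum`, `rep_sum`,
#'   `excluded`, `reason`.
#' @export
simulate_count_table <- function(cfg = scenario_config()) {
  set.seed(cfg$seed)
  regions <- c("FR", "NR", "CC", "CR")
  # CW intensity folds into CR: the count table carries no CW column
  base <- cfg$intensity[regions]
  if ("CW" %in% names(cfg$intensity)) {
    base["CR"] <- base["CR"] + cfg$intensity[["CW"]]
  }
  z <- rnorm(cfg$n_pairs, 0, cfg$pair_sd)
  z_rep <- cfg$rep_correlation * z +
    sqrt(1 - cfg$rep_correlation^2) * rnorm(cfg$n_pairs, 0, cfg$pair_sd)
  rows <- list()
  for (pi in seq_len(cfg$n_pairs)) {
    pair_id <- sprintf("SP_%02d", pi)
    short <- pi %in% cfg$short_protocol_pairs
    last_night <- if (short) min(cfg$nights, 3) else cfg$nights
    for (night in seq_len(last_night)) {
      lam <- base * exp(z[pi]) * night_factor(night, cfg)
      cts <- rpois(length(regions), lam)
      names(cts) <- regions
      mb <- if (night == last_night && night >= 3) {
        rpois(1, cfg$mb_intensity * exp(z[pi]))
      } else 0
      rep_sum <- if (pi %in% cfg$rep_pairs && night <= 3) {
        sum(rpois(length(regions),
                  base * exp(z_rep[pi]) * night_factor(night, cfg)))
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        pair = pair_id, group = if (short) "A" else "B", night = night,
        FR = cts[["FR"]], NR = cts[["NR"]], CC = cts[["CC"]],
        CR = cts[["CR"]], MB = mb, sum = sum(cts), rep_sum = rep_sum,
        excluded = FALSE, reason = NA_character_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pair_night_counts", "data.frame")
  out
}
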