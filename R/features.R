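#' Feature-extraction configuration
#'
#' Thresholds of the syllable parameter computation. The study's own
#' routine does not quantify "sudden" for frequency jumps nor its
#' turning-point guards, so these are explicit, documented reconstructions.
#'
#' @param jump_threshold minimum absolute frequency change (kHz) between
#'   consecutive frames to count as a jump.
#' @param smooth_frames moving-average window (frames) applied to the
#'   contour before turning-point detection.
#' @param min_turn_slope minimum absolute slope (kHz/ms) both flanks of a
#'   turning point must reach.
#' @param min_turn_dur minimum duration (ms) of each flanking segment.
#' @param slope_mode `"lsq"` fits frequency on time by least squares
#'   (robust to frame jitter); `"endpoint"` uses the end-to-end difference.
#' @return A list of class `"feature_config"`.
#' @export
feature_config <- function(jump_threshold = 10, smooth_frames = 5,
                           min_turn_slope = 0.1, min_turn_dur = 1,
                           slope_mode = c("lsq", "endpoint")) {
  slope_mode <- match.arg(slope_mode)
  stopifnot(jump_threshold > 0, smooth_frames >= 1,
            min_turn_slope >= 0, min_turn_dur >= 0)
  structure(list(jump_threshold = jump_threshold,
                 smooth_frames = smooth_frames,
                 min_turn_slope = min_turn_slope,
                 min_turn_dur = min_turn_dur,
                 slope_mode = slope_mode),
            class = "feature_config")
}

#' Detect frequency jumps in a contour
#'
#' A jump is a discontinuity in the peak-frequency contour: an absolute
#' frequency change of at least `jump_threshold` kHz between two
#' consecutive frames.
#'
#' @param frames data frame with `time_ms` and `freq_khz` (at least 2 rows).
#' @param jump_threshold kHz; see [feature_config()].
#' @return A data frame with one row per jump: `pos_fraction` (midpoint of
#'   the two frames as a fraction of the contour duration), `direction`
#'   (`"up"`/`"down"`) and `index` (the frame preceding the jump).
#' @export
detect_jumps <- function(frames, jump_threshold = 10) {
  stopifnot(nrow(frames) >= 2)
  df <- diff(frames$freq_khz)
  hit <- which(abs(df) >= jump_threshold)
  dur <- frames$time_ms[nrow(frames)] - frames$time_ms[1]
  mid <- (frames$time_ms[hit] + frames$time_ms[hit + 1]) / 2
  data.frame(
    pos_fraction = if (dur > 0) (mid - frames$time_ms[1]) / dur else rep(0, length(hit)),
    direction = ifelse(df[hit] > 0, "up", "down"),
    index = hit
  )
}

# centered moving average with shrinking window at the edges, so the
# smoothed contour keeps its length and endpoints stay anchored
moving_average <- function(x, w) {
  if (w <= 1 || length(x) < 3) return(x)
  h <- (w - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Detect turning points in a contour
#'
#' A turning point is a reversal of the frequency trajectory: a sign change
#' of the local slope. To avoid counting frame jitter, the contour is
#' smoothed with a moving average, jump discontinuities are excluded (the
#' contour is cut at each jump and the pieces analysed separately), and a
#' reversal only counts when both flanking monotone segments have absolute
#' slope of at least `min_turn_slope` kHz/ms and last at least
#' `min_turn_dur` ms.
#'
#' @param frames data frame with `time_ms` and `freq_khz` (at least 3 rows).
#' @param cfg a [feature_config()].
#' @param jumps optional precomputed result of [detect_jumps()]; computed
#'   when missing.
#' @return A data frame with one row per turn: `pos_fraction` (time of the
#'   reversal as a fraction of contour duration) and `pattern`
#'   (`"up-down"` or `"down-up"`).
#' @export
detect_turns <- function(frames, cfg = feature_config(), jumps = NULL) {
  stopifnot(nrow(frames) >= 3)
  if (is.null(jumps)) jumps <- detect_jumps(frames, cfg$jump_threshold)
  t0 <- frames$time_ms[1]
  dur <- frames$time_ms[nrow(frames)] - t0
  # cut at jumps: piece k runs up to (and including) the frame before jump k
  cut_after <- sort(unique(jumps$index))
  piece_id <- cumsum(seq_len(nrow(frames)) %in% c(1, cut_after + 1))
  turns <- list()
  for (p in split(seq_len(nrow(frames)), piece_id)) {
    if (length(p) < 3) next
    tt <- frames$time_ms[p]
    ff <- moving_average(frames$freq_khz[p], cfg$smooth_frames)
    segs <- monotone_segments(tt, ff)
    segs <- segs[abs(segs$slope) >= cfg$min_turn_slope &
                   segs$dur >= cfg$min_turn_dur, , drop = FALSE]
    if (nrow(segs) < 2) next
    for (i in seq_len(nrow(segs) - 1)) {
      s1 <- sign(segs$slope[i]); s2 <- sign(segs$slope[i + 1])
      if (s1 != s2) {
        turns[[length(turns) + 1]] <- data.frame(
          pos_fraction = if (dur > 0) (segs$t_end[i] - t0) / dur else 0,
          pattern = if (s1 > 0) "up-down" else "down-up"
        )
      }
    }
  }
  if (length(turns) == 0) {
    return(data.frame(pos_fraction = numeric(0), pattern = character(0)))
  }
  do.call(rbind, turns)
}

# maximal runs of constant slope sign on a (smoothed) contour; returns one
# row per run with its boundary times, overall slope and duration
monotone_segments <- function(tt, ff) {
  s <- sign(diff(ff))
  # zero steps inherit the sign of the previous step so plateaus do not
  # fragment a monotone run
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  run <- cumsum(c(1, as.integer(s[-1] != s[-length(s)])))
  out <- lapply(split(seq_along(s), run), function(idx) {
    i0 <- idx[1]; i1 <- idx[length(idx)] + 1
    data.frame(t_start = tt[i0], t_end = tt[i1],
               slope = (ff[i1] - ff[i0]) / max(tt[i1] - tt[i0], 1e-9),
               dur = tt[i1] - tt[i0])
  })
  do.call(rbind, out)
}

#' Compute syllable parameters
#'
#' Computes the per-syllable parameter set used throughout the study:
#' duration (`sylDur`, ms), start frequency (`staFreq`, the first frame's
#' frequency, kHz), minimum frequency (`minFreq`), frequency bandwidth
#' (`freqBand` = max - min), centre of gravity (`freqCOG`, the
#' amplitude-weighted mean frequency using linear-amplitude weights, or the
#' plain mean when amplitudes are missing), overall slope (kHz/ms), and the
#' counts and positions of frequency jumps and turning points.
#'
#' @param syl a syllable from [split_syllables()] (>= 2 frames).
#' @param cfg a [feature_config()].
#' @return A list of class `"syllable_features"` with fields `sylDur`,
#'   `staFreq`, `minFreq`, `freqBand`, `freqCOG`, `slope`, `jumps`,
#'   `turns`, `jump_list`, `turn_list`.
#' @export
compute_syllable_features <- function(syl, cfg = feature_config()) {
  fr <- syl$frames
  if (nrow(fr) < 2) {
    stop("degenerate syllable: need at least 2 frames, got ", nrow(fr))
  }
  sylDur <- syl$offset - syl$onset
  w <- if (all(is.finite(fr$amp_db))) 10^(fr$amp_db / 20) else rep(1, nrow(fr))
  freqCOG <- sum(fr$freq_khz * w) / sum(w)
  slope <- if (cfg$slope_mode == "endpoint") {
    (fr$freq_khz[nrow(fr)] - fr$freq_khz[1]) / sylDur
  } else {
    unname(coef(lm(fr$freq_khz ~ fr$time_ms))[2])
  }
  jl <- detect_jumps(fr, cfg$jump_threshold)
  tl <- if (nrow(fr) >= 3) detect_turns(fr, cfg, jumps = jl) else
    data.frame(pos_fraction = numeric(0), pattern = character(0))
  structure(list(sylDur = sylDur,
                 staFreq = fr$freq_khz[1],
                 minFreq = min(fr$freq_khz),
                 freqBand = max(fr$freq_khz) - min(fr$freq_khz),
                 freqCOG = freqCOG,
                 slope = slope,
                 jumps = nrow(jl), turns = nrow(tl),
                 jump_list = jl, turn_list = tl),
            class = "syllable_features")
}

#' Compute song parameters
#'
#' Song duration (`soDur`) runs from the onset of the first syllable to the
#' offset of the last; `n_syls` counts syllables; the syllable rate
#' (`sylRate`, syllables/s) is only defined for songs with at least two
#' syllables — one-syllable songs are excluded from any rate analysis and
#' carry `sylRate = NA`.
#'
#' @param song a song from [group_songs()].
#' @return A list of class `"song_features"` with `soDur` (ms), `n_syls`
#'   and `sylRate` (NA when `n_syls == 1`).
#' @export
compute_song_features <- function(song) {
  n <- length(song$syllables)
  soDur <- song$offset - song$onset
  structure(list(soDur = soDur, n_syls = n,
                 sylRate = if (n >= 2) n / (soDur / 1000) else NA_real_),
            class = "song_features")
}
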