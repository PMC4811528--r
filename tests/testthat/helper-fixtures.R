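# small constructors shared across test files

# contour frames on a regular grid
make_frames <- function(t, f, a = 60) {
  data.frame(time_ms = t, freq_khz = f, amp_db = rep(a, length(t))[seq_along(t)])
}

# a flat-tone trace with optional internal gaps: `gaps` is a named list
# mapping frame index -> extra silence (ms) inserted after that frame
make_gapped_trace <- function(n = 40, step = 1, f = 70, gaps = list()) {
  t <- seq(0, by = step, length.out = n)
  for (g in names(gaps)) {
    i <- as.integer(g)
    t[(i + 1):n] <- t[(i + 1):n] + gaps[[g]]
  }
  contour_trace(t, rep(f, n), rep(60, n), validate = FALSE)
}

# synthesized syllable from a frequency function of time
make_syllable <- function(t, f, a = 60) {
  fr <- make_frames(t, f, a)
  structure(list(frames = fr, onset = min(t), offset = max(t),
                 channel_id = 1L, event_id = "test"),
            class = "usv_syllable")
}

# simple recording event without traces, for dedup tests
bare_event <- function(start, end, channel, id = "e") {
  recording_event(start, end, list(), channel_id = as.integer(channel),
                  event_id = id)
}

# brute-force gap segmentation oracle: partition indices by scanning all
# gaps, independent of the package's cumsum-based implementation
brute_force_segments <- function(times, gap) {
  groups <- list(1L)
  for (i in seq_along(times)[-1]) {
    if (times[i] - times[i - 1] > gap) {
      groups[[length(groups) + 1]] <- i
    } else {
      g <- length(groups)
      groups[[g]] <- c(groups[[g]], i)
    }
  }
  groups
}
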