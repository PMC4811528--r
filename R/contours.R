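#' Spectrogram configuration
#'
#' Settings of the short-time Fourier transform used for peak-frequency
#' contour extraction. Defaults mirror the recording protocol of the
#' encounter experiment: 500 kHz sampling, 256-point Hann-windowed FFT with
#' 85% overlap, zero-padded until the bin width is at most 0.49 kHz.
#'
#' @param sample_rate sampling rate in Hz.
#' @param fft_len analysis window length in samples.
#' @param window window name; only `"hann"` is implemented.
#' @param overlap fractional overlap between consecutive windows, in `[0, 1)`.
#' @param target_resolution desired frequency bin width in kHz, achieved by
#'   zero-padding the windowed segment to the next power of two.
#' @param band_lo,band_hi frequency band (kHz) searched for the peak.
#' @param noise_floor_db a frame is kept only if its in-band peak exceeds the
#'   median in-band spectral level by this many dB. The original workflow
#'   relied on hardware triggering plus manual checking; this floor is the
#'   automated stand-in.
#' @param median_filter if `TRUE`, apply a 3-frame running median to the
#'   extracted frequency contour (an automated replacement for the manual
#'   correction pass; off by default).
#' @return A list of class `"spectro_config"`.
#' @export
spectro_config <- function(sample_rate = 500000, fft_len = 256,
                           window = "hann", overlap = 0.85,
                           target_resolution = 0.49,
                           band_lo = 20, band_hi = 250,
                           noise_floor_db = 20, median_filter = FALSE) {
  stopifnot(overlap >= 0, overlap < 1, target_resolution > 0)
  if (target_resolution > sample_rate / fft_len / 1000) {
    stop("target_resolution coarser than the un-padded bin width")
  }
  structure(list(sample_rate = sample_rate, fft_len = fft_len,
                 window = window, overlap = overlap,
                 target_resolution = target_resolution,
                 band_lo = band_lo, band_hi = band_hi,
                 noise_floor_db = noise_floor_db,
                 median_filter = median_filter),
            class = "spectro_config")
}

#' Whistle-trigger configuration
#'
#' Parameters of the recorder's automatic whistle detection: sounds in the
#' 20-250 kHz band lasting at least 10 ms trigger a recording event that
#' starts 200 ms before the whistle and runs until 1 s after the last
#' detected whistle.
#'
#' @param band_lo,band_hi trigger band in kHz.
#' @param min_dur minimum whistle duration in ms.
#' @param pre_trigger recording lead before the first whistle, ms.
#' @param post_hold recording tail after the last whistle, ms; whistles
#'   closer than this merge into one event.
#' @param run_gap frames separated by more than this many ms belong to
#'   different sound runs (silence threshold for run detection).
#' @return A list of class `"trigger_config"`.
#' @export
trigger_config <- function(band_lo = 20, band_hi = 250, min_dur = 10,
                           pre_trigger = 200, post_hold = 1000,
                           run_gap = 10) {
  stopifnot(band_lo < band_hi, min_dur > 0, pre_trigger > 0, post_hold > 0)
  structure(list(band_lo = band_lo, band_hi = band_hi, min_dur = min_dur,
                 pre_trigger = pre_trigger, post_hold = post_hold,
                 run_gap = run_gap),
            class = "trigger_config")
}

#' Construct a peak-frequency contour trace
#'
#' A contour trace holds the time course of the spectrogram peak: one row
#' per analysis frame with time (ms), peak frequency (kHz) and amplitude
#' (dB). Times must be strictly increasing with approximately constant
#' spacing, frequencies positive.
#'
#' @param time_ms,freq_khz,amp_db numeric vectors of equal length.
#' @param channel_id integer microphone channel.
#' @param event_id identifier of the recording event the trace belongs to.
#' @param validate check invariants (strictly increasing time, near-constant
#'   spacing, positive frequency).
#' @return An object of class `"contour_trace"`: a list with a `frames`
#'   data frame plus `channel_id` and `event_id`.
#' @export
contour_trace <- function(time_ms, freq_khz, amp_db = rep(NA_real_, length(time_ms)),
                          channel_id = 1L, event_id = "ev1", validate = TRUE) {
  frames <- data.frame(time_ms = as.numeric(time_ms),
                       freq_khz = as.numeric(freq_khz),
                       amp_db = as.numeric(amp_db))
  tr <- structure(list(frames = frames,
                       channel_id = as.integer(channel_id),
                       event_id = as.character(event_id)),
                  class = "contour_trace")
  if (validate) validate_contour_trace(tr)
  tr
}

validate_contour_trace <- function(tr) {
  fr <- tr$frames
  if (nrow(fr) == 0) return(invisible(tr))
  dt <- diff(fr$time_ms)
  if (any(dt <= 0)) {
    stop("contour trace of event '", tr$event_id,
         "': frame times not strictly increasing")
  }
  if (length(dt) > 1) {
    med <- median(dt)
    # regular frames may wobble 10% around the median step; strictly longer
    # steps are silences between sound runs and are legitimate
    if (any(dt < 0.9 * med - 1e-9)) {
      stop("contour trace of event '", tr$event_id,
           "': frame spacing not approximately constant")
    }
  }
  if (any(fr$freq_khz <= 0)) {
    stop("contour trace of event '", tr$event_id, "': non-positive frequency")
  }
  invisible(tr)
}

#' @export
print.contour_trace <- function(x, ...) {
  cat(sprintf("<contour_trace> event %s, channel %d, %d frames",
              x$event_id, x$channel_id, nrow(x$frames)))
  if (nrow(x$frames) > 0) {
    cat(sprintf(", %.1f-%.1f ms, %.1f-%.1f kHz",
                min(x$frames$time_ms), max(x$frames$time_ms),
                min(x$frames$freq_khz), max(x$frames$freq_khz)))
  }
  cat("\n")
  invisible(x)
}

#' Construct a recording event
#'
#' Container for one triggered recording: a time window on one channel
#' holding one or more contour traces.
#'
#' @param start,end event window in ms, `start < end`.
#' @param traces list of [contour_trace()] objects whose frames fall inside
#'   the window.
#' @param channel_id integer channel.
#' @param event_id identifier.
#' @return An object of class `"recording_event"`.
#' @export
recording_event <- function(start, end, traces, channel_id = 1L,
                            event_id = "ev1") {
  stopifnot(start < end)
  for (tr in traces) {
    if (nrow(tr$frames) > 0 &&
        (min(tr$frames$time_ms) < start - 1e-9 ||
         max(tr$frames$time_ms) > end + 1e-9)) {
      stop("trace frames outside event window [", start, ", ", end, "]")
    }
  }
  structure(list(start = start, end = end, traces = traces,
                 channel_id = as.integer(channel_id),
                 event_id = as.character(event_id)),
            class = "recording_event")
}

event_duration <- function(ev) ev$end - ev$start

#' Read a contour table
#'
#' Reads the CSV dialect of exported spectrogram contours: one row per
#' frame with header `event_id,channel,time_ms,freq_khz,amp_db`. Rows are
#' grouped into one trace per (event, channel); frame times must already be
#' strictly increasing within each trace.
#'
#' @param path file path.
#' @return A list of [recording_event()] objects, one per distinct
#'   (event_id, channel) pair, each holding a single trace.
#' @export
read_contour_table <- function(path) {
  if (!file.exists(path)) stop("contour table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("event_id", "channel", "time_ms", "freq_khz", "amp_db")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("contour table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0) return(list())
  key <- paste(df$event_id, df$channel, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    tr <- contour_trace(g$time_ms, g$freq_khz, g$amp_db,
                        channel_id = g$channel[1], event_id = g$event_id[1])
    recording_event(start = min(g$time_ms), end = max(g$time_ms) + 1e-6,
                    traces = list(tr), channel_id = g$channel[1],
                    event_id = g$event_id[1])
  }) |> unname()
}

#' Write a contour table
#'
#' Inverse of [read_contour_table()]: serializes recording events to the
#' contour CSV dialect. An empty event list yields a header-only file.
#'
#' @param events list of [recording_event()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contour_table <- function(events, path) {
  rows <- lapply(events, function(ev) {
    do.call(rbind, lapply(ev$traces, function(tr) {
      if (nrow(tr$frames) == 0) return(NULL)
      data.frame(event_id = tr$event_id, channel = tr$channel_id,
                 time_ms = tr$frames$time_ms, freq_khz = tr$frames$freq_khz,
                 amp_db = tr$frames$amp_db)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(event_id = character(), channel = integer(),
                      time_ms = numeric(), freq_khz = numeric(),
                      amp_db = numeric())
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Zero-padded FFT length: smallest power of two whose bin width
# (sample_rate / nfft) is at most the target resolution, never shorter than
# the analysis window itself.
padded_fft_length <- function(cfg) {
  nfft <- 2^ceiling(log2(cfg$sample_rate / (cfg$target_resolution * 1000)))
  max(nfft, cfg$fft_len)
}

#' Extract a peak-frequency contour from a waveform
#'
#' Computes a short-time Fourier transform of the waveform (Hann window,
#' zero-padded to the configured resolution) and keeps, per frame, the
#' frequency bin with the highest in-band amplitude — the automated
#' counterpart of the "brightest pixel per FFT column" extraction step.
#' Frames whose peak does not clear the noise floor are dropped, so silence
#' yields an empty trace.
#'
#' @param waveform numeric vector of audio samples (any amplitude scale).
#' @param cfg a [spectro_config()].
#' @param channel_id,event_id identifiers stored on the trace.
#' @return A [contour_trace()]; empty (0 frames) for all-silent input.
#' @export
extract_contour <- function(waveform, cfg = spectro_config(),
                            channel_id = 1L, event_id = "ev1") {
  n <- length(waveform)
  if (n < cfg$fft_len) stop("waveform shorter than one FFT window")
  win <- signal::hanning(cfg$fft_len)
  hop <- max(1L, as.integer(round((1 - cfg$overlap) * cfg$fft_len)))
  nfft <- padded_fft_length(cfg)
  starts <- seq(1L, n - cfg$fft_len + 1L, by = hop)
  freqs_khz <- (0:(nfft %/% 2)) * cfg$sample_rate / nfft / 1000
  in_band <- which(freqs_khz >= cfg$band_lo & freqs_khz <= cfg$band_hi)
  t_ms <- f_khz <- a_db <- numeric(0)
  for (s in starts) {
    seg <- waveform[s:(s + cfg$fft_len - 1L)] * win
    spec <- fft(c(seg, numeric(nfft - cfg$fft_len)))
    mag_db <- 20 * log10(Mod(spec[in_band]) + 1e-12)
    k <- which.max(mag_db)
    if (mag_db[k] >= median(mag_db) + cfg$noise_floor_db) {
      t_ms <- c(t_ms, (s - 1 + cfg$fft_len / 2) / cfg$sample_rate * 1000)
      f_khz <- c(f_khz, freqs_khz[in_band[k]])
      a_db <- c(a_db, mag_db[k])
    }
  }
  if (cfg$median_filter && length(f_khz) >= 3) {
    f_khz <- stats::runmed(f_khz, 3)
  }
  contour_trace(t_ms, f_khz, a_db, channel_id = channel_id,
                event_id = event_id, validate = FALSE)
}

#' Emulate the recorder's whistle trigger
#'
#' Reconstructs recording events from a continuous, time-sorted frame
#' stream containing silences. Frames separated by more than `run_gap` ms
#' form distinct sound runs; a run qualifies as a whistle when it lies in
#' the trigger band and lasts at least `min_dur` ms. Each event opens
#' `pre_trigger` ms before its first qualifying whistle and closes
#' `post_hold` ms after the last; whistles falling inside an open event
#' extend it.
#'
#' @param frames data frame with columns `time_ms`, `freq_khz` and
#'   optionally `amp_db`, sorted by time.
#' @param cfg a [trigger_config()].
#' @param channel_id channel stamped on the emitted events.
#' @return A list of [recording_event()] objects (possibly empty).
#' @export
emulate_trigger <- function(frames, cfg = trigger_config(), channel_id = 1L) {
  if (is.null(frames$amp_db)) frames$amp_db <- NA_real_
  if (nrow(frames) == 0) return(list())
  if (is.unsorted(frames$time_ms, strictly = FALSE)) {
    stop("frame stream must be time-sorted")
  }
  run_id <- cumsum(c(1, as.integer(diff(frames$time_ms) > cfg$run_gap)))
  runs <- split(frames, run_id)
  whistle <- vapply(runs, function(r) {
    dur <- max(r$time_ms) - min(r$time_ms)
    dur >= cfg$min_dur && all(r$freq_khz >= cfg$band_lo) &&
      all(r$freq_khz <= cfg$band_hi)
  }, logical(1))
  if (!any(whistle)) return(list())
  w_on <- unname(vapply(runs[whistle], function(r) min(r$time_ms), numeric(1)))
  w_off <- unname(vapply(runs[whistle], function(r) max(r$time_ms), numeric(1)))
  # merge whistles into events: a whistle starting before the current
  # event's provisional end (last offset + post_hold) extends the event
  ev_start <- w_on[1] - cfg$pre_trigger
  ev_last_off <- w_off[1]
  events <- list()
  flush <- function(events, s, last_off) {
    e <- last_off + cfg$post_hold
    # the recorder cannot rewind into an event it already closed
    if (length(events) > 0) s <- max(s, events[[length(events)]]$end)
    keep <- frames$time_ms >= s & frames$time_ms <= e
    eid <- sprintf("trig%03d", length(events) + 1L)
    tr <- contour_trace(frames$time_ms[keep], frames$freq_khz[keep],
                        frames$amp_db[keep], channel_id = channel_id,
                        event_id = eid, validate = FALSE)
    c(events, list(recording_event(s, e, list(tr), channel_id = channel_id,
                                   event_id = eid)))
  }
  if (length(w_on) > 1) {
    for (i in 2:length(w_on)) {
      if (w_on[i] <= ev_last_off + cfg$post_hold) {
        ev_last_off <- max(ev_last_off, w_off[i])
      } else {
        events <- flush(events, ev_start, ev_last_off)
        ev_start <- w_on[i] - cfg$pre_trigger
        ev_last_off <- w_off[i]
      }
    }
  }
  flush(events, ev_start, ev_last_off)
}

#' Deduplicate double-recorded events across two channels
#'
#' The two microphones nearest the contact window often capture the same
#' vocalization. For every temporally overlapping cross-channel pair only
#' the longer event is kept; at equal length the event from the
#' lower-numbered channel survives. Non-overlapping events pass through.
#'
#' @param events_ch1,events_ch2 lists of [recording_event()] objects from
#'   the two channels of one compartment side.
#' @return A single list holding the surviving events of both channels,
#'   sorted by start time.
#' @export
dedup_events <- function(events_ch1, events_ch2) {
  all_ev <- c(events_ch1, events_ch2)
  if (length(all_ev) <= 1) return(all_ev)
  overlaps <- function(a, b) min(a$end, b$end) - max(a$start, b$start) > 0
  beats <- function(a, b) {
    # does a displace b? longer wins; ties go to the lower channel id
    da <- event_duration(a); db <- event_duration(b)
    da > db || (da == db && a$channel_id < b$channel_id)
  }
  drop <- vapply(all_ev, function(e) {
    any(vapply(all_ev, function(o) {
      o$channel_id != e$channel_id && overlaps(o, e) && beats(o, e)
    }, logical(1)))
  }, logical(1))
  kept <- all_ev[!drop]
  kept[order(vapply(kept, function(e) e$start, numeric(1)),
             vapply(kept, function(e) e$channel_id, integer(1)))]
}

#' Read a mono 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE reader for the recorder's raw output (16-bit PCM,
#' single channel). Returns samples scaled to `[-1, 1)` plus the sample
#' rate so the result can feed [extract_contour()] directly.
#'
#' @param path WAV file path.
#' @return A list with `samples` (numeric) and `sample_rate` (Hz).
#' @export
read_wav_mono <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      channels <- fmt[2]
      sample_rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      invisible(readBin(con, "integer", 1, size = 2, endian = "little"))
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (fmt[1] != 1 || bits != 16) stop("only 16-bit PCM WAV is supported")
      leftover <- size - 16
      if (leftover > 0) invisible(readBin(con, "raw", leftover))
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", size / 2, size = 2,
                         endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (!is.null(channels) && channels != 1) stop("expected a mono WAV file")
  list(samples = samples / 32768, sample_rate = sample_rate)
}
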