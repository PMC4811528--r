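test_that("contour table round-trips through write and read", {
  t <- seq(0, 10, by = 0.5)
  tr <- contour_trace(t, 70 + 0.3 * t, rep(55, length(t)),
                      channel_id = 2L, event_id = "evA")
  ev <- recording_event(0, 11, list(tr), channel_id = 2L, event_id = "evA")
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_table(list(ev), path)
  back <- read_contour_table(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$traces[[1]]$frames$time_ms, t, tolerance = 1e-6)
  expect_equal(back[[1]]$traces[[1]]$frames$freq_khz, 70 + 0.3 * t,
               tolerance = 1e-6)
  expect_equal(back[[1]]$channel_id, 2L)
})

test_that("contour reader validates schema and time order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("event_id,channel,time_ms", path) # missing columns
  expect_error(read_contour_table(path), "missing column")

  df <- data.frame(event_id = "e1", channel = 1,
                   time_ms = c(0, 2, 1), freq_khz = 70, amp_db = 60)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_contour_table(path), "e1")

  # 3-row file, one event -> one event with one 3-frame trace
  df$time_ms <- c(0, 1, 2)
  write.csv(df, path, row.names = FALSE)
  evs <- read_contour_table(path)
  expect_length(evs, 1)
  expect_equal(nrow(evs[[1]]$traces[[1]]$frames), 3)
})

test_that("writing an empty event list yields a header-only file", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_table(list(), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_length(read_contour_table(path), 0)
})

test_that("extract_contour recovers a pure tone within one padded bin", {
  cfg <- spectro_config()
  t <- seq(0, 0.05, by = 1 / cfg$sample_rate)
  tr <- extract_contour(sin(2 * pi * 70000 * t), cfg)
  bin_khz <- cfg$sample_rate / 1024 / 1000 # 1024-point zero-padded FFT
  expect_gt(nrow(tr$frames), 100)
  expect_true(all(abs(tr$frames$freq_khz - 70) <= bin_khz))
})

test_that("extract_contour recovers a linear chirp slope within 10%", {
  cfg <- spectro_config()
  t <- seq(0, 0.02, by = 1 / cfg$sample_rate)
  # instantaneous frequency 60 + 1 kHz/ms: phase integral of f(t)
  wave <- sin(2 * pi * (60000 * t + 0.5 * (20000 / 0.02) * t^2))
  tr <- extract_contour(wave, cfg)
  slope <- unname(coef(lm(freq_khz ~ time_ms, data = tr$frames))[2])
  expect_lt(abs(slope - 1), 0.1)
})

test_that("extract_contour returns an empty trace on silence", {
  tr <- extract_contour(rep(0, 5000), spectro_config())
  expect_equal(nrow(tr$frames), 0)
})

test_that("whistle trigger applies duration, pre-trigger and merge rules", {
  mkrun <- function(t0, dur, f = 70) make_frames(seq(t0, t0 + dur, by = 0.5),
                                                 f)
  # below the 10 ms minimum: no event
  expect_length(emulate_trigger(mkrun(500, 5)), 0)
  # 12 ms whistle at 500 ms: event opens 200 ms earlier
  ev <- emulate_trigger(mkrun(500, 12))
  expect_length(ev, 1)
  expect_equal(ev[[1]]$start, 300)
  # two whistles 800 ms apart merge (post-hold 1000 ms)
  ev2 <- emulate_trigger(rbind(mkrun(500, 20), mkrun(1320, 20)))
  expect_length(ev2, 1)
  expect_equal(ev2[[1]]$end, 1340 + 1000)
  # 1500 ms apart: two events
  ev3 <- emulate_trigger(rbind(mkrun(500, 20), mkrun(2020, 20)))
  expect_length(ev3, 2)
  # out-of-band run does not trigger
  expect_length(emulate_trigger(mkrun(500, 20, f = 10)), 0)
})

test_that("trigger events never overlap and contain every whistle", {
  set.seed(42)
  for (rep in 1:10) {
    starts <- sort(runif(8, 0, 20000))
    frames <- do.call(rbind, lapply(starts, function(s) {
      make_frames(seq(s, s + runif(1, 11, 40), by = 0.5), 70)
    }))
    frames <- frames[order(frames$time_ms), ]
    frames <- frames[c(TRUE, diff(frames$time_ms) > 0), ]
    evs <- emulate_trigger(frames)
    if (length(evs) > 1) {
      b <- t(vapply(evs, function(e) c(e$start, e$end), numeric(2)))
      expect_true(all(b[-1, 1] >= b[-nrow(b), 2]))
    }
    covered <- vapply(starts, function(s) {
      any(vapply(evs, function(e) s >= e$start & s <= e$end, logical(1)))
    }, logical(1))
    expect_true(all(covered))
  }
})

test_that("dedup keeps the longer of overlapping cross-channel events", {
  a <- bare_event(0, 120, 1)
  b <- bare_event(50, 140, 2) # 90 ms, overlaps a
  kept <- dedup_events(list(a), list(b))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$channel_id, 1L)

  # disjoint events both survive
  kept2 <- dedup_events(list(bare_event(0, 100, 1)),
                        list(bare_event(200, 300, 2)))
  expect_length(kept2, 2)
})

test_that("dedup tie-break and idempotence are order-independent", {
  # equal length overlap: lower channel id wins regardless of argument order
  a <- bare_event(0, 100, 1)
  b <- bare_event(50, 150, 2)
  for (args in list(list(list(a), list(b)), list(list(b), list(a)))) {
    kept <- do.call(dedup_events, args)
    expect_length(kept, 1)
    expect_equal(kept[[1]]$channel_id, 1L)
  }
  # idempotence on a random cross-channel layout
  set.seed(7)
  ch1 <- lapply(1:6, function(i) {
    s <- runif(1, 0, 1000); bare_event(s, s + runif(1, 20, 200), 1, paste0("a", i))
  })
  ch2 <- lapply(1:6, function(i) {
    s <- runif(1, 0, 1000); bare_event(s, s + runif(1, 20, 200), 2, paste0("b", i))
  })
  once <- dedup_events(ch1, ch2)
  again <- dedup_events(Filter(function(e) e$channel_id == 1, once),
                        Filter(function(e) e$channel_id == 2, once))
  expect_equal(vapply(again, function(e) e$event_id, character(1)),
               vapply(once, function(e) e$event_id, character(1)))
})

test_that("wav reader round-trips a PCM16 file into extract_contour", {
  sr <- 500000L
  t <- seq(0, 0.03, by = 1 / sr)
  samples <- as.integer(round(sin(2 * pi * 70000 * t) * 30000))
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  data_size <- length(samples) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")      # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(samples, con, size = 2, endian = "little")
  close(con)
  wav <- read_wav_mono(path)
  expect_equal(wav$sample_rate, sr)
  tr <- extract_contour(wav$samples, spectro_config())
  expect_true(all(abs(tr$frames$freq_khz - 70) <= 0.5))
})
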