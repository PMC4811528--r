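test_that("constant and linear contours yield the textbook parameters", {
  t <- seq(0, 20, by = 0.5)
  flat <- compute_syllable_features(make_syllable(t, rep(70, length(t))))
  expect_equal(flat$sylDur, 20)
  expect_equal(flat$staFreq, 70)
  expect_equal(flat$minFreq, 70)
  expect_equal(flat$freqBand, 0)
  expect_equal(flat$freqCOG, 70)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$jumps, 0)
  expect_equal(flat$turns, 0)

  chirp <- compute_syllable_features(make_syllable(t, 60 + t))
  expect_equal(chirp$slope, 1, tolerance = 1e-10)
  expect_equal(chirp$freqBand, 20)
  expect_equal(chirp$staFreq, 60)

  expect_error(
    compute_syllable_features(make_syllable(5, 70)),
    "degenerate")
})

test_that("freqCOG weights by linear amplitude and stays in range", {
  t <- c(0, 1, 2, 3)
  f <- c(60, 60, 80, 80)
  a <- c(40, 40, 60, 60) # second half 20 dB (10x) louder
  ft <- compute_syllable_features(make_syllable(t, f, a))
  expect_equal(ft$freqCOG, (60 * 2 * 100 + 80 * 2 * 1000) / (2 * 100 + 2 * 1000))
  # unweighted fallback when amplitudes are missing
  syl <- make_syllable(t, f)
  syl$frames$amp_db <- NA_real_
  expect_equal(compute_syllable_features(syl)$freqCOG, 70)
})

test_that("jump detection records threshold, direction and position", {
  t <- seq(0, 20, by = 0.5)
  f <- rep(65, length(t)); f[t > 6] <- f[t > 6] + 20
  jl <- detect_jumps(make_frames(t, f), 10)
  expect_equal(nrow(jl), 1)
  expect_equal(jl$direction, "up")
  expect_equal(jl$pos_fraction, 0.3125, tolerance = 0.05) # step at 30% of 20 ms

  # smooth chirp never jumps
  expect_equal(nrow(detect_jumps(make_frames(t, 60 + t), 10)), 0)

  # +20 then -25 discontinuities: up then down
  f2 <- rep(65, length(t)); f2[t > 6] <- f2[t > 6] + 20
  f2[t > 14] <- f2[t > 14] - 25
  jl2 <- detect_jumps(make_frames(t, f2), 10)
  expect_equal(jl2$direction, c("up", "down"))
})

test_that("jump count is non-increasing in the threshold", {
  set.seed(12)
  t <- seq(0, 30, by = 0.5)
  f <- 70 + cumsum(sample(c(0, 0, 0, 12, -15), length(t), replace = TRUE))
  fr <- make_frames(t, pmax(f, 30))
  counts <- vapply(c(5, 10, 14, 20, 30),
                   function(th) nrow(detect_jumps(fr, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("turn detection finds slope reversals and ignores jitter", {
  t <- seq(0, 30, by = 0.5)
  v <- ifelse(t < 15, 80 - 0.8 * t, 80 - 0.8 * 15 + 0.8 * (t - 15))
  tl <- detect_turns(make_frames(t, v))
  expect_equal(nrow(tl), 1)
  expect_equal(tl$pattern, "down-up")
  # monotone contour: no turns
  expect_equal(nrow(detect_turns(make_frames(t, 60 + 0.5 * t))), 0)
  # sub-threshold jitter on a flat contour: no turns
  set.seed(5)
  flat <- make_frames(t, 70 + rnorm(length(t), 0, 0.05))
  expect_equal(nrow(detect_turns(flat)), 0)
})

test_that("alternating piecewise segments match a brute-force slope scan", {
  # three +1/-1/+1 kHz/ms segments: reversals at the two interior knots
  t <- seq(0, 30, by = 0.5)
  knots <- c(10, 20)
  f <- numeric(length(t)); f0 <- 65
  slope <- c(1, -1, 1)
  seg_of <- findInterval(t, knots) + 1
  f_start <- c(f0, f0 + 10, f0 + 10 - 10)
  t_start <- c(0, knots)
  f <- f_start[seg_of] + slope[seg_of] * (t - t_start[seg_of])
  tl <- detect_turns(make_frames(t, f))
  # brute-force oracle over the analytic segment slopes
  oracle_turns <- sum(diff(sign(slope)) != 0)
  expect_equal(nrow(tl), oracle_turns)
  expect_equal(tl$pattern, c("up-down", "down-up"))
})

test_that("turns are not counted across jump discontinuities", {
  # rising, +20 kHz jump, then rising again: the apparent reversal at the
  # jump must not register as a turn
  t <- seq(0, 20, by = 0.5)
  f <- 60 + 0.5 * t; f[t > 10] <- f[t > 10] + 20
  ft <- compute_syllable_features(make_syllable(t, f))
  expect_equal(ft$jumps, 1)
  expect_equal(ft$turns, 0)
})

test_that("frequency statistics stay within the observed frame range", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:80, 1)
    t <- seq(0, by = 0.5, length.out = n)
    f <- runif(n, 30, 110)
    a <- runif(n, 30, 70)
    ft <- compute_syllable_features(make_syllable(t, f, a))
    expect_gte(ft$staFreq, min(f)); expect_lte(ft$staFreq, max(f))
    expect_gte(ft$freqCOG, min(f)); expect_lte(ft$freqCOG, max(f))
    expect_equal(ft$minFreq, min(f))
    expect_equal(ft$freqBand, max(f) - min(f))
    expect_gte(ft$freqCOG, ft$minFreq)
    expect_lte(ft$freqCOG, ft$minFreq + ft$freqBand)
    expect_equal(ft$jumps, nrow(ft$jump_list))
    expect_equal(ft$turns, nrow(ft$turn_list))
  }
})

test_that("song features follow the rate-exclusion rule", {
  tr <- make_gapped_trace(n = 30, gaps = list(`10` = 20, `20` = 30))
  songs <- group_songs(split_syllables(tr))
  sf <- compute_song_features(songs[[1]])
  expect_equal(sf$n_syls, 3)
  # single-syllable song: rate undefined (excluded from rate analyses)
  one <- group_songs(split_syllables(make_gapped_trace(n = 10)))
  expect_true(is.na(compute_song_features(one[[1]])$sylRate))
  # 4 syllables spanning 0-800 ms: rate 5/s
  syls <- lapply(c(0, 250, 500, 750), function(t0) {
    make_syllable(seq(t0, t0 + 50, by = 1), rep(70, 51))
  })
  sf4 <- compute_song_features(group_songs(syls)[[1]])
  expect_equal(sf4$soDur, 800)
  expect_equal(sf4$sylRate, 5)
})
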