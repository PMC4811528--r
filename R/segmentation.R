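#' Split a contour trace into syllables
#'
#' A syllable is a maximal run of contour frames in which no inter-frame
#' silence exceeds `syllable_gap` ms. Gaps are measured from one frame to
#' the next and a new syllable starts only where the gap is strictly
#' greater than the threshold, so a gap of exactly `syllable_gap` does not
#' split. Every input frame ends up in exactly one syllable.
#'
#' @param trace a [contour_trace()].
#' @param syllable_gap silence threshold in ms (default 10, the value the
#'   study settled on by visual inspection of its recordings).
#' @return A list of `"usv_syllable"` objects, each a list with `frames`
#'   (a slice of the trace), `onset` and `offset` in ms. Empty trace gives
#'   an empty list.
#' @export
split_syllables <- function(trace, syllable_gap = 10) {
  fr <- trace$frames
  if (nrow(fr) == 0) return(list())
  syl_id <- cumsum(c(1, as.integer(diff(fr$time_ms) > syllable_gap)))
  lapply(split(fr, syl_id), function(g) {
    structure(list(frames = g, onset = min(g$time_ms),
                   offset = max(g$time_ms),
                   channel_id = trace$channel_id,
                   event_id = trace$event_id),
              class = "usv_syllable")
  }) |> unname()
}

#' Group syllables into songs
#'
#' A song is a maximal sequence of syllables in which each
#' offset-to-next-onset silence is at most `song_gap` ms; a strictly larger
#' gap starts a new song. Syllables must be time-sorted and non-overlapping.
#'
#' @param syllables list of syllables from [split_syllables()].
#' @param song_gap silence threshold in ms (default 500).
#' @return A list of `"usv_song"` objects: lists with `syllables`, `onset`
#'   and `offset`.
#' @export
group_songs <- function(syllables, song_gap = 500) {
  n <- length(syllables)
  if (n == 0) return(list())
  onsets <- vapply(syllables, function(s) s$onset, numeric(1))
  offsets <- vapply(syllables, function(s) s$offset, numeric(1))
  if (is.unsorted(onsets) || any(onsets[-1] < offsets[-n])) {
    stop("syllables must be time-sorted and non-overlapping")
  }
  gap <- onsets[-1] - offsets[-n]
  song_id <- cumsum(c(1, as.integer(gap > song_gap)))
  lapply(split(seq_len(n), song_id), function(idx) {
    structure(list(syllables = syllables[idx],
                   onset = onsets[idx[1]],
                   offset = offsets[idx[length(idx)]]),
              class = "usv_song")
  }) |> unname()
}

#' @export
print.usv_song <- function(x, ...) {
  cat(sprintf("<usv_song> %d syllable(s), %.1f-%.1f ms\n",
              length(x$syllables), x$onset, x$offset))
  invisible(x)
}
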