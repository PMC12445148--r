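#' Protected frequency band around the target
#'
#' The melodic distractor must keep a 1/3-octave guard band between its
#' components and the outermost AM sidebands of the target carrier, to
#' minimize energetic masking.  The band spans from one third octave below
#' the lower sideband of the fastest SAM rate to one third octave above the
#' upper sideband.
#'
#' @param spec a [stimulus_spec()].
#' @param fraction guard width in octaves (default 1/3).
#' @return list with `low_band_max_hz` (distractor low register must stay
#'   below this) and `high_band_min_hz` (high register must stay above it).
#' @export
protected_band <- function(spec, fraction = 1 / 3) {
  fc <- spec$carrier_multiple * spec$base_rate_hz
  am_max <- max(spec$am_multiples) * spec$base_rate_hz
  list(
    low_band_max_hz = (fc - am_max) * 2^(-fraction),
    high_band_min_hz = (fc + am_max) * 2^(fraction)
  )
}

midi_to_hz <- function(m) 440 * 2^((m - 69) / 12)

#' Construct a melody specification
#'
#' @param events tibble/data.frame with columns `pitch_hz` (NA for a rest)
#'   and `duration_beats` (positive integers).
#' @param beat_rate_hz beats per second (default 3.9, five 19.5 Hz AM periods
#'   per beat).
#' @param note_am_rate_hz per-note SAM rate (default 19.5).
#' @return an object of class `melody_spec`.
#' @export
melody_spec <- function(events, beat_rate_hz = 3.9, note_am_rate_hz = 19.5) {
  events <- as_tibble(events)
  stopifnot(all(c("pitch_hz", "duration_beats") %in% names(events)))
  if (any(events$duration_beats != round(events$duration_beats)) ||
      any(events$duration_beats < 1)) {
    abort("duration_beats must be positive integers")
  }
  ppb <- note_am_rate_hz / beat_rate_hz
  if (abs(ppb - round(ppb)) > 1e-9) {
    abort("note_am_rate_hz must be an integer multiple of beat_rate_hz")
  }
  structure(
    list(events = events, beat_rate_hz = beat_rate_hz,
         note_am_rate_hz = note_am_rate_hz),
    class = "melody_spec"
  )
}

#' @export
print.melody_spec <- function(x, ...) {
  n_note <- sum(!is.na(x$events$pitch_hz))
  cat(sprintf(
    "<melody_spec: %d events (%d notes), %g beats @ %g Hz, note AM %g Hz>\n",
    nrow(x$events), n_note, sum(x$events$duration_beats),
    x$beat_rate_hz, x$note_am_rate_hz
  ))
  invisible(x)
}

#' Detect over-repeated phrases
#'
#' A melody is rejected when any contiguous run of `min_len` or more note
#' pitches occurs `max_occurrences + 1` or more times (overlapping counts
#' included).
#'
#' @param pitches numeric vector of note pitches (rests removed).
#' @param min_len minimum phrase length in notes (default 3).
#' @param max_occurrences maximum allowed occurrences (default 2).
#' @return `TRUE` if an over-repeated phrase exists.
#' @export
has_repeated_phrase <- function(pitches, min_len = 3L, max_occurrences = 2L) {
  n <- length(pitches)
  if (n < min_len * 2L) return(FALSE)
  key <- match(pitches, unique(pitches))
  for (len in min_len:(n %/% 2L)) {
    starts <- seq_len(n - len + 1L)
    phrases <- vapply(starts, function(s) {
      paste(key[s:(s + len - 1L)], collapse = ",")
    }, character(1))
    if (max(table(phrases)) > max_occurrences) return(TRUE)
  }
  FALSE
}

melody_register <- function(band, note_am_rate_hz) {
  # keep the AM sidebands, not just the fundamentals, out of the guard band,
  # and restrict melodies to the top octave of the allowed range: low-register
  # lines below ~160 Hz sit close enough together (a whole tone ~ 12 Hz, and a
  # minor third ~ the 19.5 Hz AM sideband offset) that the melody and its
  # matched noise could no longer share a magnitude spectrum bin-wise
  hi <- band$low_band_max_hz - note_am_rate_hz
  c(low = max((band$high_band_min_hz + note_am_rate_hz) / 8, hi / 2),
    high = hi)
}

#' Generate a rule-based melodic distractor
#'
#' Stand-in melody source: a first-order Markov walk over the scale degrees
#' of a diatonic (major) scale, restricted to the register that keeps the low
#' voice (and its 3-octave duplicate) clear of the protected band.  Note
#' durations are whole beats; rests are inserted with probability
#' `rest_prob`.  Candidates containing a phrase repeated more than
#' `max_occurrences` times are rejected and redrawn (bounded attempts).
#' Pitches are 12-tone equal temperament.  Uses the current RNG state.
#'
#' @param spec a [stimulus_spec()] (defines the protected band).
#' @param n_beats total length in beats (default 32).
#' @param beat_rate_hz beats per second (default 3.9).
#' @param note_am_rate_hz per-note SAM rate (default 19.5).
#' @param rest_prob probability that an event is a rest (default 0.15).
#' @param max_attempts redraw budget for the phrase filter (default 50).
#' @return a [melody_spec()].
#' @export
generate_melody <- function(spec = stimulus_spec(), n_beats = 32L,
                            beat_rate_hz = 3.9, note_am_rate_hz = 19.5,
                            rest_prob = 0.15, max_attempts = 50L) {
  band <- protected_band(spec)
  reg <- melody_register(band, note_am_rate_hz)
  midis <- 0:127
  freqs <- midi_to_hz(midis)
  in_reg <- which(freqs >= reg["low"] & freqs <= reg["high"])
  # C-major-pentatonic degrees: no semitone intervals, so spectral lines of
  # neighboring notes stay well separated even in the low register
  scale_pc <- c(0, 2, 4, 7, 9)
  degrees <- in_reg[(midis[in_reg] %% 12) %in% scale_pc]
  if (length(degrees) < 5) abort("register too narrow for a diatonic walk")
  pool <- midis[degrees]

  for (attempt in seq_len(max_attempts)) {
    ev <- list(); beats <- 0L
    pos <- sample.int(length(pool), 1L)
    while (beats < n_beats) {
      d <- sample(c(1L, 1L, 1L, 2L), 1L)
      d <- min(d, n_beats - beats)
      if (runif(1) < rest_prob) {
        ev[[length(ev) + 1L]] <- tibble(pitch_hz = NA_real_, duration_beats = d)
      } else {
        step <- sample(c(-2L, -1L, 0L, 1L, 2L), 1L,
                       prob = c(0.15, 0.3, 0.1, 0.3, 0.15))
        pos <- min(max(pos + step, 1L), length(pool))
        ev[[length(ev) + 1L]] <- tibble(
          pitch_hz = midi_to_hz(pool[pos]), duration_beats = d
        )
      }
      beats <- beats + d
    }
    events <- dplyr::bind_rows(ev)
    pitches <- events$pitch_hz[!is.na(events$pitch_hz)]
    if (length(pitches) >= 2 && !has_repeated_phrase(pitches)) {
      return(melody_spec(events, beat_rate_hz, note_am_rate_hz))
    }
  }
  abort("could not generate a melody passing the phrase filter")
}

#' Transpose a melody into the protected-band-compatible register
#'
#' Shifts the melody by whole octaves until every pitch (with its AM
#' sidebands) fits below the protected band while the 3-octave duplicate sits
#' above it.  Melodies whose span cannot fit are rejected.
#'
#' @param melody a [melody_spec()].
#' @param spec a [stimulus_spec()].
#' @return a [melody_spec()] with transposed pitches, carrying the high
#'   register implicitly (every note is rendered at `f` and `8f`).
#' @export
transpose_and_duplicate <- function(melody, spec = stimulus_spec()) {
  band <- protected_band(spec)
  reg <- melody_register(band, melody$note_am_rate_hz)
  p <- melody$events$pitch_hz
  notes <- !is.na(p)
  if (!any(notes)) return(melody)
  lo <- min(p[notes]); hi <- max(p[notes])
  for (k in -8:8) {
    if (lo * 2^k >= reg["low"] && hi * 2^k <= reg["high"]) {
      out <- melody
      out$events$pitch_hz[notes] <- p[notes] * 2^k
      return(out)
    }
  }
  abort("melody cannot be transposed into the protected-band register",
        class = "multisync_unplaceable_melody")
}

melody_beat_samples <- function(melody, sample_rate_hz) {
  as.integer(round(sample_rate_hz / melody$beat_rate_hz))
}

#' Note/rest + SAM envelope train of a melody
#'
#' Zero during rests; during each note, a cosine-phase SAM envelope
#' completing an integer number of `note_am_rate_hz` periods (the per-beat
#' period count times the note's duration in beats).
#'
#' @param melody a [melody_spec()].
#' @param sample_rate_hz audio rate.
#' @return a [waveform()] (values in \eqn{[0, 1]}).
#' @export
melody_envelope <- function(melody, sample_rate_hz) {
  n_beat <- melody_beat_samples(melody, sample_rate_hz)
  ppb <- round(melody$note_am_rate_hz / melody$beat_rate_hz)
  segs <- lapply(seq_len(nrow(melody$events)), function(j) {
    d <- melody$events$duration_beats[j]
    n <- d * n_beat
    if (is.na(melody$events$pitch_hz[j])) return(numeric(n))
    (1 - cos(2 * pi * ppb * d * (seq_len(n) - 1) / n)) / 2
  })
  waveform(unlist(segs, use.names = FALSE), sample_rate_hz)
}

#' Render a melody as audio
#'
#' Each note is a pure tone emitted simultaneously in the low register and
#' three octaves higher, gated by the note's SAM envelope; rests are silence.
#' Tones are phase-coherent in global time, and because every note completes
#' an integer number of SAM periods the envelope is zero at every note
#' boundary, so rendering is click-free.
#'
#' @param melody a [melody_spec()].
#' @param sample_rate_hz audio rate.
#' @return list with `wave` (a [waveform()], unnormalized: unit note
#'   amplitude per register) and `events` (tibble of note/rest onsets with
#'   `onset_s`, `sample`, `kind`, `pitch_hz`, `duration_beats`,
#'   `beat_index`).
#' @export
render_melody <- function(melody, sample_rate_hz) {
  n_beat <- melody_beat_samples(melody, sample_rate_hz)
  env <- melody_envelope(melody, sample_rate_hz)$samples
  n <- length(env)
  t <- (seq_len(n) - 1) / sample_rate_hz
  x <- numeric(n)
  onsets <- integer(nrow(melody$events))
  beat0 <- integer(nrow(melody$events))
  pos <- 0L
  for (j in seq_len(nrow(melody$events))) {
    d <- melody$events$duration_beats[j]
    len <- d * n_beat
    onsets[j] <- pos + 1L
    beat0[j] <- pos %/% n_beat
    f <- melody$events$pitch_hz[j]
    if (!is.na(f)) {
      idx <- pos + seq_len(len)
      x[idx] <- env[idx] * (sin(2 * pi * f * t[idx]) + sin(2 * pi * 8 * f * t[idx]))
    }
    pos <- pos + len
  }
  events <- tibble(
    onset_s = (onsets - 1) / sample_rate_hz,
    sample = onsets,
    kind = ifelse(is.na(melody$events$pitch_hz), "rest", "note"),
    pitch_hz = melody$events$pitch_hz,
    duration_beats = melody$events$duration_beats,
    beat_index = beat0 + 1L
  )
  list(wave = waveform(x, sample_rate_hz), events = events)
}

#' Beat-occupancy weights of a melody
#'
#' For every distinct note frequency, the proportion of note-carrying beats
#' containing it.  Long or repeated notes therefore weigh more.
#'
#' @param melody a [melody_spec()].
#' @return tibble with `pitch_hz`, `beats`, `weight`.
#' @export
note_weights <- function(melody) {
  ev <- melody$events[!is.na(melody$events$pitch_hz), ]
  if (nrow(ev) == 0) return(tibble(pitch_hz = numeric(), beats = numeric(), weight = numeric()))
  w <- ev |>
    dplyr::group_by(.data$pitch_hz) |>
    dplyr::summarise(beats = sum(.data$duration_beats), .groups = "drop")
  w$weight <- w$beats / sum(w$beats)
  w
}

#' Synthesize the melody-matched noise distractor
#'
#' Sums stationary sinusoids at every distinct note frequency of the melody
#' (both registers), each scaled by the proportion of note beats containing
#' that note and given a random starting phase, then applies the melody's
#' own note/rest + SAM envelope.  The result shares the melody's long-term
#' magnitude spectrum while its frequency content is time-invariant during
#' notes.  Uses the current RNG state for the phases.
#'
#' @param melody a [melody_spec()].
#' @param sample_rate_hz audio rate.
#' @return a [waveform()] on the same amplitude scale as [render_melody()].
#' @export
make_matched_noise <- function(melody, sample_rate_hz) {
  w <- note_weights(melody)
  if (nrow(w) == 0) {
    return(melody_envelope(melody, sample_rate_hz))  # all-rest: silence
  }
  env <- melody_envelope(melody, sample_rate_hz)$samples
  t <- (seq_along(env) - 1) / sample_rate_hz
  x <- numeric(length(env))
  for (j in seq_len(nrow(w))) {
    x <- x + w$weight[j] * (
      sin(2 * pi * w$pitch_hz[j] * t + runif(1, 0, 2 * pi)) +
      sin(2 * pi * 8 * w$pitch_hz[j] * t + runif(1, 0, 2 * pi))
    )
  }
  waveform(x * env, sample_rate_hz)
}

#' Serialize a melody to CSV
#'
#' Rests are written as the literal string `REST` in the `pitch` column.
#'
#' @param melody a [melody_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_melody_csv <- function(melody, path) {
  df <- data.frame(
    pitch = ifelse(is.na(melody$events$pitch_hz), "REST",
                   format(melody$events$pitch_hz, digits = 10)),
    duration_beats = melody$events$duration_beats
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a melody from CSV written by [write_melody_csv()]
#' @param path CSV path.
#' @inheritParams melody_spec
#' @return a [melody_spec()].
#' @export
read_melody_csv <- function(path, beat_rate_hz = 3.9, note_am_rate_hz = 19.5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pitch_num <- suppressWarnings(as.numeric(df$pitch))
  melody_spec(
    tibble(
      pitch_hz = ifelse(df$pitch == "REST", NA_real_, pitch_num),
      duration_beats = as.integer(df$duration_beats)
    ),
    beat_rate_hz = beat_rate_hz, note_am_rate_hz = note_am_rate_hz
  )
}
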