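token_samples <- function(spec) as.integer(round(spec$sample_rate_hz / spec$base_rate_hz))

#' Render one SAM token
#'
#' A token lasts one base-rate period and is rendered on the fractional grid
#' `i/n` (n = samples per token), so the envelope completes exactly
#' `am_multiple` periods and the carrier exactly `carrier_multiple` periods
#' within the token regardless of the sample rate.  The modulator is
#' cosine-phase starting at its minimum, so the token begins and ends at zero
#' amplitude and concatenation is click-free.
#'
#' @param am_index index into `spec$am_multiples`.
#' @param spec a [stimulus_spec()].
#' @return a [waveform()] of duration `1/base_rate_hz`.
#' @export
make_sam_token <- function(am_index, spec) {
  if (!(am_index %in% seq_along(spec$am_multiples))) {
    abort(sprintf("am_index %s out of range", format(am_index)))
  }
  m <- spec$am_multiples[am_index]
  n <- token_samples(spec)
  frac <- (seq_len(n) - 1) / n
  env <- spec$mod_depth * (1 - cos(2 * pi * m * frac)) / 2
  waveform(env * sin(2 * pi * spec$carrier_multiple * frac), spec$sample_rate_hz)
}

#' Build a full target stimulus from a cycle plan
#'
#' Concatenates the tokens of each cycle, applies the per-cycle polarity
#' sign, peak-normalizes, and returns the waveform together with an event
#' table recording every cycle and token onset.
#'
#' @param plan a [cycle_plan()].
#' @return list with elements `wave` (a [waveform()]) and `events` (tibble
#'   with columns `onset_s`, `sample`, `kind` in `{"cycle", "token"}`,
#'   `cycle_index`, `token_index`, `am_index`, `am_multiple`,
#'   `am_nominal_hz`, `polarity`).
#' @export
build_target <- function(plan) {
  validate_cycle_plan(plan)
  spec <- plan$spec
  n_tok <- token_samples(spec)
  tokens <- lapply(seq_along(spec$am_multiples), make_sam_token, spec = spec)
  n_cycles <- length(plan$cycles)
  tpc <- spec$tokens_per_cycle

  samples <- numeric(n_cycles * tpc * n_tok)
  ev <- vector("list", n_cycles)
  pos <- 0L
  for (k in seq_len(n_cycles)) {
    pol <- plan$polarity[k]
    perm <- plan$cycles[[k]]
    cyc <- unlist(lapply(perm, function(i) tokens[[i]]$samples), use.names = FALSE)
    samples[pos + seq_along(cyc)] <- pol * cyc
    tok_start <- pos + (seq_len(tpc) - 1L) * n_tok + 1L
    ev[[k]] <- tibble(
      sample = c(tok_start[1], tok_start),
      kind = c("cycle", rep("token", tpc)),
      cycle_index = k,
      token_index = c(NA_integer_, seq_len(tpc)),
      am_index = c(NA_integer_, perm),
      polarity = pol
    )
    pos <- pos + length(cyc)
  }
  events <- dplyr::bind_rows(ev)
  events$am_multiple <- spec$am_multiples[events$am_index]
  events$am_nominal_hz <- round(events$am_multiple * spec$base_rate_hz)
  events$onset_s <- (events$sample - 1) / spec$sample_rate_hz
  events <- events[, c("onset_s", "sample", "kind", "cycle_index", "token_index",
                       "am_index", "am_multiple", "am_nominal_hz", "polarity")]
  list(wave = peak_normalize(waveform(samples, spec$sample_rate_hz)),
       events = events)
}

#' Concatenation-boundary discontinuities of a target stimulus
#'
#' For every token boundary, reports the jump between the analytic endpoint
#' value of the preceding token (zero by the cosine-envelope integer-period
#' design) and the first sample of the following token.  A clicky
#' concatenation shows up here as a nonzero jump; the smooth evolution of the
#' signal within tokens does not.
#'
#' @param target result of [build_target()].
#' @return numeric vector of absolute jumps, one per interior token boundary.
#' @export
concatenation_steps <- function(target) {
  ev <- target$events[target$events$kind == "token", ]
  starts <- ev$sample[-1]
  abs(target$wave$samples[starts] - 0)
}

#' Magnitude spectrum of a target stimulus
#'
#' With `undo_polarity = TRUE` (default) the per-cycle polarity sign is
#' removed before the FFT: polarity alternation is a square-wave modulation
#' that deliberately splits the carrier line (so it cancels in across-cycle
#' averages), and undoing it restores the single spectral peak at the
#' carrier with sidebands at the carrier plus/minus the AM rates.
#'
#' @param target result of [build_target()].
#' @param undo_polarity remove the per-cycle sign before the FFT.
#' @return tibble with `freq_hz`, `magnitude`.
#' @export
target_spectrum <- function(target, undo_polarity = TRUE) {
  w <- target$wave
  if (undo_polarity) {
    cyc <- target$events[target$events$kind == "cycle", ]
    bounds <- c(cyc$sample, length(w$samples) + 1L)
    s <- w$samples
    for (k in seq_len(nrow(cyc))) {
      idx <- bounds[k]:(bounds[k + 1L] - 1L)
      s[idx] <- s[idx] * cyc$polarity[k]
    }
    w <- waveform(s, w$sample_rate_hz)
  }
  wave_spectrum(w)
}

#' Write a stimulus event table as CSV
#' @param events event tibble from [build_target()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
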