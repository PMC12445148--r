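epoch_freqs <- function(epochs) {
  n <- dim(epochs$data)[3]
  (seq_len(n %/% 2 + 1L) - 1L) * epochs$sample_rate_hz / n
}

#' Nearest FFT bin for a frequency
#' @param epochs an [epoch_set()] (defines the bin grid).
#' @param freq_hz frequency in Hz.
#' @return 1-based bin index into the one-sided spectrum.
#' @export
freq_bin <- function(epochs, freq_hz) {
  n <- dim(epochs$data)[3]
  as.integer(round(freq_hz * n / epochs$sample_rate_hz)) + 1L
}

# unit phasors of the FFT phase: complex array epochs x channels x bins
epoch_phasors <- function(epochs, bins = NULL) {
  d <- dim(epochs$data)
  n_bins_full <- d[3] %/% 2 + 1L
  if (is.null(bins)) bins <- seq_len(n_bins_full)
  out <- array(0i, dim = c(d[1], d[2], length(bins)))
  for (ch in seq_len(d[2])) {
    sp <- mvfft(t(epochs$data[, ch, , drop = TRUE]))  # samples x epochs
    if (d[1] == 1L) sp <- mvfft(matrix(epochs$data[1, ch, ], ncol = 1))
    ph <- sp[bins, , drop = FALSE]
    mod <- Mod(ph)
    mod[mod == 0] <- 1
    out[, ch, ] <- t(ph / mod)
  }
  out
}

plv_from_phasors <- function(ph, idx = NULL) {
  # ph: epochs x channels x bins -> per-channel PLV (channels x bins)
  if (!is.null(idx)) ph <- ph[idx, , , drop = FALSE]
  n <- dim(ph)[1]
  Mod(apply(ph, c(2, 3), sum)) / n
}

new_plv_spectrum <- function(freqs, per_channel, n_epochs, window, fs) {
  structure(
    list(freqs_hz = freqs,
         plv = sqrt(colMeans(per_channel^2)),
         per_channel = per_channel,
         n_epochs = n_epochs, window = window, sample_rate_hz = fs),
    class = "plv_spectrum"
  )
}

#' Phase-locking value spectrum
#'
#' For each channel and frequency bin, the magnitude of the mean unit
#' phasor of the FFT phase across epochs; the spectrum is then aggregated
#' as the root mean square across channels.  Per-channel PLV lies in
#' \eqn{[0, 1]}; the expected value for N uniformly random phases is
#' \eqn{\sqrt{\pi / (4N)}}.  No taper is applied: component frequencies sit
#' on (or within half a bin of) the analysis grid by construction, and a
#' rectangular window avoids leakage-phase bias.
#'
#' @param epochs an [epoch_set()] with at least 2 epochs.
#' @param channels optional channel indices to retain (e.g. scalp channels
#'   surviving bad-channel exclusion).
#' @param bins optional bin indices to restrict computation to.
#' @return an object of class `plv_spectrum`.
#' @export
plv_spectrum <- function(epochs, channels = NULL, bins = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (n_epochs(epochs) < 2) abort("need at least 2 epochs")
  if (!is.null(channels)) {
    epochs$data <- epochs$data[, channels, , drop = FALSE]
  }
  freqs <- epoch_freqs(epochs)
  if (!is.null(bins)) freqs <- freqs[bins]
  ph <- epoch_phasors(epochs, bins)
  per_channel <- plv_from_phasors(ph)
  new_plv_spectrum(freqs, per_channel, n_epochs(epochs), epochs$window,
                   epochs$sample_rate_hz)
}

#' @export
print.plv_spectrum <- function(x, ...) {
  cat(sprintf(
    "<plv_spectrum[%s]: %d bins (%.3g-%.4g Hz), %d channels, %d epochs>\n",
    x$window, length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
    nrow(x$per_channel), x$n_epochs
  ))
  invisible(x)
}

#' @rdname plv_spectrum
#' @param x a `plv_spectrum`.
#' @param ... unused.
#' @export
tidy.plv_spectrum <- function(x, ...) {
  tibble(freq_hz = x$freqs_hz, plv = x$plv, n_epochs = x$n_epochs,
         window = x$window)
}

#' @rdname plv_spectrum
#' @export
glance.plv_spectrum <- function(x, ...) {
  pk <- which.max(replace(x$plv, 1, -Inf))  # ignore DC
  tibble(n_epochs = x$n_epochs, n_channels = nrow(x$per_channel),
         peak_freq_hz = x$freqs_hz[pk], peak_plv = x$plv[pk],
         window = x$window)
}

#' PLV at given frequencies
#' @param spec a [plv_spectrum()].
#' @param freqs_hz frequencies (matched to nearest bin).
#' @return numeric vector of PLV values.
#' @export
plv_at <- function(spec, freqs_hz) {
  idx <- vapply(freqs_hz, function(f) which.min(abs(spec$freqs_hz - f)), 1L)
  spec$plv[idx]
}

#' Carrier (FFR) phase locking with polarity handling
#'
#' Separates the carrier-locked response, whose sign flips with stimulus
#' polarity, from envelope-locked activity, which does not:
#' * `mode = "difference"` (default): consecutive opposite-polarity cycle
#'   epochs are paired and their waveforms subtracted before the PLV, so
#'   envelope-locked components cancel and carrier-locked components
#'   remain.
#' * `mode = "plv-difference"`: the literal per-channel PLV(positive) minus
#'   PLV(negative), aggregated as the RMS of the signed difference.  For
#'   any response with polarity-symmetric statistics its expectation is
#'   near zero; retained for fidelity experiments.
#'
#' @param epochs a cycle-window [epoch_set()] whose metadata has
#'   `polarity`.
#' @param mode `"difference"` or `"plv-difference"`.
#' @param channels optional channel subset.
#' @return a [plv_spectrum()].
#' @export
ffr_plv <- function(epochs, mode = c("difference", "plv-difference"),
                    channels = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$meta$polarity)) abort("epochs lack polarity metadata")
  if (!is.null(channels)) epochs$data <- epochs$data[, channels, , drop = FALSE]
  if (mode == "difference") {
    ord <- order(epochs$meta$trial %||% seq_len(n_epochs(epochs)),
                 epochs$meta$sample %||% seq_len(n_epochs(epochs)))
    pol <- epochs$meta$polarity[ord]
    pos_i <- ord[pol == 1L]
    neg_i <- ord[pol == -1L]
    n_pair <- min(length(pos_i), length(neg_i))
    if (n_pair < 2) abort("need at least 2 polarity pairs")
    if (length(pos_i) != length(neg_i)) {
      warn(sprintf("unpaired polarity epochs: dropping %d",
                   abs(length(pos_i) - length(neg_i))))
    }
    diffed <- epochs$data[pos_i[seq_len(n_pair)], , , drop = FALSE] -
      epochs$data[neg_i[seq_len(n_pair)], , , drop = FALSE]
    es <- epoch_set(diffed, epochs$meta[pos_i[seq_len(n_pair)], ],
                    epochs$sample_rate_hz, epochs$window)
    return(plv_spectrum(es))
  }
  pos <- subset_epochs(epochs, epochs$meta$polarity == 1L)
  neg <- subset_epochs(epochs, epochs$meta$polarity == -1L)
  sp_p <- plv_spectrum(pos)
  sp_n <- plv_spectrum(neg)
  d <- sp_p$per_channel - sp_n$per_channel
  new_plv_spectrum(sp_p$freqs_hz, d, min(sp_p$n_epochs, sp_n$n_epochs),
                   epochs$window, epochs$sample_rate_hz)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frequencies related to the stimulus
#'
#' The frequencies at which stimulus-locked activity (or mains
#' interference) is expected, to be excluded from noise-floor estimation:
#' the token rate and its low harmonics, each AM rate with sidebands at
#' multiples of the token rate, the carrier with its AM and token-rate
#' sidebands, the melody beat rate and its low harmonics (which include the
#' 19.5 Hz note-AM rate), and mains harmonics.  Harmonic and sideband
#' orders are bounded so that, even on the coarse token-window bin grid
#' (every bin a token-rate multiple), unrelated bins remain.
#'
#' @param base_rate_hz token rate (default 6.8).
#' @param beat_rate_hz melody beat rate (default 3.9).
#' @param am_multiples AM rates as token-rate multiples.
#' @param carrier_multiple carrier as a token-rate multiple.
#' @param mains_hz mains fundamentals (default 50 and 60).
#' @param max_harmonic harmonic order kept for the token and beat rates
#'   (default 5, so the 19.5 Hz note AM = 5 x beat is included).
#' @param sideband_order token-rate sideband order around AM rates and
#'   carrier components (default 2).
#' @param max_hz ceiling for the list.
#' @return sorted numeric vector of related frequencies.
#' @export
stimulus_related_freqs <- function(base_rate_hz = 6.8, beat_rate_hz = 3.9,
                                   am_multiples = c(4, 6, 8, 10, 12),
                                   carrier_multiple = 76,
                                   mains_hz = c(50, 60),
                                   max_harmonic = 5L, sideband_order = 2L,
                                   max_hz = 4000) {
  sb <- -sideband_order:sideband_order
  k <- unique(c(
    seq_len(max_harmonic),                                 # token rate + harmonics
    as.vector(outer(am_multiples, sb, "+")),               # AM rates +/- sidebands
    as.vector(outer(carrier_multiple + c(0, am_multiples, -am_multiples),
                    sb, "+"))                              # carrier +/- sidebands
  ))
  f <- c(
    base_rate_hz * k[k > 0],
    beat_rate_hz * seq_len(max_harmonic),
    unlist(lapply(mains_hz, function(m) m * seq_len(floor(max_hz / m))))
  )
  sort(unique(f[f <= max_hz]))
}

#' Noise floor of a PLV spectrum
#'
#' The mean PLV over frequency bins unrelated to the stimulus, taken within
#' a neighborhood of each frequency of interest.  Bins within half a bin
#' width of any related frequency (and the DC bin) are excluded.
#'
#' @param spec a [plv_spectrum()].
#' @param freqs_hz frequencies of interest.
#' @param related_hz related frequencies to exclude (default
#'   [stimulus_related_freqs()]).
#' @param neighborhood_bins half-width of the neighborhood (default 20).
#' @return numeric vector: one floor estimate per frequency of interest.
#' @export
noise_floor <- function(spec, freqs_hz,
                        related_hz = stimulus_related_freqs(),
                        neighborhood_bins = 20L) {
  stopifnot(inherits(spec, "plv_spectrum"))
  df <- if (length(spec$freqs_hz) > 1) diff(spec$freqs_hz[1:2]) else
    abort("spectrum has a single bin")
  vapply(freqs_hz, function(f) {
    k <- which.min(abs(spec$freqs_hz - f))
    nb <- seq(max(2L, k - neighborhood_bins), min(length(spec$freqs_hz),
                                                  k + neighborhood_bins))
    unrelated <- nb[vapply(nb, function(j) {
      all(abs(spec$freqs_hz[j] - related_hz) > df / 2)
    }, logical(1))]
    if (length(unrelated) == 0) abort("no unrelated bins in the neighborhood")
    mean(spec$plv[unrelated])
  }, numeric(1))
}

#' Equalize trial counts across conditions by bootstrap subsampling
#'
#' Conditions with more epochs are randomly subsampled to the smallest
#' condition's count across `n_iter` bootstrap iterations, and the PLV is
#' averaged over iterations, keeping noise floors comparable across
#' conditions.  A condition already at the minimum count is computed in a
#' single pass.  Uses the current RNG state.
#'
#' @param sets named list of [epoch_set()]s.
#' @param n_iter bootstrap iterations (default 600).
#' @param bins optional bin indices (shared window length assumed) to
#'   restrict computation to; strongly recommended when only a few
#'   frequencies are needed.
#' @param channels optional channel subset.
#' @return named list of [plv_spectrum()]s with equalized effective counts.
#' @export
equalize_and_average <- function(sets, n_iter = 600L, bins = NULL,
                                 channels = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1)
  counts <- vapply(sets, n_epochs, 1L)
  n_min <- min(counts)
  if (n_min < 2) abort("smallest condition has fewer than 2 epochs")
  lapply(sets, function(es) {
    if (!is.null(channels)) es$data <- es$data[, channels, , drop = FALSE]
    freqs <- epoch_freqs(es)
    if (!is.null(bins)) freqs <- freqs[bins]
    ph <- epoch_phasors(es, bins)
    ne <- dim(ph)[1]
    if (ne == n_min) {
      per_channel <- plv_from_phasors(ph)
    } else {
      acc <- 0
      for (it in seq_len(n_iter)) {
        acc <- acc + plv_from_phasors(ph, sample.int(ne, n_min))
      }
      per_channel <- acc / n_iter
    }
    new_plv_spectrum(freqs, per_channel, n_min, es$window, es$sample_rate_hz)
  })
}

#' Envelope-change PLV by AM-rate jump
#'
#' Groups two-token epochs into the signed AM-difference classes (with the
#' default five rates: +/-14, +/-27, +/-41, +/-54 Hz nominal), equalizes
#' the class counts by bootstrap subsampling, and reports the PLV at the
#' token-rate bin per class.
#'
#' @param epochs a two-token [epoch_set()] with `delta_nominal_hz`
#'   metadata.
#' @param base_rate_hz envelope-change frequency (default 6.8).
#' @param n_iter bootstrap iterations (default 600).
#' @param channels optional channel subset.
#' @return tibble with `delta_nominal_hz`, `n_epochs` (raw class count),
#'   `n_equalized`, `plv`; empty classes are absent.
#' @export
ecfr_by_delta <- function(epochs, base_rate_hz = 6.8, n_iter = 600L,
                          channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(epochs$meta$delta_nominal_hz)) {
    abort("epochs lack delta_nominal_hz metadata (need two-token windows)")
  }
  classes <- sort(unique(epochs$meta$delta_nominal_hz))
  sets <- lapply(classes, function(d) {
    subset_epochs(epochs, epochs$meta$delta_nominal_hz == d)
  })
  names(sets) <- as.character(classes)
  bin <- freq_bin(epochs, base_rate_hz)
  eq <- equalize_and_average(sets, n_iter = n_iter, bins = bin,
                             channels = channels)
  tibble(
    delta_nominal_hz = classes,
    n_epochs = vapply(sets, n_epochs, 1L),
    n_equalized = vapply(eq, function(s) s$n_epochs, 1L),
    plv = vapply(eq, function(s) s$plv[1], numeric(1))
  )
}

#' Correct/incorrect asymmetry index
#'
#' \eqn{AI = (C - I) / (C + I)} for a synchronization measure computed
#' separately on correct and incorrect trials (with matched effective trial
#' counts via [equalize_and_average()]).  Undefined when \eqn{C + I = 0}.
#'
#' @param plv_correct,plv_incorrect PLV values (vectorized).
#' @return asymmetry indices in \eqn{[-1, 1]} (NA where undefined).
#' @export
asymmetry_index <- function(plv_correct, plv_incorrect) {
  s <- plv_correct + plv_incorrect
  ifelse(s == 0, NA_real_, (plv_correct - plv_incorrect) / s)
}

#' Participant-level asymmetry table with inclusion rules
#'
#' Applies the analysis inclusion rules: a participant contributes an
#' asymmetry index for a component only when (a) their error rate is at
#' least `min_error_rate` (participants with too few error trials are
#' excluded entirely) and (b) at least one of the correct/incorrect PLVs
#' exceeds that participant's noise floor for the component.
#'
#' @param df tibble with columns `participant`, `component`, `plv_correct`,
#'   `plv_incorrect`, `noise_floor`, `error_rate`.
#' @param min_error_rate minimum error-trial proportion (default 0.15).
#' @return the input with `ai` and `included` columns added.
#' @export
asymmetry_table <- function(df, min_error_rate = 0.15) {
  df <- as_tibble(df)
  df$ai <- asymmetry_index(df$plv_correct, df$plv_incorrect)
  df$included <- df$error_rate >= min_error_rate &
    (df$plv_correct > df$noise_floor | df$plv_incorrect > df$noise_floor) &
    !is.na(df$ai)
  df
}
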