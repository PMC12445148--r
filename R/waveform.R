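#' Waveform container
#'
#' A waveform is a numeric sample vector with a sample rate, peak-bounded to
#' \eqn{|x| \le 1} after [peak_normalize()].  All stimulus synthesis functions
#' return this class.
#'
#' @param samples numeric vector of amplitudes (dimensionless).
#' @param sample_rate_hz sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate_hz) {
  stopifnot(is.numeric(samples), length(sample_rate_hz) == 1L, sample_rate_hz > 0)
  structure(
    list(samples = as.numeric(samples), sample_rate_hz = sample_rate_hz),
    class = "waveform"
  )
}

#' @export
length.waveform <- function(x) length(x$samples)

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf(
    "<waveform: %d samples @ %g Hz (%.3f s), peak %.3g>\n",
    length(x$samples), x$sample_rate_hz,
    length(x$samples) / x$sample_rate_hz, max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param x a [waveform()].
#' @return duration in seconds.
#' @export
wave_duration <- function(x) length(x$samples) / x$sample_rate_hz

#' Peak-normalize a waveform
#'
#' Scales so that \eqn{\max|x| = 1}; an all-zero waveform is returned
#' unchanged.  The applied gain is recorded in the `gain` attribute.
#'
#' @param x a [waveform()].
#' @return a `waveform` with unit peak.
#' @export
peak_normalize <- function(x) {
  stopifnot(inherits(x, "waveform"))
  pk <- max(abs(x$samples))
  g <- if (pk > 0) 1 / pk else 1
  out <- waveform(x$samples * g, x$sample_rate_hz)
  attr(out, "gain") <- g
  out
}

#' Root-mean-square amplitude
#' @param x a [waveform()] or numeric vector.
#' @return scalar RMS.
#' @export
wave_rms <- function(x) {
  s <- if (inherits(x, "waveform")) x$samples else x
  sqrt(mean(s^2))
}

#' Magnitude spectrum of a waveform
#'
#' Single-sided linear-magnitude FFT spectrum, returned as a tibble so it can
#' be filtered and plotted directly.
#'
#' @param x a [waveform()].
#' @return tibble with columns `freq_hz`, `magnitude`.
#' @export
wave_spectrum <- function(x) {
  stopifnot(inherits(x, "waveform"))
  n <- length(x$samples)
  sp <- fft(x$samples)
  half <- seq_len(floor(n / 2) + 1L)
  tibble(
    freq_hz = (half - 1) * x$sample_rate_hz / n,
    magnitude = Mod(sp[half]) * 2 / n
  )
}

#' Amplitude at arbitrary frequencies by coherent projection
#'
#' Projects the signal onto complex exponentials at the requested frequencies
#' (a direct DFT at off-grid frequencies), returning the equivalent sinusoid
#' amplitude.  Used to compare spectra at note frequencies that are not FFT
#' bin centers.
#'
#' @param x a [waveform()].
#' @param freqs_hz frequencies to evaluate.
#' @return numeric vector of amplitudes, one per frequency.
#' @export
wave_amplitude_at <- function(x, freqs_hz) {
  stopifnot(inherits(x, "waveform"))
  n <- length(x$samples)
  t <- (seq_len(n) - 1) / x$sample_rate_hz
  vapply(freqs_hz, function(f) {
    Mod(sum(x$samples * exp(-2i * pi * f * t))) * 2 / n
  }, numeric(1))
}

#' Write a waveform as 16-bit PCM WAV
#'
#' Minimal mono RIFF/WAVE writer (16-bit PCM).  Samples are clipped to
#' \eqn{[-1, 1]} before quantization.
#'
#' @param x a [waveform()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path) {
  stopifnot(inherits(x, "waveform"))
  s <- pmin(pmax(x$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  fs <- as.integer(round(x$sample_rate_hz))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 2L, con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV written by [write_wav()]
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (!identical(hdr, "RIFF")) abort("not a RIFF file")
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) abort("not a WAVE file")
  fs <- NA_integer_
  repeat {
    chunk <- readChar(con, 4)
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(chunk, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      fs <- readBin(con, "integer", size = 4, endian = "little")
      invisible(readBin(con, "raw", n = size - 8))
      if (fmt[1] != 1L || fmt[2] != 1L) abort("only mono 16-bit PCM supported")
    } else if (identical(chunk, "data")) {
      pcm <- readBin(con, "integer", n = size / 2, size = 2, endian = "little")
      return(waveform(pcm / 32767, fs))
    } else {
      invisible(readBin(con, "raw", n = size))
    }
  }
}
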