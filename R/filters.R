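#' Butterworth second-order sections
#'
#' Designs a digital Butterworth low- or high-pass analytically (analog
#' prototype poles, frequency prewarping, bilinear transform) and returns
#' cascaded biquad sections.  Transfer-function (b, a) forms of high-order
#' Butterworth filters are numerically unusable at the very low relative
#' cutoffs this package needs (e.g. 0.1 Hz at 256 Hz); pole-pair sections
#' stay well conditioned.
#'
#' @param n filter order.
#' @param fc cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @param type `"low"` or `"high"`.
#' @return matrix with one row per section: columns `b0 b1 b2 a1 a2`
#'   (`a0` = 1).
#' @export
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(fc > 0, fc < fs / 2)
  wa <- 2 * fs * tan(pi * fc / fs)      # prewarped analog cutoff
  k <- seq_len(n)
  p0 <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-circle prototype poles
  if (type == "low") {
    pa <- wa * p0
    za <- complex(0)                    # zeros at infinity -> z = -1
    ka <- wa^n
    z_digital_zero <- -1
  } else {
    pa <- wa / p0
    za <- rep(0 + 0i, n)                # zeros at s = 0 -> z = +1
    ka <- 1
    z_digital_zero <- 1
  }
  c2 <- 2 * fs
  pd <- (c2 + pa) / (c2 - pa)
  kd <- Re(ka * prod(c2 - za) / prod(c2 - pa))
  zd <- rep(z_digital_zero, n)

  # pair conjugate poles into biquads (one real pole if n is odd)
  is_real <- abs(Im(pd)) < 1e-12
  cplx <- pd[!is_real & Im(pd) > 0]
  real_p <- Re(pd[is_real])
  sections <- list()
  for (p in cplx) {
    sections[[length(sections) + 1L]] <- c(
      1, -2 * z_digital_zero, 1,        # (z - z0)^2
      -2 * Re(p), Mod(p)^2
    )
  }
  for (p in real_p) {
    sections[[length(sections) + 1L]] <- c(1, -z_digital_zero, 0, -p, 0)
  }
  sos <- do.call(rbind, sections)
  colnames(sos) <- c("b0", "b1", "b2", "a1", "a2")
  # fold the overall gain into the first section
  sos[1, 1:3] <- sos[1, 1:3] * kd
  sos
}

#' Zero-phase filtering through second-order sections
#'
#' Applies [signal::filtfilt()] once per biquad of `sos`, giving an overall
#' zero-phase response with the squared magnitude of the designed filter.
#' The signal is extended at both ends by odd reflection over several time
#' constants of the slowest pole before filtering, so edge transients decay
#' in the padding rather than in the data.
#'
#' @param x numeric signal.
#' @param sos section matrix from [butter_sos()].
#' @return filtered signal.
#' @export
sos_filtfilt <- function(x, sos) {
  n <- length(x)
  # settle length from the slowest pole of the cascade
  r <- apply(sos, 1, function(s) {
    max(Mod(polyroot(c(s[5], s[4], 1))))
  })
  r <- min(max(r), 1 - 1e-9)
  tau <- -1 / log(r)
  padlen <- min(n - 2L, as.integer(ceiling(6 * tau)))
  if (padlen > 0) {
    pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
    xp <- c(pre, x, post)
  } else {
    xp <- x
  }
  for (s in seq_len(nrow(sos))) {
    flt <- signal::Arma(b = sos[s, 1:3], a = c(1, sos[s, 4:5]))
    xp <- as.numeric(signal::filtfilt(flt, xp))
  }
  xp[padlen + seq_len(n)]
}

zero_phase_bandpass <- function(x, band, fs, order) {
  if (!is.na(band[1]) && band[1] > 0) {
    x <- sos_filtfilt(x, butter_sos(order, band[1], fs, "high"))
  }
  if (!is.na(band[2]) && band[2] < fs / 2) {
    x <- sos_filtfilt(x, butter_sos(order, band[2], fs, "low"))
  }
  x
}
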