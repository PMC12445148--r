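#' Band-pass filter and mastoid re-reference
#'
#' Zero-phase Butterworth band-pass (default 1--3000 Hz, order 4 applied
#' forward-backward as cascaded second-order sections, see
#' [butter_sos()]), then re-referencing of every channel to the average of
#' the left and right mastoids.
#'
#' @param eeg an [eeg_data()].
#' @param band two-element numeric, Hz.
#' @param order Butterworth order of each section (default 4).
#' @return an [eeg_data()] with filtered, re-referenced data.
#' @export
bandpass_and_reref <- function(eeg, band = c(1, 3000), order = 4L) {
  stopifnot(inherits(eeg, "eeg_data"))
  fs <- eeg$sample_rate_hz
  if (band[2] >= fs / 2) {
    abort("upper band edge must be below the Nyquist frequency")
  }
  mast <- match(eeg$mastoid_labels, eeg$channel_labels)
  if (anyNA(mast)) abort("mastoid channels missing")
  x <- eeg$data
  for (ch in seq_len(nrow(x))) {
    x[ch, ] <- zero_phase_bandpass(x[ch, ], band, fs, order)
  }
  ref <- colMeans(x[mast, , drop = FALSE])
  x <- sweep(x, 2, ref, "-")
  out <- eeg
  out$data <- x
  out
}

hurst_rs <- function(x, max_scales = 8L) {
  # rescaled-range estimate on the cumulative-sum profile
  n <- length(x)
  sizes <- unique(floor(n / 2^(seq_len(max_scales) - 1)))
  sizes <- sizes[sizes >= 16]
  if (length(sizes) < 3) return(NA_real_)
  rs <- vapply(sizes, function(m) {
    k <- n %/% m
    seg <- matrix(x[seq_len(k * m)], nrow = m)
    vals <- apply(seg, 2, function(s) {
      s <- s - mean(s)
      z <- cumsum(s)
      r <- max(z) - min(z)
      sdev <- sd(s)
      if (sdev == 0) NA_real_ else r / sdev
    })
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

#' Detect noisy channels via FASTER-style statistics
#'
#' Per-scalp-channel z-scores of (a) variance, (b) mean correlation with the
#' other scalp channels, and (c) a rescaled-range Hurst exponent; a channel
#' exceeding `threshold` in absolute z on any statistic is flagged.  The
#' z-scores are robust (median/MAD), so a gross outlier cannot mask itself
#' by inflating the scale at small channel counts.  Flagged channels should
#' be excluded (not interpolated) downstream.
#'
#' @param eeg an [eeg_data()].
#' @param threshold z-score threshold (default 3).
#' @param max_samples cap on samples used for the statistics (speed).
#' @return tibble with one row per scalp channel: `channel`, `label`, the
#'   three statistics, their z-scores, and `bad`.
#' @export
detect_bad_channels <- function(eeg, threshold = 3, max_samples = 65536L) {
  stopifnot(inherits(eeg, "eeg_data"))
  sc <- scalp_channels(eeg)
  if (length(sc) < 8) abort("need at least 8 scalp channels")
  n_use <- min(ncol(eeg$data), max_samples)
  x <- eeg$data[sc, seq_len(n_use), drop = FALSE]
  v <- apply(x, 1, var)
  cm <- cor(t(x))
  diag(cm) <- NA
  mc <- rowMeans(cm, na.rm = TRUE)
  h <- apply(x, 1, hurst_rs)
  zs <- function(s) {
    # robust (median/MAD) z: with few channels a gross outlier inflates the
    # plain SD enough to hide itself, so mean/SD scoring cannot reach |z| > 3
    ctr <- stats::median(s, na.rm = TRUE)
    scl <- stats::mad(s, na.rm = TRUE)
    if (!is.finite(scl) || scl == 0) return(rep(0, length(s)))
    (s - ctr) / scl
  }
  zv <- zs(v); zc <- zs(mc); zh <- zs(h)
  tibble(
    channel = sc, label = eeg$channel_labels[sc],
    variance = v, correlation = mc, hurst = h,
    z_variance = zv, z_correlation = zc, z_hurst = zh,
    bad = abs(zv) > threshold | abs(zc) > threshold |
      (is.finite(zh) & abs(zh) > threshold)
  )
}

#' Drop channels from a recording
#' @param eeg an [eeg_data()].
#' @param labels channel labels to remove.
#' @return an [eeg_data()] without those channels.
#' @export
drop_channels <- function(eeg, labels) {
  keep <- !(eeg$channel_labels %in% labels)
  out <- eeg
  out$data <- eeg$data[keep, , drop = FALSE]
  out$channel_labels <- eeg$channel_labels[keep]
  out
}

#' Epoch container
#'
#' Epochs-by-channels-by-samples array plus per-epoch metadata.  Built by
#' [extract_epochs()]; consumed by the phase-locking analyses.
#'
#' @param data 3-d numeric array (epochs x channels x samples).
#' @param meta tibble with one row per epoch.
#' @param sample_rate_hz sampling rate.
#' @param window window kind string.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, meta, sample_rate_hz, window) {
  stopifnot(length(dim(data)) == 3, nrow(meta) == dim(data)[1])
  structure(
    list(data = data, meta = as_tibble(meta),
         sample_rate_hz = sample_rate_hz, window = window),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set[%s]: %d epochs x %d channels x %d samples @ %g Hz>\n",
    x$window, d[1], d[2], d[3], x$sample_rate_hz
  ))
  invisible(x)
}

#' Number of epochs
#' @param x an [epoch_set()].
#' @return integer count.
#' @export
n_epochs <- function(x) dim(x$data)[1]

#' Subset an epoch set
#' @param x an [epoch_set()].
#' @param idx epoch indices or logical mask.
#' @return an [epoch_set()].
#' @export
subset_epochs <- function(x, idx) {
  if (is.logical(idx)) idx <- which(idx)
  epoch_set(x$data[idx, , , drop = FALSE], x$meta[idx, ],
            x$sample_rate_hz, x$window)
}

#' Extract timescale-specific epochs
#'
#' Epochs are individualized per synchronization level:
#' * `"cycle"` — one cycle (`tokens_per_cycle / base_rate` s), locked to
#'   each cycle start: carrier / FFR analysis.
#' * `"token"` — one token (`1 / base_rate` s) locked to the onsets of the
#'   tokens at one AM rate (`rate`): envelope-following analysis.
#' * `"two-token"` — two tokens, one window per token pair (aligned to the
#'   starts of even-indexed tokens, so windows are centered on the
#'   transitions and never overlap): envelope-change analysis.  Each epoch
#'   is tagged with the signed AM-rate jump it spans.
#' * `"note"` — one melody beat locked to distractor note/beat onsets:
#'   melody-beat and note-AM analysis.
#'
#' Epochs extending past the recording are dropped (count in the
#' `n_dropped` attribute).
#'
#' @param eeg an [eeg_data()] whose `meta` holds the paradigm grid.
#' @param window one of `"cycle"`, `"token"`, `"two-token"`, `"note"`.
#' @param rate nominal AM rate in Hz (token windows only).
#' @param last_cycles if given, keep only epochs from the last `last_cycles`
#'   cycles of each trial (e.g. 6: after two pattern repeats).
#' @param trials optional trial subset.
#' @return an [epoch_set()]; metadata includes `trial`, `cycle`, `polarity`,
#'   `delta_nominal_hz` (two-token), `g`, `correct`, `condition`, `context`.
#' @export
extract_epochs <- function(eeg, window = c("cycle", "token", "two-token", "note"),
                           rate = NULL, last_cycles = NULL, trials = NULL) {
  window <- match.arg(window)
  stopifnot(inherits(eeg, "eeg_data"))
  m <- eeg$meta
  if (is.null(m$samples_per_token)) abort("eeg$meta lacks the paradigm grid")
  ev <- eeg$events
  if (!is.null(trials)) ev <- ev[ev$trial %in% trials, ]

  if (window == "cycle") {
    sel <- ev[ev$kind == "cycle", ]
    len <- m$samples_per_token * m$tokens_per_cycle
  } else if (window == "token") {
    if (is.null(rate)) abort("token windows need `rate` (nominal Hz)")
    sel <- ev[ev$kind == "token" & !is.na(ev$am_nominal_hz) &
                ev$am_nominal_hz == rate, ]
    len <- m$samples_per_token
  } else if (window == "two-token") {
    sel <- ev[ev$kind == "token", ]
    sel <- sel[order(sel$trial, sel$token), ]
    first <- sel$token %% 2L == 1L  # 1-based: tokens 1,3,5,... open each pair
    pair_ok <- first & c(sel$token[-1] == sel$token[-nrow(sel)] + 1L, FALSE) &
      c(sel$trial[-1] == sel$trial[-nrow(sel)], FALSE)
    second <- which(pair_ok) + 1L
    sel_first <- sel[pair_ok, ]
    sel_first$delta_am_multiple <- sel$am_multiple[second] - sel_first$am_multiple
    sel_first$delta_nominal_hz <-
      round(sel_first$delta_am_multiple * m$base_rate_hz)
    sel <- sel_first
    len <- 2L * m$samples_per_token
  } else {
    sel <- ev[ev$kind == "note", ]
    len <- m$samples_per_beat
  }
  if (!is.null(last_cycles) && window != "note") {
    keep_from <- m$n_cycles - last_cycles + 1L
    sel <- sel[!is.na(sel$cycle) & sel$cycle >= keep_from, ]
  }
  ok <- sel$sample + len - 1L <= ncol(eeg$data)
  n_dropped <- sum(!ok)
  sel <- sel[ok, ]
  if (nrow(sel) == 0) abort("no epochs matched")

  arr <- array(0, dim = c(nrow(sel), nrow(eeg$data), len))
  for (e in seq_len(nrow(sel))) {
    arr[e, , ] <- eeg$data[, sel$sample[e] + seq_len(len) - 1L]
  }
  meta_cols <- intersect(
    c("trial", "cycle", "token", "am_multiple", "am_nominal_hz", "polarity",
      "delta_am_multiple", "delta_nominal_hz", "g", "correct", "condition",
      "context", "sample"),
    names(sel)
  )
  out <- epoch_set(arr, sel[, meta_cols], eeg$sample_rate_hz, window)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "channel_labels") <- eeg$channel_labels
  out
}
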