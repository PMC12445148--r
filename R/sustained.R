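#' Slow-band preprocessing for the sustained pattern response
#'
#' Low-pass filters the continuous recording at `band[2]` (fifth-order
#' zero-phase Butterworth) at the acquisition rate, decimates to nominally
#' 256 Hz, applies the `band[1]` high-pass on the continuous decimated data
#' (where the extremely low relative cutoff is numerically stable and the
#' record is long relative to the corner period), re-references to the
#' average of all retained scalp channels, then extracts per-trial epochs
#' (1 s prestimulus through the end of the trial) and subtracts the
#' prestimulus baseline.  The executed stage order is recorded in the
#' `stages` attribute.
#'
#' @param eeg an [eeg_data()] with trial events and paradigm metadata.
#' @param band slow band in Hz (default `c(0.1, 110)`).
#' @param target_fs_hz nominal output rate (default 256; the nearest
#'   integer decimation factor is used and the achieved rate returned).
#' @param prestim_s prestimulus baseline duration (default 1 s).
#' @param order Butterworth order (default 5).
#' @param exclude_channels labels to drop before re-referencing.
#' @return an object of class `sustained_trials`: trials x channels x
#'   samples array, output rate, prestimulus sample count.
#' @export
preprocess_sustained <- function(eeg, band = c(0.1, 110), target_fs_hz = 256,
                                 prestim_s = 1, order = 5L,
                                 exclude_channels = NULL) {
  stopifnot(inherits(eeg, "eeg_data"))
  fs <- eeg$sample_rate_hz
  m <- eeg$meta
  if (is.null(m$samples_per_token)) abort("eeg$meta lacks the paradigm grid")
  pre <- as.integer(round(prestim_s * fs))
  trial_len <- m$samples_per_token * m$tokens_per_cycle * m$n_cycles
  starts <- eeg$events$sample[eeg$events$kind == "trial"]
  if (length(starts) == 0) abort("no trial events")
  if (any(starts - pre < 1)) abort("insufficient prestimulus data")
  if (any(starts + trial_len - 1 > ncol(eeg$data))) abort("trial exceeds recording")

  keep <- setdiff(eeg$channel_labels, c(exclude_channels, eeg$mastoid_labels))
  rows <- match(keep, eeg$channel_labels)
  stages <- character()

  lp <- butter_sos(order, band[2], fs, "low")
  x <- eeg$data[rows, , drop = FALSE]
  for (ch in seq_len(nrow(x))) x[ch, ] <- sos_filtfilt(x[ch, ], lp)
  stages <- c(stages, "lowpass")

  fac <- max(1L, as.integer(round(fs / target_fs_hz)))
  fs_out <- fs / fac
  x <- x[, seq(1, ncol(x), by = fac), drop = FALSE]
  stages <- c(stages, "downsample")

  hp <- butter_sos(order, band[1], fs_out, "high")
  for (ch in seq_len(nrow(x))) x[ch, ] <- sos_filtfilt(x[ch, ], hp)
  stages <- c(stages, "highpass")

  x <- sweep(x, 2, colMeans(x), "-")  # average reference over retained scalp
  stages <- c(stages, "rereference")

  pre_out <- pre %/% fac
  len_out <- (pre + trial_len) %/% fac
  starts_out <- (starts - 1L) %/% fac + 1L
  arr <- array(0, dim = c(length(starts), length(rows), len_out))
  base_idx <- seq_len(pre_out)
  for (tr in seq_along(starts)) {
    seg <- x[, starts_out[tr] - pre_out + seq_len(len_out) - 1L, drop = FALSE]
    arr[tr, , ] <- seg - rowMeans(seg[, base_idx, drop = FALSE])
  }
  stages <- c(stages, "baseline")

  out <- structure(
    list(data = arr, sample_rate_hz = fs_out, prestim_samples = pre_out,
         channel_labels = keep,
         trial = eeg$events$trial[eeg$events$kind == "trial"],
         context = if ("context" %in% names(eeg$events)) {
           eeg$events$context[eeg$events$kind == "trial"]
         } else rep(NA_character_, length(starts))),
    class = "sustained_trials"
  )
  attr(out, "stages") <- stages
  out
}

#' @export
print.sustained_trials <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<sustained_trials: %d trials x %d channels x %d samples @ %g Hz>\n",
    d[1], d[2], d[3], x$sample_rate_hz
  ))
  invisible(x)
}

#' Reject high-power trials
#'
#' Single-pass rejection of trials whose average power (mean square over
#' channels and samples) exceeds the across-trial mean by more than
#' `n_sd` standard deviations.  One-sided: only power excesses are
#' rejected.
#'
#' @param trials a `sustained_trials` object.
#' @param n_sd rejection threshold in standard deviations (default 2).
#' @return the retained `sustained_trials`; rejected indices in the
#'   `rejected` attribute.
#' @export
reject_high_power_trials <- function(trials, n_sd = 2) {
  stopifnot(inherits(trials, "sustained_trials"))
  if (dim(trials$data)[1] < 5) abort("need at least 5 trials")
  pw <- apply(trials$data, 1, function(m) mean(m^2))
  bad <- pw > mean(pw) + n_sd * sd(pw)
  out <- trials
  out$data <- trials$data[!bad, , , drop = FALSE]
  out$trial <- trials$trial[!bad]
  out$context <- trials$context[!bad]
  attr(out, "stages") <- c(attr(trials, "stages"), "reject")
  attr(out, "rejected") <- which(bad)
  out
}

#' Denoising source separation biased to trial-repeatable activity
#'
#' Low-pass filters the trials at `lowpass_hz`, then performs DSS with the
#' covariance of the across-trial average as the bias function: the data
#' are whitened by the total covariance (components below a relative rank
#' tolerance discarded), the biased covariance is eigendecomposed in
#' whitened space, and the data are projected onto the leading `n_keep`
#' components and back to sensor space.
#'
#' @param trials a `sustained_trials` object.
#' @param n_keep number of components to keep (default 5; reduced with a
#'   warning if the data rank is lower).
#' @param lowpass_hz pre-DSS low-pass (default 30 Hz, fifth-order
#'   zero-phase Butterworth); `NULL` to skip.
#' @param rank_tol relative eigenvalue tolerance for whitening (default
#'   1e-9).
#' @return the denoised `sustained_trials`; component eigenvalues, spatial
#'   filters and patterns in the `dss` attribute.
#' @export
dss_trial_average <- function(trials, n_keep = 5L, lowpass_hz = 30,
                              rank_tol = 1e-9) {
  stopifnot(inherits(trials, "sustained_trials"))
  arr <- trials$data
  d <- dim(arr)
  stages <- attr(trials, "stages")
  if (!is.null(lowpass_hz)) {
    lp <- butter_sos(5, lowpass_hz, trials$sample_rate_hz, "low")
    for (tr in seq_len(d[1])) {
      for (ch in seq_len(d[2])) {
        arr[tr, ch, ] <- sos_filtfilt(arr[tr, ch, ], lp)
      }
    }
    stages <- c(stages, "lowpass30")
  }
  # total covariance pooled over trials, bias covariance from trial average
  c0 <- matrix(0, d[2], d[2])
  avg <- matrix(0, d[2], d[3])
  for (tr in seq_len(d[1])) {
    xt <- arr[tr, , , drop = TRUE]
    c0 <- c0 + tcrossprod(xt)
    avg <- avg + xt
  }
  c0 <- c0 / (d[1] * d[3])
  avg <- avg / d[1]
  c1 <- tcrossprod(avg) / d[3]

  e0 <- eigen(c0, symmetric = TRUE)
  keep_w <- e0$values > rank_tol * max(e0$values)
  r <- sum(keep_w)
  if (r < n_keep) {
    warn(sprintf("data rank %d below n_keep = %d; keeping %d", r, n_keep, r))
    n_keep <- r
  }
  w <- e0$vectors[, keep_w, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep_w]), r)
  e1 <- eigen(crossprod(w, c1 %*% w), symmetric = TRUE)
  filt <- w %*% e1$vectors                 # spatial filters, bias-sorted
  patt <- c0 %*% filt                      # corresponding patterns
  fk <- filt[, seq_len(n_keep), drop = FALSE]
  ak <- patt[, seq_len(n_keep), drop = FALSE]
  proj <- ak %*% t(fk)

  out <- trials
  for (tr in seq_len(d[1])) {
    out$data[tr, , ] <- proj %*% arr[tr, , , drop = TRUE]
  }
  attr(out, "stages") <- c(stages, "dss")
  attr(out, "dss") <- list(eigenvalues = e1$values, filters = filt,
                           patterns = patt, n_keep = n_keep)
  out
}

#' RMS-across-channels sustained time course
#'
#' The sustained response: root mean square across channels of the
#' across-trial average.
#'
#' @param trials a `sustained_trials` object (typically after
#'   [dss_trial_average()]).
#' @return an object of class `sustained_result`: tibble with `time_s`
#'   (relative to stimulus onset) and `rms` plus the stage trace.
#' @export
sustained_timecourse <- function(trials) {
  stopifnot(inherits(trials, "sustained_trials"))
  avg <- apply(trials$data, c(2, 3), mean)
  rms <- sqrt(colMeans(avg^2))
  out <- structure(
    list(
      timecourse = tibble(
        time_s = (seq_along(rms) - 1 - trials$prestim_samples) /
          trials$sample_rate_hz,
        rms = rms
      ),
      sample_rate_hz = trials$sample_rate_hz,
      n_trials = dim(trials$data)[1]
    ),
    class = "sustained_result"
  )
  attr(out, "stages") <- c(attr(trials, "stages"), "rms")
  out
}

#' @export
print.sustained_result <- function(x, ...) {
  cat(sprintf(
    "<sustained_result: %d samples @ %g Hz, %d trials>\n",
    nrow(x$timecourse), x$sample_rate_hz, x$n_trials
  ))
  invisible(x)
}

#' @rdname sustained_timecourse
#' @param x a `sustained_result`.
#' @param ... unused.
#' @export
tidy.sustained_result <- function(x, ...) x$timecourse

#' Pre/post-transition difference statistic
#'
#' Mean of the sustained time course over the third and fourth cycles after
#' the transition (`[t + 2T, t + 4T)`) minus the mean over the two cycles
#' before it (`[t - 2T, t)`), where `T` is the cycle duration.  For
#' random-random trials the same windows are applied at the nominal
#' transition time.
#'
#' @param result a `sustained_result` (or tibble with `time_s`, `rms`).
#' @param transition_s transition time relative to stimulus onset.
#' @param cycle_s cycle duration in seconds.
#' @return scalar difference statistic.
#' @export
transition_difference <- function(result, transition_s, cycle_s) {
  tc <- if (inherits(result, "sustained_result")) result$timecourse else
    as_tibble(result)
  t <- tc$time_s
  pre <- t >= transition_s - 2 * cycle_s & t < transition_s
  post <- t >= transition_s + 2 * cycle_s & t < transition_s + 4 * cycle_s
  if (!any(pre) || !any(post) ||
      transition_s - 2 * cycle_s < min(t) ||
      transition_s + 4 * cycle_s > max(t) + 1 / 256) {
    abort("transition windows fall outside the time course")
  }
  mean(tc$rms[post]) - mean(tc$rms[pre])
}

#' Bootstrap floor for the transition statistic
#'
#' Distribution of [transition_difference()] at uniformly drawn valid
#' nominal transition points, as a floor for the observed statistic.  Uses
#' the current RNG state.
#'
#' @param result a `sustained_result`.
#' @param cycle_s cycle duration in seconds.
#' @param n_boot bootstrap draws (default 1000).
#' @param range_s optional two-element limits for the drawn transition
#'   times (defaults to the widest valid range within the stimulus).
#' @param probs percentile envelope to report (default 2.5% and 97.5%).
#' @return list with `samples`, `envelope` (named quantiles), `n_boot`.
#' @export
bootstrap_transition_floor <- function(result, cycle_s, n_boot = 1000L,
                                       range_s = NULL,
                                       probs = c(0.025, 0.975)) {
  tc <- result$timecourse
  lo <- min(tc$time_s) + 2 * cycle_s
  hi <- max(tc$time_s) - 4 * cycle_s
  if (!is.null(range_s)) {
    lo <- max(lo, range_s[1]); hi <- min(hi, range_s[2])
  }
  if (hi <= lo) abort("time course too short for the bootstrap windows")
  samples <- vapply(runif(n_boot, lo, hi), function(tt) {
    transition_difference(result, tt, cycle_s)
  }, numeric(1))
  list(samples = samples, envelope = quantile(samples, probs), n_boot = n_boot)
}
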