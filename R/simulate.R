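#' Parameters of the synthetic EEG generator
#'
#' Defines the phase-locked components, their amplitudes (arbitrary units
#' against a background-noise RMS of `noise_scale`), the attention model,
#' and the recording geometry.  Components: `ffr` (carrier-locked,
#' polarity-flipping), `efr` (one per AM rate, token-onset-locked), `ecfr`
#' (token-transition-locked, at the base rate), `beat` (melody-beat-locked)
#' and `distractor_efr` (note-AM-locked, 19.5 Hz).
#'
#' Attention is a per-trial state \eqn{g \in [0, 1]}; components listed in
#' `attention$coupled` are scaled by `g` (target components) or `1 - g`
#' (distractor components), and the response label is drawn with
#' \eqn{P(\mathrm{correct}) = \mathrm{logistic}(a + b g)}.  Component
#' amplitudes default to values that place every peak clearly above the
#' phase-locking noise floor at desk-scale epoch counts.
#'
#' @param n_channels number of scalp channels (default 64).
#' @param sample_rate_hz simulation rate (default 16384, so the 1--3000 Hz
#'   analysis band is representable).
#' @param amplitudes named numeric vector for components
#'   `ffr`, `efr`, `ecfr`, `beat`, `distractor_efr`.
#' @param phases named numeric vector of locking phases (radians).
#' @param polarity_flip components whose sign inverts with stimulus polarity
#'   (default `"ffr"`).
#' @param noise_exponent 1/f spectral slope of the background (default 1).
#' @param noise_scale background RMS per channel (default 1).
#' @param channel_gains optional per-scalp-channel topography weights;
#'   drawn as a smooth random gain vector if `NULL`.
#' @param attention list with logistic intercept `a`, slope `b`,
#'   `coupled` (the components whose amplitude tracks the attention state),
#'   and the uniform attention-state range `g_min`, `g_max`.
#' @param ecfr_delta_scaling if `TRUE`, the envelope-change component in
#'   each token is scaled by the normalized AM-rate jump |dAM| into that
#'   token, so class-wise PLV grows with |dAM|.
#' @param condition_gain named per-condition gain applied to the `ecfr`
#'   amplitude, encoding graded distraction (target-alone > matched noise >
#'   melody).
#' @param sustained_step amplitude (a.u.) of a pattern-evoked sustained
#'   (DC) shift added from the transition cycle onward in random-pattern
#'   trials (default 0: no sustained pattern response, the null case).
#' @param beat_rate_hz melody beat rate (default 3.9).
#' @param n_cycles cycles per trial (default 12, the EEG task).
#' @param pre_s silence (noise only) before each trial, seconds.
#' @param gap_s silence after each trial, seconds.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_channels = 64L,
                       sample_rate_hz = 16384,
                       amplitudes = c(ffr = 0.5, efr = 0.5, ecfr = 0.5,
                                      beat = 0.5, distractor_efr = 0.5),
                       phases = c(ffr = 0, efr = 0, ecfr = 0,
                                  beat = 0, distractor_efr = 0),
                       polarity_flip = "ffr",
                       noise_exponent = 1,
                       noise_scale = 1,
                       channel_gains = NULL,
                       attention = list(a = -1.5, b = 4,
                                        coupled = c("ecfr", "beat"),
                                        g_min = 0, g_max = 1),
                       ecfr_delta_scaling = FALSE,
                       condition_gain = c("target-alone" = 1,
                                          "target+noise" = 0.7,
                                          "target+melody" = 0.45),
                       sustained_step = 0,
                       beat_rate_hz = 3.9,
                       n_cycles = 12L,
                       pre_s = 0.25,
                       gap_s = 0.25) {
  if (any(amplitudes < 0)) abort("amplitudes must be >= 0")
  if (!is.null(channel_gains) && any(!is.finite(channel_gains))) {
    abort("channel_gains must be finite")
  }
  structure(
    list(n_channels = as.integer(n_channels), sample_rate_hz = sample_rate_hz,
         amplitudes = amplitudes, phases = phases,
         polarity_flip = polarity_flip, noise_exponent = noise_exponent,
         noise_scale = noise_scale, channel_gains = channel_gains,
         attention = attention, ecfr_delta_scaling = ecfr_delta_scaling,
         condition_gain = condition_gain, sustained_step = sustained_step,
         beat_rate_hz = beat_rate_hz,
         n_cycles = as.integer(n_cycles), pre_s = pre_s, gap_s = gap_s),
    class = "sim_params"
  )
}

#' Simulate the per-trial attention series
#'
#' Draws an attention state \eqn{g \sim U(0, 1)} per trial and a
#' correct/incorrect label through the logistic link
#' \eqn{P(\mathrm{correct}) = \mathrm{logistic}(a + b g)}; `g` is returned
#' with the label so that recovery analyses have ground truth.
#'
#' @param n_trials number of trials.
#' @param params a [sim_params()].
#' @param seed mandatory integer seed.
#' @return tibble with `trial`, `g`, `correct`.
#' @export
simulate_attention_series <- function(n_trials, params = sim_params(), seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  set.seed(seed)
  att <- params$attention
  g <- runif(n_trials, att$g_min %||% 0, att$g_max %||% 1)
  p <- plogis(att$a + att$b * g)
  tibble(trial = seq_len(n_trials), g = g, correct = runif(n_trials) < p)
}

#' 1/f noise
#'
#' Gaussian noise spectrally shaped to a power spectral density proportional
#' to \eqn{f^{-\alpha}}, scaled to the requested RMS.  Uses the current RNG
#' state.
#'
#' @param n length in samples.
#' @param sample_rate_hz sampling rate.
#' @param exponent PSD slope \eqn{\alpha} (default 1).
#' @param rms target root-mean-square amplitude.
#' @return numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, sample_rate_hz, exponent = 1, rms = 1) {
  m <- stats::nextn(n)  # pad to a 2-3-5-smooth length: FFT cost, then crop
  white <- rnorm(m)
  sp <- fft(white)
  shape <- c(0, pmin(seq_len(m - 1), m - seq_len(m - 1))^(-exponent / 2))
  x <- Re(fft(sp * shape, inverse = TRUE))[seq_len(n)] / m
  x * rms / sqrt(mean(x^2))
}

smooth_gains <- function(n) {
  raw <- rnorm(n)
  if (n < 5) return(1 + 0.3 * raw / max(sd(raw), 1))
  k <- stats::filter(raw, rep(1 / 5, 5), circular = TRUE)
  1 + 0.3 * as.numeric(k) / sd(k)
}

trial_source <- function(perms, params, spec, g, condition,
                         context = "random-random",
                         transition_cycle = NA_integer_) {
  fs <- params$sample_rate_hz
  n_tok <- as.integer(round(fs / spec$base_rate_hz))
  tpc <- spec$tokens_per_cycle
  n_cycles <- length(perms)
  len <- n_cycles * tpc * n_tok
  i <- seq_len(len) - 1L
  tok_frac <- (i %% n_tok) / n_tok
  tok_id <- i %/% n_tok
  cyc_id <- tok_id %/% tpc
  pol <- rep_len(c(1, -1), n_cycles)[cyc_id + 1L]
  m_seq <- unlist(lapply(perms, function(p) spec$am_multiples[p]),
                  use.names = FALSE)
  m_tok <- m_seq[tok_id + 1L]

  A <- params$amplitudes
  ph <- params$phases
  coupled <- params$attention$coupled
  tgain <- function(comp) if (comp %in% coupled) g else 1
  dgain <- function(comp) if (comp %in% coupled) 1 - g else 1
  flip <- function(comp) if (comp %in% params$polarity_flip) pol else 1

  src <- numeric(len)
  if (A["ffr"] > 0) {
    src <- src + A["ffr"] * tgain("ffr") * flip("ffr") *
      sin(2 * pi * spec$carrier_multiple * tok_frac + ph["ffr"])
  }
  if (A["efr"] > 0) {
    src <- src + A["efr"] * tgain("efr") * flip("efr") *
      sin(2 * pi * m_tok * tok_frac + ph["efr"])
  }
  if (A["ecfr"] > 0) {
    cg <- params$condition_gain
    cgain <- if (!is.null(condition) && condition %in% names(cg)) cg[[condition]] else 1
    dscale <- 1
    if (params$ecfr_delta_scaling) {
      dm <- abs(diff(m_seq))
      dmax <- max(spec$am_multiples) - min(spec$am_multiples)
      per_tok <- c(mean(dm) / dmax, dm / dmax)
      dscale <- per_tok[tok_id + 1L]
    }
    src <- src + A["ecfr"] * cgain * tgain("ecfr") * dscale * flip("ecfr") *
      sin(2 * pi * tok_frac + ph["ecfr"])
  }
  if (params$sustained_step != 0 && identical(context, "random-pattern") &&
      !is.na(transition_cycle)) {
    src <- src + params$sustained_step * (cyc_id >= transition_cycle - 1L)
  }
  has_distractor <- !is.null(condition) && !identical(condition, "target-alone")
  if (has_distractor) {
    n_beat <- as.integer(round(fs / params$beat_rate_hz))
    b_frac <- (i %% n_beat) / n_beat
    if (A["beat"] > 0) {
      src <- src + A["beat"] * dgain("beat") * sin(2 * pi * b_frac + ph["beat"])
    }
    if (A["distractor_efr"] > 0) {
      ppb <- 5  # 19.5 Hz note AM = 5 periods per 3.9 Hz beat
      src <- src + A["distractor_efr"] * dgain("distractor_efr") *
        sin(2 * pi * ppb * b_frac + ph["distractor_efr"])
    }
  }
  src
}

#' Simulate a multichannel EEG recording for a block of trials
#'
#' For each trial of `plan`, a stimulus cycle plan is drawn, an attention
#' state is sampled, and every phase-locked component contributes a
#' sinusoid locked to its event class: the FFR to carrier cycles
#' (sign-flipping with stimulus polarity), EFRs to token onsets at the
#' token's AM rate, the ECFR to token transitions at the base rate, and the
#' melody beat and 19.5 Hz note-AM components to the distractor beat grid
#' (distractor conditions only).  The source is spread over channels by the
#' topography gains and added to independent per-channel 1/f noise; the
#' mastoid channels carry noise only.  Events record every trial, cycle,
#' token (with AM identity, polarity, and signed AM jump) and beat onset.
#'
#' @param plan a [build_block()] tibble (or any tibble with `condition` and
#'   `context` columns, one row per trial).
#' @param params a [sim_params()].
#' @param spec a [stimulus_spec()]; its audio sample rate is ignored
#'   (events are laid out on the EEG sampling grid).
#' @param seed mandatory integer seed; the same seed reproduces the
#'   recording bit for bit.
#' @return an [eeg_data()]; the per-trial attention series is in
#'   `attr(, "attention")` and also on the trial events.
#' @export
simulate_recording <- function(plan, params = sim_params(),
                               spec = stimulus_spec(), seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory")
  n_trials <- nrow(plan)
  att <- simulate_attention_series(n_trials, params, seed = seed)
  # keep drawing from the same stream after the attention series
  fs <- params$sample_rate_hz
  n_tok <- as.integer(round(fs / spec$base_rate_hz))
  tpc <- spec$tokens_per_cycle
  trial_len <- params$n_cycles * tpc * n_tok
  pre <- as.integer(round(params$pre_s * fs))
  gap <- as.integer(round(params$gap_s * fs))
  slot <- pre + trial_len + gap
  total <- n_trials * slot

  n_scalp <- params$n_channels
  gains <- params$channel_gains
  if (is.null(gains)) gains <- smooth_gains(n_scalp)
  if (length(gains) != n_scalp) abort("channel_gains length must equal n_channels")
  all_gains <- c(gains, 0, 0)  # mastoids carry no locked signal
  labels <- c(sprintf("Ch%02d", seq_len(n_scalp)), "M1", "M2")

  perms_list <- vector("list", n_trials)
  patterns <- enumerate_patterns(spec)
  for (tr in seq_len(n_trials)) {
    ctx <- if ("context" %in% names(plan)) plan$context[tr] else "random-random"
    pat <- NULL
    if (!is.null(plan$pattern_id) && !is.na(plan$pattern_id[tr])) {
      pat <- patterns[plan$pattern_id[tr], ]
    }
    cp <- cycle_plan(spec, params$n_cycles, ctx,
                     transition_cycle = min(5L, params$n_cycles),
                     pattern = pat)
    perms_list[[tr]] <- cp$cycles
  }

  data <- matrix(0, nrow = n_scalp + 2L, ncol = total)
  for (ch in seq_len(n_scalp + 2L)) {
    data[ch, ] <- one_over_f_noise(total, fs, params$noise_exponent,
                                   params$noise_scale)
  }

  ev <- vector("list", n_trials)
  for (tr in seq_len(n_trials)) {
    cond <- if ("condition" %in% names(plan)) plan$condition[tr] else "target-alone"
    ctx <- if ("context" %in% names(plan)) plan$context[tr] else "random-random"
    g <- att$g[tr]
    src <- trial_source(perms_list[[tr]], params, spec, g, cond,
                        context = ctx,
                        transition_cycle = min(5L, params$n_cycles))
    idx <- (tr - 1L) * slot + pre + seq_len(trial_len)
    data[, idx] <- data[, idx] + all_gains %o% src

    start <- idx[1]
    m_seq <- unlist(lapply(perms_list[[tr]], function(p) spec$am_multiples[p]),
                    use.names = FALSE)
    n_tok_trial <- length(m_seq)
    tok_start <- start + (seq_len(n_tok_trial) - 1L) * n_tok
    tok_cycle <- (seq_len(n_tok_trial) - 1L) %/% tpc + 1L
    pol_cycle <- rep_len(c(1L, -1L), params$n_cycles)
    delta <- c(NA_integer_, diff(m_seq))
    rows <- list(
      tibble(sample = start, kind = "trial", trial = tr, cycle = NA_integer_,
             token = NA_integer_, am_multiple = NA_integer_,
             polarity = NA_integer_, delta_am_multiple = NA_integer_,
             condition = cond, context = ctx, g = g, correct = att$correct[tr]),
      tibble(sample = start + (seq_len(params$n_cycles) - 1L) * tpc * n_tok,
             kind = "cycle", trial = tr, cycle = seq_len(params$n_cycles),
             token = NA_integer_, am_multiple = NA_integer_,
             polarity = pol_cycle, delta_am_multiple = NA_integer_,
             condition = cond, context = ctx, g = g, correct = att$correct[tr]),
      tibble(sample = tok_start, kind = "token", trial = tr,
             cycle = tok_cycle, token = seq_len(n_tok_trial),
             am_multiple = m_seq, polarity = pol_cycle[tok_cycle],
             delta_am_multiple = delta,
             condition = cond, context = ctx, g = g, correct = att$correct[tr])
    )
    if (!identical(cond, "target-alone")) {
      n_beat <- as.integer(round(fs / params$beat_rate_hz))
      n_beats <- trial_len %/% n_beat
      rows[[4]] <- tibble(
        sample = start + (seq_len(n_beats) - 1L) * n_beat,
        kind = "note", trial = tr, cycle = NA_integer_,
        token = seq_len(n_beats), am_multiple = NA_integer_,
        polarity = NA_integer_, delta_am_multiple = NA_integer_,
        condition = cond, context = ctx, g = g, correct = att$correct[tr]
      )
    }
    ev[[tr]] <- dplyr::bind_rows(rows)
  }
  events <- dplyr::bind_rows(ev)
  events$am_nominal_hz <- round(events$am_multiple * spec$base_rate_hz)
  events$delta_nominal_hz <- round(events$delta_am_multiple * spec$base_rate_hz)

  out <- eeg_data(
    data, fs, labels, events,
    mastoid_labels = c("M1", "M2"),
    meta = list(
      base_rate_hz = spec$base_rate_hz,
      samples_per_token = n_tok,
      tokens_per_cycle = tpc,
      n_cycles = params$n_cycles,
      transition_cycle = min(5L, params$n_cycles),
      samples_per_beat = as.integer(round(fs / params$beat_rate_hz)),
      beat_rate_hz = params$beat_rate_hz,
      carrier_multiple = spec$carrier_multiple,
      am_multiples = spec$am_multiples
    )
  )
  attr(out, "attention") <- att
  out
}
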