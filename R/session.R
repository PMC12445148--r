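#' Mix target and distractor at a given SNR
#'
#' Scales the distractor so that broadband RMS(target) / RMS(distractor)
#' equals `10^(snr_db/20)` and returns the peak-normalized sum.  The
#' distractor is cropped or zero-padded to the target length.  By default
#' RMS is taken over the full stimulus duration (distractor rests included);
#' `reference = "active"` instead uses the distractor's nonzero portion.
#'
#' @param target a [waveform()].
#' @param distractor a [waveform()] at the same sample rate, or `NULL` for
#'   the target-alone condition (identity).
#' @param snr_db signal-to-noise ratio in dB.
#' @param reference `"broadband"` (default) or `"active"`.
#' @return a peak-normalized [waveform()]; attributes `distractor_gain` and
#'   `gain` (normalization) record the applied scaling.
#' @export
mix_at_snr <- function(target, distractor, snr_db, reference = c("broadband", "active")) {
  reference <- match.arg(reference)
  stopifnot(inherits(target, "waveform"))
  if (is.null(distractor)) return(peak_normalize(target))
  stopifnot(inherits(distractor, "waveform"))
  if (distractor$sample_rate_hz != target$sample_rate_hz) {
    abort("sample rates must match")
  }
  n <- length(target$samples)
  d <- distractor$samples
  d <- if (length(d) >= n) d[seq_len(n)] else c(d, numeric(n - length(d)))
  d_rms <- if (reference == "active") {
    act <- abs(d) > 0
    if (!any(act)) 0 else sqrt(mean(d[act]^2))
  } else {
    sqrt(mean(d^2))
  }
  if (d_rms == 0) abort("silent distractor: SNR undefined")
  g <- wave_rms(target) / (d_rms * 10^(snr_db / 20))
  out <- peak_normalize(waveform(target$samples + g * d, target$sample_rate_hz))
  attr(out, "distractor_gain") <- g
  out
}

#' Assemble a block of trials
#'
#' A laboratory block pairs 120 random-pattern trials — one for each of the
#' 5! = 120 pattern permutations per context — with 120 random-random
#' trials, the conditions (e.g. target-alone, target+melody, target+noise,
#' or SNR levels) spread evenly across trials, and the trial order shuffled.
#' Uses the current RNG state.
#'
#' @param conditions character vector of condition labels.
#' @param spec a [stimulus_spec()].
#' @param n_per_context trials per context (default 120; must be a multiple
#'   of `length(conditions)` and, for the pattern context, is matched to the
#'   permutation set by recycling the lexicographic enumeration).
#' @param snr_db named numeric vector or single value giving each
#'   condition's SNR (NA for target-alone); optional bookkeeping only.
#' @return a `block_plan`: tibble with columns `trial_index`, `condition`,
#'   `context`, `pattern_id` (index into [enumerate_patterns()], NA for
#'   random-random), `snr_db`.
#' @export
build_block <- function(conditions = "target-alone", spec = stimulus_spec(),
                        n_per_context = 120L, snr_db = NA_real_) {
  n_perm <- factorial(spec$tokens_per_cycle)
  if (n_per_context %% length(conditions) != 0) {
    abort("n_per_context must be divisible by the number of conditions")
  }
  pattern_ids <- rep_len(seq_len(n_perm), n_per_context)
  if (n_per_context == n_perm) pattern_ids <- seq_len(n_perm)
  cond_seq <- rep(conditions, each = n_per_context / length(conditions))
  snr_of <- function(cond) {
    if (length(snr_db) > 1 && !is.null(names(snr_db))) unname(snr_db[cond]) else snr_db[1]
  }
  plan <- dplyr::bind_rows(
    tibble(
      condition = cond_seq,
      context = "random-pattern",
      pattern_id = sample(pattern_ids)
    ),
    tibble(
      condition = cond_seq,
      context = "random-random",
      pattern_id = NA_integer_
    )
  )
  plan <- plan[sample.int(nrow(plan)), ]
  plan$snr_db <- unname(vapply(plan$condition, snr_of, numeric(1)))
  plan$trial_index <- seq_len(nrow(plan))
  out <- plan[, c("trial_index", "condition", "context", "pattern_id", "snr_db")]
  class(out) <- c("block_plan", class(out))
  out
}

#' Score one speeded-task trial
#'
#' A hidden counter starts at 1000 points when audio playback begins and
#' counts down linearly, reaching zero at the end of the response window
#' (stimulus duration plus `timeout_s`).  A correct response earns the
#' points left on the counter, an incorrect response loses them, and no
#' response within `timeout_s` after stimulus offset loses a flat 350
#' points.
#'
#' @param correct logical, or `NA` for no response.
#' @param rt_s reaction time from audio onset, seconds.
#' @param stimulus_duration_s stimulus duration, seconds.
#' @param timeout_s response window after stimulus offset (default 1 s).
#' @return integer score in \eqn{[-1000, 1000] \cup \{-350\}}.
#' @export
score_trial <- function(correct, rt_s, stimulus_duration_s, timeout_s = 1) {
  if (is.na(correct)) return(-350L)
  if (rt_s < 0) abort("rt_s must be >= 0")
  rate <- 1000 / (stimulus_duration_s + timeout_s)
  counter <- max(0, 1000 - round(rate * rt_s))
  as.integer(if (correct) counter else -counter)
}

#' Rationalized arcsine units
#'
#' Variance-stabilizing transform of a proportion-correct score
#' (Studebaker): \eqn{\theta = \arcsin\sqrt{X/(N+1)} +
#' \arcsin\sqrt{(X+1)/(N+1)}}, \eqn{RAU = (146/\pi)\,\theta - 23}.  Chance
#' on a two-alternative task (X = N/2) maps to approximately 50, and
#' RAU(X) + RAU(N - X) = 100.
#'
#' @param correct_count number correct, `0 <= X <= N` (vectorized).
#' @param n_trials number of trials N.
#' @return RAU score(s).
#' @export
rau <- function(correct_count, n_trials) {
  if (any(correct_count < 0) || any(correct_count > n_trials)) {
    abort("correct_count must lie in [0, n_trials]")
  }
  theta <- asin(sqrt(correct_count / (n_trials + 1))) +
    asin(sqrt((correct_count + 1) / (n_trials + 1)))
  (146 / pi) * theta - 23
}

#' Summarize a trial table
#'
#' Per condition/context accuracy (proportion and RAU), median reaction
#' time, and total score.
#'
#' @param trials tibble with columns `condition`, `context`, `response`,
#'   `correct` (logical, NA for no response), `rt_s`, `score`.
#' @return tibble, one row per condition x context.
#' @export
summarize_block <- function(trials) {
  trials |>
    dplyr::group_by(.data$condition, .data$context) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_scored = sum(!is.na(.data$correct)),
      prop_correct = mean(.data$correct[!is.na(.data$correct)]),
      rau = rau(sum(.data$correct, na.rm = TRUE), sum(!is.na(.data$correct))),
      median_rt_s = stats::median(.data$rt_s[!is.na(.data$correct)]),
      total_score = sum(.data$score),
      .groups = "drop"
    )
}
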