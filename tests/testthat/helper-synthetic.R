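# Shared fixture builders.  All synthetic data are generated in code at test
# time; sample rates are chosen as multiples of the 6.8 Hz token rate so that
# analysis bins fall exactly on component frequencies.

audio_spec <- function() stimulus_spec(sample_rate_hz = 8160)

eeg_fs <- 2040  # = 6.8 * 300; carrier 516.8 Hz < Nyquist

small_params <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 8L, sample_rate_hz = eeg_fs, n_cycles = 12L,
         pre_s = 0.2, gap_s = 0.1),
    list(...)
  )
  do.call(sim_params, args)
}

flat_plan <- function(n_trials, condition = "target-alone",
                      context = "random-random") {
  tibble::tibble(
    condition = condition,
    context = rep_len(context, n_trials),
    pattern_id = ifelse(rep_len(context, n_trials) == "random-pattern",
                        seq_len(n_trials), NA_integer_)
  )
}

# epoch_set of pure white-noise epochs (uniform FFT phases)
noise_epochs <- function(n_ep, n_ch = 4L, n_s = 200L, fs = 1000) {
  arr <- array(rnorm(n_ep * n_ch * n_s), dim = c(n_ep, n_ch, n_s))
  epoch_set(arr, tibble::tibble(epoch = seq_len(n_ep)), fs, "cycle")
}

# epoch_set with a phase-locked sinusoid at FFT bin `k` (1-based bin k+1)
# plus a FIXED noise realization shared across calls via `noise`
locked_epochs <- function(amp, k, noise, fs = 1000) {
  d <- dim(noise)
  s <- sin(2 * pi * k * (seq_len(d[3]) - 1) / d[3])
  arr <- noise + rep(amp * s, each = d[1] * d[2])
  epoch_set(arr, tibble::tibble(epoch = seq_len(d[1])), fs, "cycle")
}
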