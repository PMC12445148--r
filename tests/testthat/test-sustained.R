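sus_fs <- 2048

sus_params <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 8L, sample_rate_hz = sus_fs, n_cycles = 12L,
         pre_s = 1.2, gap_s = 0.3),
    list(...)
  )
  do.call(sim_params, args)
}

step_params <- function(h, ...) {
  sus_params(
    sustained_step = h, noise_scale = 0.5,
    amplitudes = c(ffr = 0, efr = 0, ecfr = 0, beat = 0, distractor_efr = 0),
    # zero-mean topography: a spatially uniform shift would be removed by
    # the average reference and carry no information anyway
    channel_gains = rep(c(1, -1), 4), ...
  )
}

pattern_plan <- function(n) {
  tibble::tibble(condition = "target-alone", context = "random-pattern",
                 pattern_id = seq_len(n))
}

T_cyc <- 5 / 6.8

test_that("slow-band preprocessing hits 256 Hz, zeroes baselines, and logs stages", {
  p <- sus_params()
  eeg <- simulate_recording(flat_plan(6), p, stimulus_spec(), seed = 71)
  eeg$data <- eeg$data + 5  # constant offset must not survive
  st <- preprocess_sustained(eeg)
  expect_equal(st$sample_rate_hz, 256)
  expect_equal(attr(st, "stages"),
               c("lowpass", "downsample", "highpass", "rereference", "baseline"))
  base <- st$data[, , seq_len(st$prestim_samples)]
  expect_lt(max(abs(apply(base, c(1, 2), mean))), 1e-8)
  # mastoids are not among retained channels
  expect_false(any(c("M1", "M2") %in% st$channel_labels))
})

test_that("the slow band rejects a 200 Hz tone by at least 20 dB", {
  p <- sus_params(noise_scale = 0,
                  amplitudes = c(ffr = 0, efr = 0, ecfr = 0, beat = 0,
                                 distractor_efr = 0))
  eeg <- simulate_recording(flat_plan(2), p, stimulus_spec(), seed = 72)
  t <- (seq_len(ncol(eeg$data)) - 1) / sus_fs
  tone <- sin(2 * pi * 200 * t)
  # inject on one channel: the average reference would cancel a common tone
  eeg$data[1, ] <- eeg$data[1, ] + tone
  st <- preprocess_sustained(eeg)
  out_rms <- stats::sd(st$data[1, 1, ])
  expect_lt(20 * log10(out_rms / stats::sd(tone)), -20)
})

test_that("preprocessing requires a full prestimulus window", {
  p <- sus_params(pre_s = 0.3)
  eeg <- simulate_recording(flat_plan(2), p, stimulus_spec(), seed = 73)
  expect_error(preprocess_sustained(eeg, prestim_s = 1), "prestimulus")
})

test_that("trial rejection is one-sided, single-pass, and at the normal tail rate", {
  mk <- function(pw) {
    n_tr <- length(pw)
    arr <- array(rnorm(n_tr * 3 * 128), dim = c(n_tr, 3, 128))
    for (tr in seq_len(n_tr)) arr[tr, , ] <- arr[tr, , ] * sqrt(pw[tr])
    structure(list(data = arr, sample_rate_hz = 256, prestim_samples = 0,
                   channel_labels = c("a", "b", "c"),
                   trial = seq_len(n_tr), context = rep("x", n_tr)),
              class = "sustained_trials")
  }
  set.seed(74)
  even <- mk(rep(1, 20))
  expect_length(attr(reject_high_power_trials(even), "rejected"), 0)

  hot <- mk(c(rep(1, 19), 100))
  expect_equal(attr(reject_high_power_trials(hot), "rejected"), 20L)

  # low-power outliers are kept: rejection is upper-tail only
  cold <- mk(c(rep(1, 19), 1e-4))
  expect_length(attr(reject_high_power_trials(cold), "rejected"), 0)

  set.seed(75)
  gauss <- mk(pmax(rnorm(400, 1, 0.1), 0.1))
  frac <- length(attr(reject_high_power_trials(gauss), "rejected")) / 400
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.045)

  expect_error(reject_high_power_trials(mk(rep(1, 3))), "at least 5")
})

test_that("DSS recovers a planted repeatable source better than any raw channel", {
  set.seed(76)
  n_tr <- 30; n_ch <- 10; n_s <- 512
  src <- sin(2 * pi * 3 * (0:(n_s - 1)) / 256) *
    exp(-((0:(n_s - 1)) - 256)^2 / 8000)
  mix <- rnorm(n_ch)
  arr <- array(0, dim = c(n_tr, n_ch, n_s))
  for (tr in seq_len(n_tr)) {
    arr[tr, , ] <- mix %o% src + matrix(rnorm(n_ch * n_s, sd = 1.5), n_ch)
  }
  st <- structure(list(data = arr, sample_rate_hz = 256, prestim_samples = 0,
                       channel_labels = paste0("C", 1:n_ch),
                       trial = seq_len(n_tr), context = rep("x", n_tr)),
                  class = "sustained_trials")
  std <- dss_trial_average(st, n_keep = 1)
  d <- attr(std, "dss")
  avg <- apply(arr, c(2, 3), mean)
  comp1 <- as.numeric(crossprod(d$filters[, 1, drop = FALSE], avg))
  cor_dss <- abs(stats::cor(src, comp1))
  cor_raw <- max(abs(stats::cor(src, t(avg))))
  expect_gt(cor_dss, cor_raw)
  expect_gt(cor_dss, 0.9)
})

test_that("full-rank DSS is the identity and low-rank data trims with a warning", {
  set.seed(77)
  n_tr <- 8; n_ch <- 6; n_s <- 256
  arr <- array(rnorm(n_tr * n_ch * n_s), dim = c(n_tr, n_ch, n_s))
  st <- structure(list(data = arr, sample_rate_hz = 256, prestim_samples = 0,
                       channel_labels = paste0("C", 1:n_ch),
                       trial = seq_len(n_tr), context = rep("x", n_tr)),
                  class = "sustained_trials")
  std <- dss_trial_average(st, n_keep = n_ch, lowpass_hz = NULL)
  expect_equal(std$data, arr, tolerance = 1e-10)

  # noise-free identical trials whose repeatable activity spans fewer
  # dimensions than n_keep are reconstructed exactly
  sources <- matrix(rnorm(4 * n_s), 4)
  one <- matrix(rnorm(n_ch * 4), n_ch) %*% sources
  arr2 <- arr
  for (tr in seq_len(n_tr)) arr2[tr, , ] <- one
  st2 <- st; st2$data <- arr2
  std2 <- suppressWarnings(dss_trial_average(st2, n_keep = 5, lowpass_hz = NULL))
  expect_lt(max(abs(std2$data - arr2)) / max(abs(arr2)), 0.01)

  # rank-deficient input: keep what exists, warn
  lowrank <- st
  for (ch in 2:n_ch) lowrank$data[, ch, ] <- lowrank$data[, 1, ] * ch
  expect_warning(dss_trial_average(lowrank, n_keep = 5, lowpass_hz = NULL),
                 "rank")
})

test_that("the transition statistic is zero for a stationary time course", {
  res <- structure(
    list(timecourse = tibble::tibble(time_s = seq(-1, 9, by = 1 / 256),
                                     rms = 0.5),
         sample_rate_hz = 256, n_trials = 10),
    class = "sustained_result"
  )
  expect_equal(transition_difference(res, 3, T_cyc), 0)
  expect_error(transition_difference(res, 8.5, T_cyc), "outside")
  expect_error(transition_difference(res, -0.5, T_cyc), "outside")
})

test_that("an injected pattern-evoked shift is recovered at the transition", {
  h <- 2
  eeg <- simulate_recording(pattern_plan(20), step_params(h),
                            stimulus_spec(), seed = 78)
  # the 0.02 Hz high-pass keeps the shift inside the analysis band so the
  # window arithmetic can be checked against the injected amplitude
  st <- reject_high_power_trials(preprocess_sustained(eeg, band = c(0.02, 110)))
  res <- sustained_timecourse(dss_trial_average(st))
  stat <- transition_difference(res, 4 * T_cyc, T_cyc)
  expect_equal(stat, h, tolerance = 0.2)
})

test_that("the transition statistic respects random-random bootstrap floors", {
  # null case: no sustained shift anywhere
  p0 <- sus_params(sustained_step = 0, noise_scale = 0.5,
                   amplitudes = c(ffr = 0, efr = 0, ecfr = 0, beat = 0,
                                  distractor_efr = 0))
  eeg0 <- simulate_recording(flat_plan(16), p0, stimulus_spec(), seed = 79)
  res0 <- sustained_timecourse(
    dss_trial_average(reject_high_power_trials(preprocess_sustained(eeg0)))
  )
  stat0 <- transition_difference(res0, 4 * T_cyc, T_cyc)
  set.seed(80)
  fl0 <- bootstrap_transition_floor(res0, T_cyc, n_boot = 300)
  expect_gt(stat0, fl0$envelope[1])
  expect_lt(stat0, fl0$envelope[2])

  # positive control: a large pattern-evoked shift exceeds the floor of a
  # matched random-random run (the paradigm's own control comparison)
  eeg1 <- simulate_recording(pattern_plan(20), step_params(3),
                             stimulus_spec(), seed = 81)
  res1 <- sustained_timecourse(dss_trial_average(reject_high_power_trials(
    preprocess_sustained(eeg1, band = c(0.02, 110)))))
  stat1 <- transition_difference(res1, 4 * T_cyc, T_cyc)
  eeg_rr <- simulate_recording(flat_plan(20), step_params(3),
                               stimulus_spec(), seed = 81)
  res_rr <- sustained_timecourse(dss_trial_average(reject_high_power_trials(
    preprocess_sustained(eeg_rr, band = c(0.02, 110)))))
  set.seed(82)
  fl_rr <- bootstrap_transition_floor(res_rr, T_cyc, n_boot = 300)
  expect_gt(stat1, fl_rr$envelope[2])

  # determinism of the floor itself
  set.seed(83)
  f1 <- bootstrap_transition_floor(res0, T_cyc, n_boot = 50)
  set.seed(83)
  f2 <- bootstrap_transition_floor(res0, T_cyc, n_boot = 50)
  expect_identical(f1$samples, f2$samples)
})

test_that("the full sustained pipeline runs its stages in order", {
  p <- sus_params(noise_scale = 0.4)
  eeg <- simulate_recording(flat_plan(8), p, stimulus_spec(), seed = 84)
  res <- sustained_timecourse(
    dss_trial_average(reject_high_power_trials(preprocess_sustained(eeg)))
  )
  expect_equal(attr(res, "stages"),
               c("lowpass", "downsample", "highpass", "rereference",
                 "baseline", "reject", "lowpass30", "dss", "rms"))
  expect_true(all(res$timecourse$rms >= 0))
})

test_that("noise-only sustained time courses are flat", {
  p <- sus_params(noise_scale = 0.5,
                  amplitudes = c(ffr = 0, efr = 0, ecfr = 0, beat = 0,
                                 distractor_efr = 0))
  eeg <- simulate_recording(flat_plan(30), p, stimulus_spec(), seed = 85)
  res <- sustained_timecourse(
    dss_trial_average(reject_high_power_trials(preprocess_sustained(eeg)))
  )
  tc <- res$timecourse[res$timecourse$time_s > 0, ]
  fit <- stats::lm(rms ~ time_s, data = tc)
  drift <- abs(stats::coef(fit)[2]) * diff(range(tc$time_s))
  expect_lt(drift, 0.25 * mean(tc$rms))
})
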