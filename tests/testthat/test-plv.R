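test_that("PLV is 1 for identical epochs and 0 for opposite phases", {
  s <- sin(2 * pi * 6 * (0:199) / 200) + 0.5 * sin(2 * pi * 20 * (0:199) / 200)
  arr <- aperm(array(rep(s, 10 * 2), dim = c(200, 2, 10)), c(3, 2, 1))
  es <- epoch_set(arr, tibble::tibble(epoch = 1:10), 1000, "cycle")
  ps <- plv_spectrum(es)
  expect_equal(ps$plv[7], 1)   # 30 Hz bin
  expect_equal(ps$plv[21], 1)  # 100 Hz bin

  arr2 <- aperm(array(c(s, -s), dim = c(200, 1, 2)), c(3, 2, 1))
  es2 <- epoch_set(arr2, tibble::tibble(epoch = 1:2), 1000, "cycle")
  expect_equal(plv_spectrum(es2)$plv[7], 0, tolerance = 1e-12)

  es1 <- subset_epochs(es, 1)
  expect_error(plv_spectrum(es1), "at least 2")
})

test_that("uniform-phase noise epochs sit at the analytic floor", {
  set.seed(61)
  for (N in c(50, 300)) {
    es <- noise_epochs(N, n_ch = 6, n_s = 400)
    ps <- plv_spectrum(es)
    m <- mean(ps$per_channel[, 2:200])
    expect_equal(m, sqrt(pi / (4 * N)), tolerance = 0.05)
  }
})

test_that("the RMS aggregate never exceeds the largest per-channel PLV", {
  set.seed(62)
  es <- noise_epochs(40, n_ch = 5, n_s = 256)
  ps <- plv_spectrum(es)
  expect_true(all(ps$per_channel >= 0 & ps$per_channel <= 1))
  expect_true(all(ps$plv <= apply(ps$per_channel, 2, max) + 1e-12))
})

test_that("waveform-difference FFR isolates the polarity-flipping carrier", {
  set.seed(63)
  n <- 1500; fs <- eeg_fs
  frac <- (0:(n - 1)) / n
  pol <- rep(c(1L, -1L), 20)
  arr <- array(0, dim = c(40, 4, n))
  for (e in 1:40) {
    for (ch in 1:4) {
      arr[e, ch, ] <- pol[e] * sin(2 * pi * 380 * frac) +  # carrier-locked
        sin(2 * pi * 50 * frac) +                          # envelope-locked
        rnorm(n)
    }
  }
  es <- epoch_set(arr, tibble::tibble(trial = 1, sample = 1:40, polarity = pol),
                  fs, "cycle")
  f_car <- 380 * fs / n
  f_env <- 50 * fs / n

  pd <- ffr_plv(es, "difference")
  expect_gte(plv_at(pd, f_car), 0.9)
  fl <- noise_floor(pd, f_env)
  expect_lt(plv_at(pd, f_env), fl + 3 * stats::sd(pd$plv[10:200]))

  # literal per-channel PLV difference is near zero for polarity-symmetric
  # statistics
  pl <- ffr_plv(es, "plv-difference")
  expect_lt(plv_at(pl, f_car), 0.05)
  expect_lt(plv_at(pl, f_env), 0.05)

  # noise-free flipping carrier: difference-mode PLV of exactly 1
  arr0 <- array(0, dim = c(8, 2, n))
  for (e in 1:8) for (ch in 1:2) {
    arr0[e, ch, ] <- rep(c(1, -1), 4)[e] * sin(2 * pi * 380 * frac)
  }
  es0 <- epoch_set(arr0, tibble::tibble(trial = 1, sample = 1:8,
                                        polarity = rep(c(1L, -1L), 4)),
                   fs, "cycle")
  expect_equal(plv_at(ffr_plv(es0, "difference"), f_car), 1)

  # unpairable counts: the trailing epoch is dropped with a warning
  es9 <- subset_epochs(es, 1:9)
  expect_warning(ffr_plv(es9, "difference"), "unpaired")
})

test_that("noise floors ignore injected peaks and scale as 1/sqrt(N)", {
  set.seed(64)
  base <- array(rnorm(100 * 4 * 300), dim = c(100, 4, 300))
  es_clean <- epoch_set(base, tibble::tibble(epoch = 1:100), eeg_fs, "cycle")
  ps_clean <- plv_spectrum(es_clean)

  s <- sin(2 * pi * 30 * (0:299) / 300)
  es_peak <- epoch_set(base + rep(3 * s, each = 400),
                       tibble::tibble(epoch = 1:100), eeg_fs, "cycle")
  ps_peak <- plv_spectrum(es_peak)
  f30 <- 30 * eeg_fs / 300
  expect_equal(noise_floor(ps_peak, f30), noise_floor(ps_clean, f30),
               tolerance = 0.1)
  expect_gt(plv_at(ps_peak, f30), 5 * noise_floor(ps_peak, f30))

  # floor shrinks like 1/sqrt(N)
  es_small <- subset_epochs(es_clean, 1:25)
  r <- noise_floor(plv_spectrum(es_small), f30) / noise_floor(ps_clean, f30)
  expect_equal(r, 2, tolerance = 0.2)

  # every neighborhood bin marked related: no floor can be estimated
  expect_error(
    noise_floor(ps_clean, f30, related_hz = ps_clean$freqs_hz),
    "no unrelated bins"
  )
})

test_that("bootstrap equalization matches plain PLV at equal counts and is seeded", {
  set.seed(65)
  a <- noise_epochs(30, n_ch = 3, n_s = 128)
  b <- noise_epochs(30, n_ch = 3, n_s = 128)
  eq <- equalize_and_average(list(a = a, b = b), n_iter = 50)
  expect_equal(eq$a$plv, plv_spectrum(a)$plv)
  expect_equal(eq$b$plv, plv_spectrum(b)$plv)

  big <- noise_epochs(120, n_ch = 3, n_s = 128)
  set.seed(66)
  e1 <- equalize_and_average(list(big = big, small = a), n_iter = 40)
  set.seed(66)
  e2 <- equalize_and_average(list(big = big, small = a), n_iter = 40)
  expect_identical(e1$big$plv, e2$big$plv)
  expect_equal(e1$big$n_epochs, 30)
  expect_error(equalize_and_average(list(x = subset_epochs(a, 1))),
               "fewer than 2")
})

test_that("subsampled floors match fresh sets at the minimum count", {
  set.seed(67)
  big <- noise_epochs(200, n_ch = 4, n_s = 200)
  small <- noise_epochs(50, n_ch = 4, n_s = 200)
  eq <- equalize_and_average(list(big = big, small = small), n_iter = 300)
  m_big <- mean(eq$big$per_channel[, 2:100])
  m_small <- mean(eq$small$per_channel[, 2:100])
  expect_equal(m_big, m_small, tolerance = 0.05)
  expect_equal(m_big, sqrt(pi / (4 * 50)), tolerance = 0.05)
})

test_that("the asymmetry index follows its closed form and inclusion rules", {
  expect_equal(asymmetry_index(0.5, 0.5), 0)
  expect_equal(asymmetry_index(0.3, 0), 1)
  expect_equal(asymmetry_index(0, 0.3), -1)
  expect_equal(asymmetry_index(0.048, 0.030), 0.2307692, tolerance = 1e-6)
  expect_true(is.na(asymmetry_index(0, 0)))

  df <- tibble::tibble(
    participant = 1:4, component = "ecfr",
    plv_correct = c(0.06, 0.05, 0.01, 0),
    plv_incorrect = c(0.03, 0.04, 0.01, 0),
    noise_floor = c(0.02, 0.02, 0.02, 0.02),
    error_rate = c(0.3, 0.1, 0.3, 0.3)
  )
  tb <- asymmetry_table(df)
  expect_equal(tb$included, c(TRUE, FALSE, FALSE, FALSE))
  # too few errors, both categories at floor, and undefined AI all excluded
  expect_equal(tb$ai[1], (0.06 - 0.03) / 0.09)
})

test_that("noise-only asymmetry indices are centered at zero", {
  set.seed(68)
  ai <- vapply(1:50, function(i) {
    correct <- noise_epochs(24, n_ch = 3, n_s = 100)
    incorrect <- noise_epochs(12, n_ch = 3, n_s = 100)
    eq <- equalize_and_average(list(c = correct, i = incorrect),
                               n_iter = 60, bins = 5L)
    asymmetry_index(eq$c$plv[1], eq$i$plv[1])
  }, numeric(1))
  se <- stats::sd(ai) / sqrt(length(ai))
  expect_lt(abs(mean(ai)), 2 * se)
})

test_that("measured PLV rises monotonically with locking amplitude", {
  set.seed(69)
  noise <- array(rnorm(30 * 3 * 200), dim = c(30, 3, 200))
  plvs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(a) {
    plv_spectrum(locked_epochs(a, 12L, noise))$plv[13]
  }, numeric(1))
  expect_true(all(diff(plvs) > 0))
  expect_lt(plvs[1], 0.6)
  expect_gt(plvs[5], 0.9)
})
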