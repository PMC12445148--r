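test_that("SAM tokens complete integer carrier and AM periods and end at zero", {
  spec <- audio_spec()
  n <- length(make_sam_token(1, spec)$samples)
  expect_equal(n, round(spec$sample_rate_hz / spec$base_rate_hz))

  for (i in seq_along(spec$am_multiples)) {
    tok <- make_sam_token(i, spec)
    # carrier completes exactly 76 periods: count zero crossings of the
    # carrier factor recovered on the token grid
    carrier <- sin(2 * pi * spec$carrier_multiple * (seq_len(n) - 1) / n)
    expect_equal(sum(diff(sign(carrier)) != 0) / 2, spec$carrier_multiple)
    # cosine-phase modulator: zero amplitude at both endpoints
    expect_equal(tok$samples[1], 0)
    expect_lt(abs(tok$samples[n]), 1e-3)
    # envelope completes exactly m periods: spectral peak of the recovered
    # envelope at bin m of the token window
    env <- spec$mod_depth * (1 - cos(2 * pi * spec$am_multiples[i] *
                                       (seq_len(n) - 1) / n)) / 2
    sp <- Mod(stats::fft(env))[2:40]
    expect_equal(which.max(sp), spec$am_multiples[i])
  }
  expect_error(make_sam_token(9, spec), "out of range")
})

test_that("token AM rates reproduce the nominal 27/41/54/68/82 Hz set", {
  rates <- am_rates(stimulus_spec())
  expect_equal(rates$nominal_hz, c(27, 41, 54, 68, 82))
  expect_equal(rates$rate_hz, c(27.2, 40.8, 54.4, 68, 81.6))
})

test_that("pattern enumeration covers all permutations in lexicographic order", {
  expect_equal(nrow(enumerate_patterns(stimulus_spec())), 120)
  p3 <- enumerate_patterns(stimulus_spec(am_multiples = c(4, 6, 8)))
  expect_equal(nrow(p3), 6)
  expect_equal(p3[1, ], c(1L, 2L, 3L))
  expect_equal(p3[6, ], c(3L, 2L, 1L))
  p5 <- enumerate_patterns(stimulus_spec())
  expect_true(all(apply(p5, 1, function(r) setequal(r, 1:5))))
  expect_equal(anyDuplicated(p5), 0)
})

test_that("random cycles avoid repeating the previous last token and are uniform", {
  spec <- stimulus_spec()
  set.seed(11)
  draws <- replicate(10000, draw_random_cycle(spec, prev_last = 4L)[1])
  expect_false(any(draws == 4L))

  # support has 120 - 4! = 96 permutations, hit uniformly
  perms <- enumerate_patterns(spec)
  ids <- apply(perms, 1, paste, collapse = "")
  allowed <- ids[perms[, 1] != 4L]
  expect_length(allowed, 96)
  set.seed(12)
  big <- replicate(96000, paste(draw_random_cycle(spec, prev_last = 4L),
                                collapse = ""))
  counts <- table(factor(big, levels = allowed))
  expect_equal(length(counts), 96)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)

  # without a constraint the full set is reachable
  set.seed(13)
  free <- replicate(5000, paste(draw_random_cycle(spec), collapse = ""))
  expect_gt(length(unique(free)), 110)
})

test_that("built targets have the paradigm durations and event structure", {
  spec <- audio_spec()
  set.seed(2)
  t4 <- build_target(cycle_plan(spec, 4, "random-random"))
  expect_equal(round(wave_duration(t4$wave), 1), 2.9)
  expect_equal(wave_duration(t4$wave), 4 * 5 / 6.8, tolerance = 1e-3)

  t12 <- build_target(cycle_plan(spec, 12, "random-pattern"))
  expect_equal(wave_duration(t12$wave), 60 / 6.8, tolerance = 1e-3)

  ev <- t12$events
  expect_equal(sum(ev$kind == "cycle"), 12)
  expect_equal(sum(ev$kind == "token"), 60)
  tok <- ev[ev$kind == "token", ]
  expect_equal(unique(diff(tok$sample)),
               round(spec$sample_rate_hz / spec$base_rate_hz))
  expect_true(all(tok$polarity == rep(rep(c(1, -1), 6), each = 5)))
})

test_that("polarity alternation makes odd cycles the negation of even cycles", {
  spec <- audio_spec()
  perm <- c(2L, 4L, 1L, 5L, 3L)
  plan <- structure(
    list(cycles = rep(list(perm), 4), context = "random-pattern",
         transition_cycle = 1L, polarity = c(1L, -1L, 1L, -1L), spec = spec),
    class = "cycle_plan"
  )
  tg <- build_target(plan)
  n_cyc <- length(tg$wave$samples) / 4
  c1 <- tg$wave$samples[seq_len(n_cyc)]
  c2 <- tg$wave$samples[n_cyc + seq_len(n_cyc)]
  expect_equal(c2, -c1)
})

test_that("concatenation is click-free at every token boundary", {
  spec <- audio_spec()
  set.seed(3)
  tg <- build_target(cycle_plan(spec, 12, "random-random"))
  expect_lt(max(concatenation_steps(tg)), 1e-6)
})

test_that("random-pattern plans repeat the pattern bit-identically after transition", {
  spec <- audio_spec()
  set.seed(4)
  plan <- cycle_plan(spec, 12, "random-pattern", transition_cycle = 5)
  expect_true(all(vapply(plan$cycles[5:12],
                         function(cy) identical(cy, plan$cycles[[5]]),
                         logical(1))))
  tg <- build_target(plan)
  n_cyc <- length(tg$wave$samples) / 12
  seg <- function(k) tg$wave$samples[(k - 1) * n_cyc + seq_len(n_cyc)] *
    plan$polarity[k]
  for (k in 6:12) expect_identical(seg(k), seg(5))
  # and cycles never open with the previous cycle's closing token
  for (k in 2:12) {
    expect_false(plan$cycles[[k]][1] == plan$cycles[[k - 1]][5])
  }
})

test_that("the polarity-corrected target spectrum peaks at the carrier with AM sidebands", {
  spec <- audio_spec()
  set.seed(5)
  tg <- build_target(cycle_plan(spec, 12, "random-random"))
  sp <- target_spectrum(tg)
  hi <- sp[sp$freq_hz > 100, ]
  peak <- hi$freq_hz[which.max(hi$magnitude)]
  expect_equal(peak, 516.8, tolerance = 1e-4)

  # sidebands at carrier +/- each AM rate stand above the local background
  floor_mag <- stats::median(hi$magnitude)
  for (f in 516.8 + c(-1, 1) %o% c(27.2, 40.8, 54.4, 68, 81.6)) {
    at <- hi$magnitude[which.min(abs(hi$freq_hz - f))]
    expect_gt(at, 10 * floor_mag)
  }
})

test_that("stimulus configs round-trip through YAML with a mandatory seed", {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(base_rate_hz = 6.8, carrier_multiple = 76,
                        am_multiples = c(4, 6, 8, 10, 12),
                        sample_rate_hz = 8160, seed = 77), path)
  spec <- read_stimulus_config(path)
  expect_s3_class(spec, "stimulus_spec")
  expect_equal(attr(spec, "seed"), 77L)
  yaml::write_yaml(list(base_rate_hz = 6.8), path)
  expect_error(read_stimulus_config(path), "seed")
})

test_that("waveforms survive a WAV round trip", {
  w <- peak_normalize(waveform(sin(2 * pi * 440 * (0:8159) / 8160), 8160))
  path <- tempfile(fileext = ".wav")
  write_wav(w, path)
  r <- read_wav(path)
  expect_equal(r$sample_rate_hz, 8160)
  expect_equal(r$samples, w$samples, tolerance = 1e-4)
})
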