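pad <- function(w, n = 40) c(rep(0, n), w, rep(0, n))

test_that("decomposition inverts the synthesizer on clean waveforms", {
  fs <- 8000
  set.seed(301)
  for (k in 1:40) {
    pitch <- stats::runif(1, 200, 600)
    n <- sample(4:10, 1)
    r <- stats::runif(1, 0.9, 1.6)
    pol <- sample(c(-1, 1), 1)
    w <- synthesize_crackle(pitch, n, t2_over_t1 = r, amplitude_decay = 0.8,
                            polarity = pol, sample_rate = fs)
    d <- decompose_half_periods(pad(w), fs)
    expect_true(d$valid)
    expect_equal(d$n, n)
    expect_equal(d$peak_sign, pol)
    # durations within one sample period
    expect_lt(max(abs(d$T_ms - attr(w, "durations_ms"))), 1000 / fs)
    # amplitudes within discretization error
    expect_lt(max(abs(d$A - attr(w, "amplitudes")) / attr(w, "amplitudes")), 0.05)
  }
})

test_that("a pure sine burst decomposes into equal half-periods", {
  fs <- 8000
  period <- 1 / 250
  t <- seq(0, 6 * period, by = 1 / fs)
  d <- decompose_half_periods(pad(sin(2 * pi * 250 * t)), fs, detrend = FALSE)
  expect_true(d$valid)
  expect_lt(max(abs(d$T_ms - period / 2 * 1000)), 1000 / fs)
})

test_that("windows without enough half-periods are discarded with a reason", {
  fs <- 8000
  w <- synthesize_crackle(400, 4, amplitude_decay = 0.2, sample_rate = fs)
  d <- decompose_half_periods(pad(w), fs)     # lobes 2-4 fall under the floor
  expect_false(d$valid)
  expect_match(d$reason, "4 half-periods")
  expect_false(decompose_half_periods(rep(0, 100), fs)$valid)
})

test_that("features implement the stated formulas", {
  d <- structure(list(valid = TRUE, T_ms = c(1.2, 1.2, 1.2, 1.2),
                      A = c(10, 10, 5, 5), peak_sign = 1, n = 4L,
                      reason = NULL), class = "hp_decomposition")
  f <- compute_features(d, timing_code = 5)
  expect_equal(f$pitch, 2000 / 4.8)           # 416.7 Hz
  expect_equal(f$zxs, 5)                      # n + 1 bounding crossings
  expect_equal(f$duration_variability, 0)
  expect_equal(f$a2_over_a1, 1)
  expect_equal(f$a3_over_a1, 0.5)
  expect_equal(f$amplitude_variability, stats::sd(c(10, 10, 5, 5)) / 7.5 * 100)
  expect_equal(round(f$amplitude_variability, 2), 38.49)
  expect_equal(f$timing_code, 5L)
  expect_true(is.na(f$ctc))
  expect_error(compute_features(decompose_half_periods(rep(0, 100), 8000)),
               "cannot compute")
})

test_that("pitch is always 2000 over the first four half-period durations", {
  set.seed(99)
  for (k in 1:20) {
    T_ms <- stats::runif(5, 0.8, 3)
    d <- structure(list(valid = TRUE, T_ms = T_ms, A = rep(1, 5),
                        peak_sign = -1, n = 5L, reason = NULL),
                   class = "hp_decomposition")
    expect_identical(compute_features(d, 1)$pitch, 2000 / sum(T_ms[1:4]))
  }
})

test_that("every feature except amplitude is scale invariant", {
  fs <- 8000
  w <- pad(synthesize_crackle(380, 6, t2_over_t1 = 1.3, amplitude_decay = 0.8,
                              sample_rate = fs))
  f1 <- compute_features(decompose_half_periods(w, fs), 2)
  f2 <- compute_features(decompose_half_periods(w * 37.5, fs), 2)
  for (col in setdiff(names(f1), c("amplitude", "ctc")))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-10, label = col)
  expect_equal(f2$amplitude, 37.5 * f1$amplitude, tolerance = 1e-10)
})

test_that("time reversal cannot change the crossing count", {
  fs <- 8000
  set.seed(12)
  for (k in 1:10) {
    w <- pad(synthesize_crackle(stats::runif(1, 250, 500), sample(4:8, 1),
                                amplitude_decay = 1, sample_rate = fs))
    f <- compute_features(decompose_half_periods(w, fs), 1)
    fr <- compute_features(decompose_half_periods(rev(w), fs), 1)
    expect_equal(fr$zxs, f$zxs)
  }
})

test_that("patient summaries take medians per phase and flag empty phases", {
  feats <- rbind(
    data.frame(phase = "inspiration", zxs = 5, t1 = 1.2, pitch = 400,
               t2_over_t1 = 1.2, duration_variability = 10, timing_code = 1,
               ctc = 10, amplitude = 1, a2_over_a1 = 1, a3_over_a1 = 0.5,
               amplitude_variability = 40, polarity = 1),
    data.frame(phase = "inspiration", zxs = 7, t1 = 1.4, pitch = 500,
               t2_over_t1 = 1.3, duration_variability = 20, timing_code = 2,
               ctc = 30, amplitude = 2, a2_over_a1 = 0.9, a3_over_a1 = 0.4,
               amplitude_variability = 50, polarity = -1))
  s <- patient_feature_summary(feats, "inspiration", n_breaths = 2)
  expect_equal(s$median_pitch, 450)
  expect_equal(s$mean_ctc, 20)
  expect_equal(s$crackle_rate, 1)
  expect_equal(s$positive_polarity_pct, 50)
  expect_false(s$missing)
  # single crackle: median equals that crackle
  s1 <- patient_feature_summary(feats[1, ], "inspiration", n_breaths = 3)
  expect_equal(s1$median_pitch, 400)
  # empty phase flagged missing, not zero
  s0 <- patient_feature_summary(feats, "expiration", n_breaths = 3)
  expect_true(s0$missing)
  expect_true(is.na(s0$median_pitch))
})
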