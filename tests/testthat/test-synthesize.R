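test_that("synthesized crackle half-periods reproduce the requested pitch and ratio", {
  fs <- 8000
  cases <- expand.grid(pitch = c(250, 416.67, 600), r = c(1, 1.2, 1.5),
                       n = c(4, 6, 9))
  for (i in seq_len(nrow(cases))) {
    w <- synthesize_crackle(cases$pitch[i], cases$n[i], t2_over_t1 = cases$r[i],
                            amplitude_decay = 0.8, sample_rate = fs)
    d <- attr(w, "durations_ms")
    expect_length(d, cases$n[i])
    expect_equal(2000 / sum(d[1:4]), cases$pitch[i], tolerance = 1e-10)
    expect_equal(d[2] / d[1], cases$r[i], tolerance = 1e-10)
  }
  # equal half-periods at 416.67 Hz are 1.2 ms each
  w <- synthesize_crackle(416.67, 4, t2_over_t1 = 1, sample_rate = fs)
  expect_equal(attr(w, "durations_ms"), rep(1.2, 4), tolerance = 1e-4)
})

test_that("crackle polarity controls the direction of the highest peak", {
  wp <- synthesize_crackle(400, 5, amplitude_decay = 0.8, polarity = +1)
  wn <- synthesize_crackle(400, 5, amplitude_decay = 0.8, polarity = -1)
  expect_gt(wp[which.max(abs(wp))], 0)
  expect_lt(wn[which.max(abs(wn))], 0)
})

test_that("no decay means equal half-period amplitudes", {
  w <- synthesize_crackle(416.67, 4, amplitude_decay = 1, sample_rate = 8000)
  d <- decompose_half_periods(c(rep(0, 20), w, rep(0, 20)), 8000)
  expect_true(d$valid)
  expect_equal(d$A[2] / d$A[1], 1, tolerance = 0.02)
  expect_equal(d$A[3] / d$A[1], 1, tolerance = 0.02)
})

test_that("a too-low sample rate is rejected", {
  expect_error(synthesize_crackle(600, 4, sample_rate = 4000), "sample_rate")
})

test_that("recordings are bit-identical for identical seeds and differ across seeds", {
  geo <- default_geometry(14)
  p <- builtin_profile("PN")
  r1 <- synthesize_recording(p, geo, duration = 8, n_breaths = 3, seed = 99)
  r2 <- synthesize_recording(p, geo, duration = 8, n_breaths = 3, seed = 99)
  expect_identical(r1$signal, r2$signal)
  expect_identical(r1$crackles, r2$crackles)
  r3 <- synthesize_recording(p, geo, duration = 8, n_breaths = 3, seed = 100)
  expect_false(identical(r1$signal, r3$signal))
})

test_that("recording preconditions are enforced", {
  p <- builtin_profile("IPF")
  expect_error(synthesize_recording(p, duration = 4, n_breaths = 3), "2 s per breath")
  one_sided <- channel_geometry(data.frame(
    channel = 1:3, x = c(-5, -5, 5), y = 0, z = c(5, 15, 10),
    side = c("left", "left", "right"),
    quadrant = c("bottom-left", "top-left", "bottom-right")))
  expect_error(synthesize_recording(p, one_sided, n_breaths = 3, seed = 1),
               "2 channels per side")
})

test_that("generated crackle rates and pitch recover the profile parameters", {
  # pool breaths across seeded patients; compare to profile means
  p <- builtin_profile("IPF")
  geo <- default_geometry(14)
  counts <- c(); pitch_means <- c()
  for (s in 1:70) {
    rec <- synthesize_recording(p, geo, duration = 6, n_breaths = 3, seed = 7000 + s)
    crk <- rec$crackles
    insp <- crk[crk$phase == "inspiration", ]
    counts <- c(counts, nrow(insp) / 3)
    if (nrow(insp)) pitch_means <- c(pitch_means, mean(insp$pitch))
  }
  expect_gte(length(counts) * 3, 200)
  se_rate <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - p$insp_crackle_rate_mean), 3 * se_rate + 1e-9)
  # per-patient mean pitch within 3 SE of the profile mean (the small
  # positive Jensen shift from duration jitter stays well inside 3 SE)
  se_pitch <- stats::sd(pitch_means) / sqrt(length(pitch_means))
  expect_lt(abs(mean(pitch_means) - p$pitch_mean), 3 * se_pitch)
})

test_that("zero transmission leaves each crackle on exactly one channel", {
  p <- builtin_profile("IPF")
  p$transmission_level <- 0
  geo <- default_geometry(14)
  rec <- synthesize_recording(p, geo, duration = 6, n_breaths = 3, seed = 3)
  expect_gt(nrow(rec$crackles), 0)
  per_crackle <- table(rec$arrivals$crackle)
  expect_true(all(per_crackle == 1))
  expect_true(all(rec$crackles$ctc_true == 0))
})

test_that("focal recordings confine sources to one quadrant region", {
  p <- builtin_profile("PN")
  geo <- default_geometry(14)
  for (s in 1:5) {
    rec <- synthesize_recording(p, geo, duration = 6, n_breaths = 3, seed = 50 + s)
    crk <- rec$crackles
    expect_gt(nrow(crk), 0)
    sides <- unique(ifelse(crk$x < 0, "left", "right"))
    expect_length(sides, 1)                       # one lung
    expect_true(all(crk$z >= 16) || all(crk$z <= 12))  # one vertical band
  }
})

test_that("basal recordings concentrate sources toward the lung bases", {
  p <- builtin_profile("CHF")
  geo <- default_geometry(14)
  z <- unlist(lapply(1:10, function(s)
    synthesize_recording(p, geo, duration = 6, n_breaths = 3,
                         seed = 800 + s)$crackles$z))
  # linear density doubling toward the base: mean z = 12.4 for zmax = 28
  expect_lt(mean(z), 14 - 2 * stats::sd(z) / sqrt(length(z)))
})

test_that("mother channel amplitude bounds every child amplitude", {
  rec <- synthesize_recording(builtin_profile("CHF"), default_geometry(14),
                              duration = 6, n_breaths = 3, seed = 77)
  arr <- rec$arrivals
  for (id in unique(arr$crackle)) {
    fam <- arr[arr$crackle == id, ]
    expect_true(all(fam$amplitude[!fam$is_mother] <=
                      fam$amplitude[fam$is_mother] + 1e-12))
  }
})

test_that("annotated arrivals above the noise floor are detected, and detections are real", {
  # closure of the detector against ground truth; arrivals occluded by a
  # same-channel neighbour within the dead time are excluded, since no
  # dead-time detector can separate them
  geo <- default_geometry(14)
  sens_all <- c(); fdr_all <- c()
  for (pf in c("CHF", "PN")) {
    rec <- synthesize_recording(builtin_profile(pf), geo, seed = 15)
    ev <- detect_all_channels(rec$signal, rec$sample_rate, rec$breaths, geo)
    arr <- rec$arrivals[rec$arrivals$amplitude >= 0.2, ]
    occluded <- vapply(seq_len(nrow(arr)), function(i) {
      a <- rec$arrivals[rec$arrivals$channel == arr$channel[i], ]
      any(abs(a$peak_ms - arr$peak_ms[i]) > 1e-9 &
            abs(a$peak_ms - arr$peak_ms[i]) < 12)
    }, logical(1))
    arr <- arr[!occluded, ]
    hit <- vapply(seq_len(nrow(arr)), function(i) {
      e <- ev[ev$channel == arr$channel[i], ]
      any(abs(e$peak_s - arr$peak_ms[i] / 1000) < 0.003)
    }, logical(1))
    false_ev <- vapply(seq_len(nrow(ev)), function(i) {
      a <- rec$arrivals[rec$arrivals$channel == ev$channel[i], ]
      !any(abs(a$peak_ms / 1000 - ev$peak_s[i]) < 0.005)
    }, logical(1))
    sens_all <- c(sens_all, mean(hit))
    fdr_all <- c(fdr_all, mean(false_ev))
  }
  expect_gte(mean(sens_all), 0.95)
  expect_lte(mean(fdr_all), 0.05)
})
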