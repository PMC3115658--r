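test_that("greedy grouping keys families to the largest-amplitude mother", {
  geo <- toy_geometry()          # channels 1-3 left, 4-6 right
  ev <- data.frame(
    event = 1:5,
    channel = c(1, 2, 3, 4, 1),
    peak_s = c(0.500, 0.502, 0.505, 0.501, 0.600),
    peak_amplitude = c(1.0, 0.5, 0.4, 0.9, 0.3),
    stringsAsFactors = FALSE)
  out <- group_families(ev, geo, window_ms = 10)
  # event 4 is contralateral: own family despite being within the window
  expect_false(out$family[4] == out$family[1])
  expect_true(all(out$family[1:3] == out$family[1]))
  expect_true(out$is_mother[1])
  expect_false(any(out$is_mother[2:3]))
  # event 5 is 100 ms away on the same side: separate family
  expect_false(out$family[5] == out$family[1])
  expect_true(out$is_mother[5])
  # every event belongs to exactly one family
  expect_false(anyNA(out$family))
})

test_that("one member per channel: the nearest in time wins", {
  geo <- toy_geometry()
  ev <- data.frame(event = 1:3, channel = c(1, 2, 2),
                   peak_s = c(0.500, 0.508, 0.501),
                   peak_amplitude = c(1, 0.6, 0.5))
  out <- group_families(ev, geo, window_ms = 10)
  expect_equal(out$family[3], out$family[1])   # nearer in time
  expect_false(out$family[2] == out$family[1])
})

test_that("grouping recovers annotated family membership", {
  geo <- default_geometry(14)
  rec <- synthesize_recording(builtin_profile("CHF"), geo, duration = 6,
                              n_breaths = 3, seed = 33)
  ev <- detect_all_channels(rec$signal, rec$sample_rate, rec$breaths, geo)
  out <- group_families(ev, geo, window_ms = 10)
  arr <- rec$arrivals
  checked <- 0
  for (id in unique(arr$crackle)) {
    fam_true <- arr[arr$crackle == id, ]
    m <- fam_true[fam_true$is_mother, ]
    j <- which(out$channel == m$channel & abs(out$peak_s - m$peak_ms / 1000) < 0.003)
    if (length(j) != 1 || !out$is_mother[j]) next
    members <- out[out$family == out$family[j], ]
    # every annotated above-floor arrival that was detected sits in this family
    for (k in seq_len(nrow(fam_true))) {
      jk <- which(out$channel == fam_true$channel[k] &
                    abs(out$peak_s - fam_true$peak_ms[k] / 1000) < 0.003)
      if (length(jk) == 1) {
        expect_equal(out$family[jk], out$family[j])
        checked <- checked + 1
      }
    }
  }
  expect_gt(checked, 20)
})

test_that("the transmission coefficient implements its defining endpoints and formula", {
  geo <- toy_geometry(4)         # 4 channels per side
  # no transmission: single-member family
  f0 <- make_family(1, 1)
  expect_equal(compute_ctc(f0, geo), 0)
  # full transmission: equal amplitude on every ipsilateral channel
  f1 <- make_family(1:4, rep(0.8, 4))
  expect_equal(compute_ctc(f1, geo), 100)
  # partial: N = 4, children at half amplitude on 2 of 3 other channels
  f2 <- make_family(c(1, 2, 3), c(1, 0.5, 0.5))
  expect_equal(compute_ctc(f2, geo), 100 * (0.5 + 0.5 + 0) / 3)
  # seven-channel side, three children at half amplitude: 25%
  geo7 <- toy_geometry(7)
  f3 <- make_family(c(1, 2, 3, 4), c(1, 0.5, 0.5, 0.5))
  expect_equal(compute_ctc(f3, geo7), 25)
  # child nominally louder than the mother is capped at ratio 1
  f4 <- make_family(c(1, 2), c(1, 0.99), mother = 1)
  f4$peak_amplitude[2] <- 1.2; f4$is_mother <- c(TRUE, FALSE)
  expect_lte(compute_ctc(f4, toy_geometry(2)), 100)
})

test_that("ctc is bounded and monotone in child amplitude", {
  geo <- toy_geometry(5)
  set.seed(5)
  prev <- -1
  for (a in seq(0.05, 0.95, by = 0.1)) {
    f <- make_family(c(1, 2, 4), c(1, a, a / 2))
    ctc <- compute_ctc(f, geo)
    expect_gte(ctc, 0); expect_lte(ctc, 100)
    expect_gte(ctc, prev)
    prev <- ctc
  }
  # fewer than two channels on the side: undefined
  geo1 <- channel_geometry(data.frame(
    channel = 1:2, x = c(-5, 5), y = 0, z = 5,
    side = c("left", "right"),
    quadrant = c("bottom-left", "bottom-right")))
  expect_error(compute_ctc(make_family(1, 1), geo1), "fewer than 2")
})

test_that("multilateration recovers a known source from exact delays", {
  geo <- default_geometry(14)
  src <- c(x = -7, y = 8, z = 12)
  ch <- geo$channels[geo$channels$side == "left", ]
  d <- sqrt((ch$x - src["x"])^2 + (ch$y - src["y"])^2 + (ch$z - src["z"])^2)
  t0 <- 1.0
  fam <- data.frame(channel = ch$channel,
                    peak_s = t0 + d / geo$sound_speed / 1000,
                    peak_amplitude = exp(-d / 15),
                    is_mother = seq_len(nrow(ch)) == which.min(d))
  est <- localize_crackle(fam, geo)
  expect_equal(attr(est, "method"), "multilateration")
  expect_lt(sqrt(sum((est - src)^2)), 1)
  # a source equidistant from two microphones predicts equal delays
  mid <- c(0, 8, 14)
  d1 <- sqrt(sum((unlist(geo$channels[1, c("x", "y", "z")]) - mid)^2))
  d8 <- sqrt(sum((unlist(geo$channels[8, c("x", "y", "z")]) - mid)^2))
  expect_equal(d1, d8)
})

test_that("small families fall back to the mother position at default depth", {
  geo <- default_geometry(14)
  fam <- make_family(3, 1, peak_s = 0.5)
  est <- localize_crackle(fam, geo)
  expect_equal(attr(est, "method"), "fallback")
  pos <- geo$channels[geo$channels$channel == 3, ]
  expect_equal(unname(est["x"]), pos$x)
  expect_equal(unname(est["y"]), pos$y + 6)
  expect_equal(unname(est["z"]), pos$z)
})

test_that("cohort-level measured transmission tracks the profile level", {
  co <- acceptance_cohort()
  for (g in c("IPF", "CHF")) {
    target <- builtin_profile(g)$transmission_level * 100
    pm <- with(co$crackles[co$crackles$group == g, ],
               tapply(ctc, patient, mean))
    se <- stats::sd(pm) / sqrt(length(pm))
    expect_lt(abs(mean(pm) - target), 3 * se + 1)
  }
})
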