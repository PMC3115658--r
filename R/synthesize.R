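#' Synthesize a single crackle waveform
#'
#' Builds the piecewise half-sine crackle model: the waveform is a train of
#' `n_half_periods` half-sine lobes of alternating sign. The first lobe
#' contains the highest peak (sign = `polarity`); its duration T1 is set so
#' that the pitch computed from the first four half-periods,
#' `2 / (T1 + T2 + T3 + T4)`, equals `pitch`. The second and later lobes
#' all have duration `t2_over_t1 * T1`, and lobe amplitudes follow the
#' geometric schedule `amplitude_decay^(i-1)`. This construction is the
#' exact generative inverse of [decompose_half_periods()].
#'
#' `durations_ms` / `amplitudes` override the schedule (used by the
#' recording generator to add within-crackle jitter); the first amplitude
#' must then remain the largest so the highest peak stays in T1.
#'
#' @param pitch crackle pitch in Hz.
#' @param n_half_periods number of half-sine lobes, at least 4.
#' @param t2_over_t1 ratio of later half-period durations to the first.
#' @param amplitude_decay geometric per-lobe amplitude factor in (0, 1].
#' @param polarity +1 (highest peak upward) or -1 (downward).
#' @param sample_rate Hz; must be at least `8 * pitch` so every half-period
#'   spans several samples.
#' @param amplitude peak amplitude (arbitrary units).
#' @param durations_ms,amplitudes optional explicit per-half-period
#'   schedules overriding the derived ones.
#' @return numeric waveform vector with attributes `durations_ms`,
#'   `amplitudes`, `polarity` and `sample_rate`.
#' @examples
#' w <- synthesize_crackle(416.67, 4, sample_rate = 8000)
#' attr(w, "durations_ms")  # four half-periods of 1.2 ms
#' @export
synthesize_crackle <- function(pitch, n_half_periods,
                               t2_over_t1 = 1, amplitude_decay = 1,
                               polarity = 1, sample_rate = 8000,
                               amplitude = 1,
                               durations_ms = NULL, amplitudes = NULL) {
  if (is.null(durations_ms)) {
    stopifnot(pitch > 0, n_half_periods >= 4)
    if (sample_rate < 8 * pitch)
      stop("sample_rate (", sample_rate, " Hz) too low to resolve half-periods",
           " of a ", pitch, " Hz crackle; need at least ", 8 * pitch, " Hz",
           call. = FALSE)
    t1_ms <- 2000 / (pitch * (1 + 3 * t2_over_t1))
    durations_ms <- c(t1_ms, rep(t2_over_t1 * t1_ms, n_half_periods - 1L))
  } else {
    n_half_periods <- length(durations_ms)
    stopifnot(n_half_periods >= 4, all(durations_ms > 0))
    if (min(durations_ms) * sample_rate / 1000 < 2)
      stop("sample_rate too low to resolve the requested half-periods",
           call. = FALSE)
  }
  if (is.null(amplitudes))
    amplitudes <- amplitude * amplitude_decay^(seq_len(n_half_periods) - 1L)
  stopifnot(length(amplitudes) == n_half_periods, all(amplitudes > 0))

  b <- c(0, cumsum(durations_ms)) / 1000            # lobe boundaries, s
  total <- b[length(b)]
  t <- seq(0, total, by = 1 / sample_rate)
  seg <- findInterval(t, b, rightmost.closed = TRUE)
  seg[seg < 1L] <- 1L
  seg[seg > n_half_periods] <- n_half_periods
  sgn <- polarity * (-1)^(seg - 1L)
  w <- sgn * amplitudes[seg] *
    sin(pi * (t - b[seg]) / (diff(b))[seg])
  structure(w, durations_ms = durations_ms, amplitudes = amplitudes,
            polarity = polarity, sample_rate = sample_rate)
}

# inverse-CDF samplers for the three spatial source patterns ----------------

sample_source_z <- function(n, pattern, zmax = 28) {
  u <- stats::runif(n)
  if (pattern == "basal") {
    # linear density w(z) = 2 - z/zmax: twice as dense at the base
    2 * zmax * (1 - sqrt(1 - 0.75 * u))
  } else {
    u * zmax
  }
}

sample_sources <- function(n, pattern, side, focal_quadrant = NULL) {
  sgn <- ifelse(side == "left", -1, 1)
  x <- sgn * stats::runif(n, 3, 13)
  y <- stats::runif(n, 3, 17)
  if (pattern == "focal") {
    zr <- if (grepl("^top", focal_quadrant)) c(16, 26) else c(2, 12)
    z <- stats::runif(n, zr[1], zr[2])
  } else {
    z <- sample_source_z(n, pattern)
  }
  cbind(x = x, y = y, z = z)
}

# Choose the child-channel gain g so that the transmission coefficient the
# measurement stage is expected to see matches the target. Channels whose
# projected amplitude would fall below the detection floor contribute
# nothing, exactly as they would go undetected downstream.
calibrate_gain <- function(target_ctc, k, mother_amp, floor_amp) {
  if (target_ctc <= 0) return(0)
  n_other <- length(k)
  if (n_other == 0L) return(0)
  g_grid <- seq(0, 1, length.out = 401L)
  ctc_g <- vapply(g_grid, function(g) {
    r <- pmin(g * k, 1)
    r[g * k * mother_amp < floor_amp] <- 0
    100 * sum(r) / n_other
  }, numeric(1))
  g_grid[which.min(abs(ctc_g - target_ctc))]
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Synthesize a multichannel recording with ground-truth annotations
#'
#' Generates a seeded multichannel chest-surface recording following a
#' [disease_profile()]: breaths alternate inspiration and expiration at
#' known boundaries; per-breath crackle counts are drawn from the profile's
#' rate distributions; each crackle is given a 3-D source location
#' following the profile's spatial pattern, synthesized with
#' [synthesize_crackle()], and projected onto every ipsilateral channel
#' with an arrival delay of distance/sound-speed and an amplitude
#' attenuation calibrated so the measured crackle transmission coefficient
#' matches the profile's transmission level. Gaussian background noise and
#' a low-frequency breath-sound component are added to every channel.
#'
#' Feature standard deviations in the profile are split into equal-variance
#' patient-level and crackle-level components, so repeated calls with
#' different seeds emulate different patients of the same group.
#'
#' @param profile a [disease_profile()].
#' @param geometry a [channel_geometry()]; needs at least 2 channels per
#'   side.
#' @param duration recording length in seconds (at least `2 * n_breaths`).
#' @param n_breaths number of full breaths.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param sample_rate Hz.
#' @param insp_fraction fraction of each breath spent in inspiration.
#' @param cal_floor_factor detection amplitude floor used in transmission
#'   calibration, as a multiple of `profile$noise_rms`.
#' @return a list of class `crackle_recording`: `signal` (samples x
#'   channels matrix), `sample_rate`, `geometry`, `breaths` (segment
#'   table), `crackles` (one row per generated crackle with source
#'   location, realized pitch/T1/polarity, mother channel and achieved
#'   transmission), and `arrivals` (one row per channel arrival with onset
#'   time and peak amplitude).
#' @export
synthesize_recording <- function(profile, geometry = default_geometry(),
                                 duration = 20, n_breaths = 3, seed = 1,
                                 sample_rate = 8000, insp_fraction = 0.4,
                                 cal_floor_factor = 3.5) {
  stopifnot(inherits(profile, "disease_profile"),
            inherits(geometry, "channel_geometry"))
  if (duration < 2 * n_breaths)
    stop("duration must be at least 2 s per breath", call. = FALSE)
  sides <- table(geometry$channels$side)
  if (length(sides) < 2 || any(sides < 2))
    stop("geometry must have at least 2 channels per side ",
         "(transmission coefficient undefined otherwise)", call. = FALSE)
  set.seed(seed)

  fs <- sample_rate
  nch <- nrow(geometry$channels)
  n <- floor(duration * fs)
  v <- geometry$sound_speed
  p <- profile

  # breath segmentation: equal breaths, fixed inspiratory fraction
  blen <- duration / n_breaths
  b0 <- (seq_len(n_breaths) - 1) * blen
  breaths <- data.frame(breath = seq_len(n_breaths),
                        insp_start = b0,
                        insp_end = b0 + insp_fraction * blen,
                        exp_end = b0 + blen)

  # patient-level effects (half the profile variance)
  s2 <- sqrt(0.5)
  pitch_p <- rtrunc_norm(1, p$pitch_mean, p$pitch_sd * s2, 120, 0.11 * fs)
  rate_insp_p <- max(stats::rnorm(1, p$insp_crackle_rate_mean,
                                  p$insp_crackle_rate_sd * s2), 0)
  rate_exp_p <- max(stats::rnorm(1, p$exp_crackle_rate_mean,
                                 p$exp_crackle_rate_sd * s2), 0)
  nhp_p <- max(stats::rnorm(1, p$n_half_periods_mean,
                            p$n_half_periods_sd * s2), 4)
  pol_p <- min(max(stats::rnorm(1, p$positive_polarity_fraction, 0.10),
                   0.02), 0.98)
  trans_p <- min(max(stats::rnorm(1, p$transmission_level, p$transmission_sd),
                     0), 0.95)
  if (p$transmission_level == 0) trans_p <- 0
  source_side_focal <- sample(c("left", "right"), 1)
  focal_quadrant <- sample(c("top", "bottom"), 1)
  focal_quadrant <- paste0(focal_quadrant, "-", source_side_focal)

  # largest half-period count whose decayed amplitude stays above the
  # 10% decomposition floor, so generated and measured counts agree
  nhp_max <- if (p$amplitude_decay < 1)
    1L + floor(log(0.12) / log(p$amplitude_decay)) else 24L

  # per-breath, per-phase crackle counts
  plan <- do.call(rbind, lapply(seq_len(n_breaths), function(b) {
    rbind(
      data.frame(breath = b, phase = "inspiration",
                 count = max(0L, round(stats::rnorm(1, rate_insp_p,
                                                    p$insp_crackle_rate_sd * s2)))),
      data.frame(breath = b, phase = "expiration",
                 count = max(0L, round(stats::rnorm(1, rate_exp_p,
                                                    p$exp_crackle_rate_sd * s2)))))
  }))
  n_crk <- sum(plan$count)

  signal <- matrix(stats::rnorm(n * nch, 0, p$noise_rms), n, nch)

  # breath-sound component: band-limited (< 300 Hz) noise shaped by a
  # per-phase envelope, louder during inspiration
  lp <- signal::butter(2, 300 / (fs / 2), type = "low")
  lp_g2 <- zero_phase_gain2(lp, n)
  tt <- (seq_len(n) - 1) / fs
  env <- numeric(n)
  for (b in seq_len(n_breaths)) {
    ii <- tt >= breaths$insp_start[b] & tt < breaths$insp_end[b]
    ei <- tt >= breaths$insp_end[b] & tt < breaths$exp_end[b]
    env[ii] <- 0.8 * sin(pi * (tt[ii] - breaths$insp_start[b]) /
                           (breaths$insp_end[b] - breaths$insp_start[b]))
    env[ei] <- 0.4 * sin(pi * (tt[ei] - breaths$insp_end[b]) /
                           (breaths$exp_end[b] - breaths$insp_end[b]))
  }
  # one breath-sound realization per side: chest-wall breath sounds are
  # strongly correlated among neighbouring microphones
  bs_side <- replicate(2, {
    bs <- zero_phase_filter(lp, stats::rnorm(n), g2 = lp_g2)
    bs / max(stats::sd(bs), 1e-12)
  })
  side_idx <- as.integer(geometry$channels$side == "right") + 1L
  for (c in seq_len(nch))
    signal[, c] <- signal[, c] + p$noise_rms * env * bs_side[, side_idx[c]]

  crackles <- NULL
  arrivals <- NULL
  if (n_crk > 0) {
    mics <- as.matrix(geometry$channels[, c("x", "y", "z")])
    # local detection floor: the detector's background rises with the
    # in-band part of the breath sound, so the floor tracks the envelope
    env_at <- function(t) env[min(max(round(t * fs) + 1L, 1L), n)]
    floor_at <- function(t) cal_floor_factor * p$noise_rms *
      sqrt(1 + (1.2 * env_at(t))^2)
    crk_list <- vector("list", n_crk)
    arr_list <- vector("list", n_crk)
    id <- 0L
    for (r in seq_len(nrow(plan))) {
      if (plan$count[r] == 0L) next
      seg <- breaths[plan$breath[r], ]
      lim <- if (plan$phase[r] == "inspiration")
        c(seg$insp_start, seg$insp_end) else c(seg$insp_end, seg$exp_end)
      for (k in seq_len(plan$count[r])) {
        id <- id + 1L
        side <- if (p$spatial_pattern == "focal") source_side_focal else
          sample(c("left", "right"), 1)
        src <- sample_sources(1, p$spatial_pattern, side, focal_quadrant)
        t0 <- stats::runif(1, lim[1] + 0.05, lim[2] - 0.08)

        # crackle-level waveform parameters
        pitch_c <- rtrunc_norm(1, pitch_p, p$pitch_sd * s2, 100, 0.12 * fs)
        nhp_c <- min(max(4L, round(stats::rnorm(1, nhp_p, p$n_half_periods_sd * s2))),
                     nhp_max)
        pol_c <- if (stats::runif(1) < pol_p) 1 else -1
        amp_c <- stats::rlnorm(1, p$amplitude_meanlog, p$amplitude_sdlog)
        t1_ms <- 2000 / (pitch_c * (1 + 3 * p$t2_over_t1))
        dur <- c(t1_ms, rep(p$t2_over_t1 * t1_ms, nhp_c - 1L)) *
          exp(stats::rnorm(nhp_c, 0, p$duration_jitter))
        amp <- p$amplitude_decay^(seq_len(nhp_c) - 1L) *
          exp(stats::rnorm(nhp_c, 0, p$amplitude_jitter))
        amp[-1] <- pmin(pmax(amp[-1], 0.12), 0.95)  # keep A1 the peak, all above floor
        amp[1] <- 1
        wave <- synthesize_crackle(sample_rate = fs, polarity = pol_c,
                                   durations_ms = dur, amplitudes = amp)

        # project onto ipsilateral channels
        ips <- which(geometry$channels$side == side)
        d <- sqrt(rowSums((mics[ips, , drop = FALSE] -
                             matrix(src, length(ips), 3, byrow = TRUE))^2))
        mother_i <- which.min(d)
        kfac <- exp(-(d - d[mother_i]) / p$lambda)
        floor_amp <- floor_at(t0)
        g <- calibrate_gain(100 * trans_p, kfac[-mother_i], amp_c, floor_amp)
        scale <- g * kfac
        scale[mother_i] <- 1
        ratios <- pmin(scale[-mother_i], 1)
        ratios[scale[-mother_i] * amp_c < floor_amp] <- 0
        ctc_true <- 100 * sum(ratios) / (length(ips) - 1L)

        t_arr <- t0 + (d - d[mother_i]) / v / 1000  # mother arrives at t0
        # children below the detection floor are not inserted at all: they
        # would not be measurable, and leaving them out keeps the achieved
        # transmission of the signal equal to the calibrated value
        keep <- scale * amp_c >= floor_amp
        keep[mother_i] <- TRUE
        for (j in which(keep)) {
          i0 <- round(t_arr[j] * fs) + 1L
          i1 <- min(i0 + length(wave) - 1L, n)
          if (i0 >= 1 && i0 <= n)
            signal[i0:i1, ips[j]] <- signal[i0:i1, ips[j]] +
              amp_c * scale[j] * wave[seq_len(i1 - i0 + 1L)]
        }

        peak_ms <- (t0 + dur[1] / 2000) * 1000
        third <- timing_code_at(t0 + dur[1] / 2000, seg)
        crk_list[[id]] <- data.frame(
          crackle = id, breath = plan$breath[r], phase = plan$phase[r],
          timing_code = third,
          x = src[1], y = src[2], z = src[3],
          onset_ms = t0 * 1000, peak_ms = peak_ms,
          pitch = 2000 / sum(dur[1:4]), t1_ms = dur[1],
          t2_over_t1 = dur[2] / dur[1],
          n_half_periods = nhp_c, polarity = pol_c,
          amplitude = amp_c, ctc_true = ctc_true,
          mother_channel = geometry$channels$channel[ips[mother_i]])
        arr_list[[id]] <- data.frame(
          crackle = id, channel = geometry$channels$channel[ips],
          onset_ms = t_arr * 1000,
          peak_ms = (t_arr + dur[1] / 2000) * 1000,
          amplitude = amp_c * scale,
          is_mother = seq_along(ips) == mother_i)[keep, ]
      }
    }
    crackles <- do.call(rbind, crk_list)
    arrivals <- do.call(rbind, arr_list)
    rownames(crackles) <- rownames(arrivals) <- NULL
  } else {
    crackles <- data.frame()
    arrivals <- data.frame()
  }

  structure(list(signal = signal, sample_rate = fs, geometry = geometry,
                 breaths = breaths, crackles = crackles, arrivals = arrivals,
                 profile = p$name, seed = seed),
            class = "crackle_recording")
}

#' @export
print.crackle_recording <- function(x, ...) {
  cat("<crackle_recording>", x$profile, "profile, seed", x$seed, "\n")
  cat(sprintf("  %.1f s x %d channels at %d Hz, %d breaths, %d crackles\n",
              nrow(x$signal) / x$sample_rate, ncol(x$signal), x$sample_rate,
              nrow(x$breaths), nrow(x$crackles)))
  invisible(x)
}
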