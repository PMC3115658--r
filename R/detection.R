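#' Detector configuration
#'
#' Parameters of the per-channel crackle detector: a band-pass filter, a
#' transient score (rectified amplitude over a trailing background RMS),
#' a score threshold, a maximum rise time from onset to peak, a dead time
#' between events and the analysis window length.
#'
#' @param band band-pass corner frequencies in Hz.
#' @param threshold transient score threshold.
#' @param bg_window_ms trailing background RMS window in ms.
#' @param dead_time_ms minimum separation between events on one channel.
#' @param max_rise_ms maximum onset-to-peak rise time for a candidate.
#' @param window_ms length of the waveform window cut around each peak.
#' @return a list of class `detector_config`.
#' @export
detector_config <- function(band = c(100, 2000), threshold = 4,
                            bg_window_ms = 200, dead_time_ms = 10,
                            max_rise_ms = 3, window_ms = 20,
                            energy_factor = 2, energy_window_ms = 3) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1],
            threshold > 0, bg_window_ms > 0, dead_time_ms > 0,
            max_rise_ms > 0, window_ms > 0, energy_factor >= 0)
  structure(list(band = band, threshold = threshold,
                 bg_window_ms = bg_window_ms, dead_time_ms = dead_time_ms,
                 max_rise_ms = max_rise_ms, window_ms = window_ms,
                 energy_factor = energy_factor,
                 energy_window_ms = energy_window_ms),
            class = "detector_config")
}

#' Segment a recording into breaths
#'
#' When `known_boundaries` is supplied (synthetic recordings carry their
#' true boundaries) it is validated and returned unchanged. Otherwise
#' boundaries are estimated from the low-frequency (< 300 Hz) breath-sound
#' envelope: the squared signal is smoothed, troughs of the smoothed
#' envelope mark breath boundaries, and the envelope peak between two
#' boundaries marks the inspiration/expiration transition. Only full
#' breaths are returned.
#'
#' @param x single-channel signal.
#' @param sample_rate Hz.
#' @param known_boundaries optional data.frame with columns `breath`,
#'   `insp_start`, `insp_end`, `exp_end` (seconds).
#' @return data.frame of breath segments (possibly empty, with a warning,
#'   when no breath cycle is detectable).
#' @export
segment_breaths <- function(x, sample_rate, known_boundaries = NULL) {
  if (!is.null(known_boundaries)) {
    b <- as.data.frame(known_boundaries)
    stopifnot(all(c("breath", "insp_start", "insp_end", "exp_end") %in% names(b)))
    if (any(b$insp_start >= b$insp_end | b$insp_end >= b$exp_end))
      stop("breath boundaries must satisfy insp_start < insp_end < exp_end",
           call. = FALSE)
    return(b)
  }
  fs <- sample_rate
  n <- length(x)
  if (n < fs * 2) {
    warning("signal shorter than one breath; no segments")
    return(empty_breaths())
  }
  lp <- signal::butter(2, min(300 / (fs / 2), 0.9), type = "low")
  xl <- zero_phase_filter(lp, x)
  env <- sqrt(moving_mean(xl^2, round(0.2 * fs)))
  sm <- moving_mean(env, round(0.75 * fs))
  base <- stats::quantile(sm, 0.1, names = FALSE)
  height <- max(sm) - base
  if (height < 5 * stats::sd(diff(sm)) || height < 1e-9) {
    warning("no detectable breath cycle")
    return(empty_breaths())
  }
  # sound humps above threshold; inspiratory humps are the tall ones and
  # each breath runs from one inspiratory hump to just before the next
  thr <- base + 0.3 * height
  r <- rle(sm > thr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  h_start <- starts[r$values]; h_end <- ends[r$values]
  h_peak <- vapply(seq_along(h_start), function(i)
    max(sm[h_start[i]:h_end[i]]), numeric(1))
  insp <- which(h_peak - base >= 0.55 * height)
  # merge inspiratory humps closer than a plausible breath period
  if (length(insp) > 1) insp <- insp[c(TRUE, diff(h_start[insp]) > 2 * fs)]
  if (length(insp) < 1) {
    warning("no detectable breath cycle")
    return(empty_breaths())
  }
  segs <- list()
  for (j in seq_along(insp)) {
    i <- insp[j]
    nxt <- if (j < length(insp)) h_start[insp[j + 1]] else length(sm) + 1L
    # expiration extends through the (quieter) expiratory hump; when that
    # hump is buried in the noise the breath still runs to just before
    # the next inspiration
    tail_humps <- which(h_start > h_end[i] & h_end < nxt)
    tail_end <- if (length(tail_humps)) max(h_end[tail_humps]) else NA_integer_
    exp_end <- if (j < length(insp)) {
      floor(if (is.na(tail_end)) nxt - 1L else (tail_end + nxt) / 2)
    } else tail_end                       # last breath needs a visible end
    if (j == length(insp) && is.na(exp_end)) break
    if (j == length(insp) && (nxt - exp_end) < 0.2 * fs) break  # cut-off breath
    insp_start <- h_start[i]
    insp_end <- h_end[i]
    if (insp_end <= insp_start || exp_end <= insp_end) next
    segs[[length(segs) + 1L]] <- data.frame(
      breath = length(segs) + 1L,
      insp_start = (insp_start - 1) / fs,
      insp_end = (insp_end - 1) / fs,
      exp_end = (exp_end - 1) / fs)
  }
  if (!length(segs)) {
    warning("fewer than one full breath detected")
    return(empty_breaths())
  }
  do.call(rbind, segs)
}

empty_breaths <- function() {
  data.frame(breath = integer(), insp_start = numeric(),
             insp_end = numeric(), exp_end = numeric())
}

# zero-phase IIR filtering in the frequency domain: applies the filter's
# squared magnitude response |H(f)|^2, the ideal that forward-backward
# filtering approximates, in O(n log n) via FFT
.gain_cache <- new.env(parent = emptyenv())

zero_phase_gain2 <- function(flt, n) {
  key <- paste(n, paste(signif(c(flt$b, flt$a), 12), collapse = ","))
  hit <- .gain_cache[[key]]
  if (!is.null(hit)) return(hit)
  z <- exp(-2i * pi * (seq_len(n) - 1) / n)
  horner <- function(cf) {          # evaluate sum cf[k+1] z^k
    acc <- rep(cf[length(cf)] + 0i, n)
    for (k in rev(seq_len(length(cf) - 1L))) acc <- acc * z + cf[k]
    acc
  }
  g2 <- Mod(horner(flt$b) / horner(flt$a))^2
  if (length(ls(.gain_cache)) > 20) rm(list = ls(.gain_cache),
                                       envir = .gain_cache)
  .gain_cache[[key]] <- g2
  g2
}

zero_phase_filter <- function(flt, x, X = NULL, g2 = NULL) {
  n <- length(if (is.null(X)) x else X)
  if (is.null(X)) X <- stats::fft(x)
  if (is.null(g2)) g2 <- zero_phase_gain2(flt, n)
  Re(stats::fft(X * g2, inverse = TRUE)) / n
}

# O(n) trailing/centred moving average via cumulative sums
moving_mean <- function(x, k, trailing = FALSE) {
  n <- length(x)
  k <- max(1L, min(k, n))
  cs <- cumsum(x)
  if (trailing) {
    lo <- pmax(seq_len(n) - k, 0L)
    (cs - c(0, cs)[lo + 1L]) / (seq_len(n) - lo)
  } else {
    h <- k %/% 2L
    hi <- pmin(seq_len(n) + h, n)
    lo <- pmax(seq_len(n) - h - 1L, 0L)
    (cs[hi] - c(0, cs)[lo + 1L]) / (hi - lo)
  }
}

#' Timing code of a time point within a breath
#'
#' Codes 1-3 are the early/mid/late thirds of inspiration, 4-6 the
#' early/mid/late thirds of expiration. Thirds are computed on each
#' phase's own duration.
#'
#' @param t time in seconds.
#' @param segment one row of a breath segment table.
#' @return integer in 1..6, or NA if `t` lies outside the breath.
#' @export
timing_code_at <- function(t, segment) {
  if (t < segment$insp_start || t > segment$exp_end) return(NA_integer_)
  if (t < segment$insp_end) {
    frac <- (t - segment$insp_start) / (segment$insp_end - segment$insp_start)
    as.integer(min(3, 1 + floor(frac * 3)))
  } else {
    frac <- (t - segment$insp_end) / (segment$exp_end - segment$insp_end)
    as.integer(min(6, 4 + floor(frac * 3)))
  }
}

#' Detect crackles on one channel
#'
#' Band-passes the signal, scores every sample as rectified amplitude over
#' a trailing background RMS (computed on an amplitude-clipped copy so
#' that the crackles themselves do not inflate the background), and turns
#' supra-threshold runs into events. Runs closer than the dead time merge;
#' each event is windowed symmetrically around its highest absolute
#' deflection, truncated at breath boundaries; events must rise from onset
#' to peak within the configured rise time and lie inside a full breath.
#'
#' @param x single-channel signal.
#' @param sample_rate Hz.
#' @param segments breath segment table from [segment_breaths()].
#' Candidate events must additionally show sustained transient energy: the
#' local RMS over a few milliseconds around the peak must exceed
#' `energy_factor` times the background, which isolated noise exceedances
#' essentially never do.
#'
#' @param config a [detector_config()].
#' @return data.frame with one row per event: `onset_s`, `peak_s`,
#'   `peak_amplitude` (band-passed), `breath`, `timing_code`, and the
#'   windowed waveform in the list column `waveform`.
#' @export
detect_crackles <- function(x, sample_rate, segments,
                            config = detector_config()) {
  stopifnot(inherits(config, "detector_config"))
  if (nrow(segments) == 0L)
    stop("breath segments must be non-empty", call. = FALSE)
  fs <- sample_rate
  n <- length(x)
  bp <- signal::butter(4, pmin(config$band / (fs / 2), 0.99), type = "pass")
  # feature windows come from a gentler (order-2) filter over the same
  # band: the steep detection band-pass can swallow the baseline
  # crossings of short low-amplitude half-periods
  fp <- signal::butter(2, pmin(config$band / (fs / 2), 0.99), type = "pass")
  X <- stats::fft(x)
  xb <- zero_phase_filter(bp, X = X)
  xf <- zero_phase_filter(fp, X = X)
  sigma0 <- stats::mad(xb[seq.int(1L, n, by = 4L)])
  if (sigma0 <= 0) sigma0 <- stats::sd(xb) + 1e-12
  clip <- pmin(abs(xb), 3 * sigma0)
  k <- round(config$bg_window_ms / 1000 * fs)
  bg <- sqrt(pmax(moving_mean(c(rep(sigma0^2, k), clip^2), k,
                              trailing = TRUE)[-seq_len(k)],
                  (0.25 * sigma0)^2))
  bg <- c(sigma0, bg[-n])                # strictly trailing
  score <- abs(xb) / bg
  cand <- score > config$threshold
  if (!any(cand)) return(empty_events())
  eh <- max(1L, round(config$energy_window_ms / 2000 * fs))
  rms_at <- function(i) sqrt(mean(xb[max(1L, i - eh):min(n, i + eh)]^2))

  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]
  # merge runs separated by less than the dead time; remember the original
  # sub-run onsets so the rise time is measured from the supra-threshold
  # onset of the deflection that actually peaks
  if (length(run_start) > 1L) {
    gap <- (run_start[-1] - run_end[-length(run_end)]) / fs * 1000
    grp <- cumsum(c(1L, as.integer(gap >= config$dead_time_ms)))
  } else grp <- rep(1L, length(run_start))
  ev_start <- tapply(run_start, grp, min)
  ev_end <- tapply(run_end, grp, max)

  half <- round(config$window_ms / 2000 * fs)
  out <- lapply(seq_along(ev_start), function(i) {
    i0 <- ev_start[i]; i1 <- ev_end[i]
    pk <- i0 + which.max(abs(xb[i0:i1])) - 1L
    t_pk <- (pk - 1) / fs
    # explosive onset: the signal must have been near baseline (below 10%
    # of the peak) within the allowed rise time before the peak
    lo <- max(1L, pk - ceiling(config$max_rise_ms / 1000 * fs))
    if (!any(abs(xb[lo:pk]) < 0.1 * abs(xb[pk]))) return(NULL)
    if (rms_at(pk) < config$energy_factor * bg[pk]) return(NULL)
    b <- which(segments$insp_start <= t_pk & t_pk <= segments$exp_end)
    if (!length(b)) return(NULL)
    b <- b[1]
    w0 <- max(pk - half, 1L, floor(segments$insp_start[b] * fs) + 1L)
    w1 <- min(pk + half, n, ceiling(segments$exp_end[b] * fs))
    data.frame(onset_s = (i0 - 1) / fs, peak_s = t_pk,
               peak_amplitude = abs(xb[pk]),
               breath = segments$breath[b],
               timing_code = timing_code_at(t_pk, segments[b, ]),
               waveform = I(list(xf[w0:w1])))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty_events() else { rownames(out) <- NULL; out }
}

empty_events <- function() {
  data.frame(onset_s = numeric(), peak_s = numeric(),
             peak_amplitude = numeric(), breath = integer(),
             timing_code = integer(), waveform = I(list()))
}

#' Detect crackles on every channel of a recording
#'
#' Convenience wrapper running [detect_crackles()] per channel of a
#' multichannel signal matrix.
#'
#' @param signal samples x channels matrix.
#' @param sample_rate Hz.
#' @param segments breath segment table.
#' @param geometry a [channel_geometry()] whose channel ids index the
#'   matrix columns.
#' @param config a [detector_config()].
#' @return data.frame of events across channels with a `channel` column
#'   and an `event` id.
#' @export
detect_all_channels <- function(signal, sample_rate, segments,
                                geometry, config = detector_config()) {
  chans <- geometry$channels$channel
  out <- lapply(seq_along(chans), function(j) {
    ev <- detect_crackles(signal[, j], sample_rate, segments, config)
    if (nrow(ev)) ev$channel <- chans[j]
    ev
  })
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    return(cbind(empty_events(), channel = integer(), event = integer()))
  out <- out[order(out$peak_s), ]
  out$event <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
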