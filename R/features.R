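#' Decompose a crackle window into half-periods
#'
#' Half-periods are the intervals between consecutive baseline crossings
#' of the (detrended) waveform. T1 is the half-period containing the
#' highest absolute peak; subsequent half-periods are enumerated rightward.
#' Enumeration stops when a half-period's amplitude falls below the
#' configured floor (a fraction of the highest peak) or when the window
#' runs out of complete half-periods. Crossing positions are refined by
#' linear interpolation between samples, so durations are sub-sample
#' accurate on clean waveforms.
#'
#' @param waveform numeric crackle window.
#' @param sample_rate Hz.
#' @param floor_frac amplitude floor as a fraction of the highest peak.
#' @param detrend subtract the window median (robust baseline) before
#'   finding crossings.
#' @return a list of class `hp_decomposition` with fields `valid`,
#'   `T_ms` (ordered half-period durations), `A` (per-half-period peak
#'   amplitudes), `peak_sign` (+1/-1), `n`, and `reason` when invalid
#'   (fewer than four half-periods above the floor).
#' @export
decompose_half_periods <- function(waveform, sample_rate, floor_frac = 0.1,
                                   detrend = TRUE) {
  w <- as.numeric(waveform)
  if (detrend) w <- w - stats::median(w)
  n <- length(w)
  if (n < 8 || all(w == 0))
    return(invalid_decomp("window empty or too short"))
  # highest |peak|; sampled near-ties (within 2%) resolve to the earliest,
  # since the mother deflection reaches the microphone first
  a_max <- max(abs(w))
  p <- which(abs(w) >= (1 - 0.02) * a_max)[1]
  a1 <- abs(w[p])
  peak_sign <- sign(w[p])

  cr <- zero_crossings(w)
  if (length(cr) < 2) return(invalid_decomp("fewer than 2 baseline crossings"))

  # amplitude floor: fraction of the highest peak, but never below the
  # window's own noise level, estimated from the pre-onset segment (the
  # window is centred on the peak, so its first quarter precedes the
  # crackle); fall back to a lower-quartile estimate for short windows
  pre <- w[seq_len(min(max(8L, floor(n / 4)), max(p - 8L, 8L)))]
  noise_sigma <- if (length(pre) >= 8) stats::mad(pre) else
    stats::quantile(abs(w), 0.25, names = FALSE) / 0.32
  floor_amp <- max(floor_frac * a1, 1.5 * noise_sigma)

  # noise briefly re-crosses the baseline inside a genuine half-period,
  # splitting off sub-floor slivers far shorter than any physiological
  # half-period; merge those back into their neighbours
  min_frag <- 0.4 / 1000 * sample_rate       # samples
  repeat {
    if (length(cr) < 2) break
    amps <- vapply(seq_len(length(cr) - 1L), function(i) {
      samp <- seq(ceiling(cr[i]), floor(cr[i + 1L]))
      if (length(samp)) max(abs(w[samp])) else 0
    }, numeric(1))
    frag <- which(diff(cr) < min_frag & amps < floor_amp)
    if (!length(frag)) break
    cr <- cr[-c(frag[1], frag[1] + 1L)]      # drop both bounding crossings
  }
  if (length(cr) < 2) return(invalid_decomp("fewer than 2 baseline crossings"))

  left <- cr[cr < p]
  right <- cr[cr >= p]
  if (!length(left) || !length(right))
    return(invalid_decomp("highest peak not bracketed by baseline crossings"))
  # boundaries from the crossing just left of the peak rightward
  bounds <- c(left[length(left)], right)
  T_ms <- numeric(0)
  A <- numeric(0)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    samp <- seq(ceiling(lo), floor(hi))
    amp <- if (length(samp)) max(abs(w[samp])) else 0
    if (amp < floor_amp) break
    T_ms <- c(T_ms, (hi - lo) / sample_rate * 1000)
    A <- c(A, amp)
  }
  if (length(T_ms) < 4)
    return(invalid_decomp("fewer than 4 half-periods above the amplitude floor"))
  structure(list(valid = TRUE, T_ms = T_ms, A = A,
                 peak_sign = peak_sign, n = length(T_ms), reason = NULL),
            class = "hp_decomposition")
}

invalid_decomp <- function(reason) {
  structure(list(valid = FALSE, T_ms = numeric(), A = numeric(),
                 peak_sign = NA_real_, n = 0L, reason = reason),
            class = "hp_decomposition")
}

# Fractional sample positions of baseline crossings. Sign changes between
# non-zero samples are interpolated linearly; zero runs bounded by
# opposite signs cross at the run centre; a leading/trailing zero run next
# to signal counts as a crossing at its inner edge.
zero_crossings <- function(w) {
  n <- length(w)
  nz <- which(w != 0)
  if (length(nz) < 2) return(numeric(0))
  cr <- numeric(0)
  s_prev <- sign(w[nz[1]])
  i_prev <- nz[1]
  if (nz[1] > 1) cr <- nz[1] - 1          # onset out of a leading zero run
  for (j in nz[-1]) {
    s <- sign(w[j])
    if (s != s_prev) {
      if (j - i_prev == 1L) {
        cr <- c(cr, i_prev + w[i_prev] / (w[i_prev] - w[j]))
      } else {
        cr <- c(cr, (i_prev + j) / 2)     # crossing inside a zero run
      }
    }
    s_prev <- s
    i_prev <- j
  }
  if (i_prev < n) cr <- c(cr, i_prev + 1) # decay into a trailing zero run
  cr
}

#' Per-crackle waveform features
#'
#' Computes the individual crackle features from a half-period
#' decomposition: number of baseline crossings (ZXS), T1, pitch
#' (`2000 / (T1+T2+T3+T4)` Hz with durations in ms), T2/T1, half-period
#' duration variability (SD/mean x 100%), amplitude of the highest peak,
#' A2/A1, A3/A1, half-period amplitude variability, and polarity. The
#' transmission coefficient slot is left unset; it is a family-level
#' quantity filled in by [compute_ctc()].
#'
#' @param d an `hp_decomposition` from [decompose_half_periods()].
#' @param timing_code integer 1-6 locating the crackle within its breath.
#' @return one-row data.frame of features.
#' @examples
#' d <- decompose_half_periods(synthesize_crackle(416.67, 4), 8000)
#' compute_features(d, timing_code = 1)$pitch
#' @export
compute_features <- function(d, timing_code = NA_integer_) {
  stopifnot(inherits(d, "hp_decomposition"))
  if (!isTRUE(d$valid) || d$n < 4)
    stop("cannot compute features: ", d$reason %||% "decomposition invalid",
         call. = FALSE)
  T_ms <- d$T_ms; A <- d$A
  data.frame(
    zxs = d$n + 1L,
    t1 = T_ms[1],
    pitch = 2000 / sum(T_ms[1:4]),
    t2_over_t1 = T_ms[2] / T_ms[1],
    duration_variability = stats::sd(T_ms) / mean(T_ms) * 100,
    timing_code = as.integer(timing_code),
    ctc = NA_real_,
    amplitude = A[1],
    a2_over_a1 = A[2] / A[1],
    a3_over_a1 = A[3] / A[1],
    amplitude_variability = stats::sd(A) / mean(A) * 100,
    polarity = d$peak_sign
  )
}

#' Per-patient feature summary
#'
#' Combines a patient's per-crackle features within one breath phase into
#' medians and means, plus the crackle rate (crackles per full breath).
#' With no crackles in the phase the summary is flagged missing rather
#' than zero.
#'
#' @param features per-crackle feature table with a `phase` column
#'   (`"inspiration"` / `"expiration"`).
#' @param phase which phase to summarize.
#' @param n_breaths number of full breaths the features came from (needed
#'   for the crackle rate).
#' @return one-row data.frame with `crackle_rate`, `n_crackles`,
#'   `missing`, and `median_*` / `mean_*` columns for each feature.
#' @export
patient_feature_summary <- function(features, phase = c("inspiration", "expiration"),
                                    n_breaths = NULL) {
  phase <- match.arg(phase)
  cols <- c("zxs", "t1", "pitch", "t2_over_t1", "duration_variability",
            "timing_code", "ctc", "amplitude", "a2_over_a1", "a3_over_a1",
            "amplitude_variability", "polarity")
  f <- if (NROW(features) == 0L || is.null(features$phase))
    data.frame() else features[features$phase == phase, , drop = FALSE]
  if (nrow(f) == 0L) {
    out <- data.frame(phase = phase, n_crackles = 0L, missing = TRUE,
                      crackle_rate = NA_real_, positive_polarity_pct = NA_real_)
    for (cc in cols) {
      out[[paste0("median_", cc)]] <- NA_real_
      out[[paste0("mean_", cc)]] <- NA_real_
    }
    return(out)
  }
  out <- data.frame(phase = phase, n_crackles = nrow(f), missing = FALSE,
                    crackle_rate = if (is.null(n_breaths)) NA_real_ else
                      nrow(f) / n_breaths,
                    positive_polarity_pct = mean(f$polarity > 0) * 100)
  for (cc in cols) {
    v <- f[[cc]]
    out[[paste0("median_", cc)]] <- stats::median(v, na.rm = TRUE)
    out[[paste0("mean_", cc)]] <- mean(v, na.rm = TRUE)
  }
  out
}
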