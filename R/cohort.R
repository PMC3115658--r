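#' Extract crackle features from a recording
#'
#' Runs the full measurement chain on one multichannel recording: breath
#' segmentation (true boundaries are used when the recording carries
#' them), per-channel detection, grouping into crackle families,
#' half-period feature extraction on each mother crackle, transmission
#' coefficient, source localization, and per-breath aggregate features.
#'
#' @param rec a `crackle_recording` from [synthesize_recording()], or a
#'   list with `signal`, `sample_rate`, `geometry` and optionally
#'   `breaths`.
#' @param detector a [detector_config()].
#' @param family_window_ms grouping window for [group_families()].
#' @param localize compute source locations.
#' @return list with `crackles` (family-level feature table), `breaths`
#'   (per-breath aggregates incl. zero-crackle breaths), `segments`, and
#'   `diagnostics` (discard and exclusion counts).
#' @export
extract_recording <- function(rec, detector = detector_config(),
                              family_window_ms = 10, localize = TRUE) {
  segments <- segment_breaths(rec$signal[, 1], rec$sample_rate,
                              known_boundaries = rec$breaths)
  events <- detect_all_channels(rec$signal, rec$sample_rate, segments,
                                rec$geometry, detector)
  ft <- family_table(events, rec$geometry, rec$sample_rate,
                     window_ms = family_window_ms, localize = localize)
  crackles <- ft$crackles
  aggs <- lapply(segments$breath, function(b) {
    rows <- if (nrow(crackles)) crackles[crackles$breath == b, ] else crackles
    cbind(breath = b, aggregate_breath(rows, rec$geometry))
  })
  breaths <- do.call(rbind, aggs)
  list(crackles = crackles, breaths = breaths, segments = segments,
       diagnostics = list(n_events = nrow(events),
                          n_families_discarded = ft$n_discarded,
                          n_zero_crackle_breaths =
                            sum(breaths$crackles_per_breath == 0)))
}

#' Simulate and measure one patient
#'
#' @param profile a [disease_profile()].
#' @param patient patient id.
#' @param seed integer seed for the recording.
#' @param geometry a [channel_geometry()].
#' @param ... passed to [synthesize_recording()].
#' @param detector a [detector_config()].
#' @return list with tagged `crackles` and `breaths` tables and the
#'   recording's diagnostics.
#' @export
simulate_patient <- function(profile, patient, seed,
                             geometry = default_geometry(), ...,
                             detector = detector_config()) {
  rec <- synthesize_recording(profile, geometry, seed = seed, ...)
  ex <- extract_recording(rec, detector = detector)
  if (nrow(ex$crackles)) {
    ex$crackles$patient <- patient
    ex$crackles$group <- profile$name
  }
  ex$breaths$patient <- patient
  ex$breaths$group <- profile$name
  ex$n_breaths <- nrow(ex$segments)
  ex
}

#' Simulate a multi-group cohort
#'
#' Synthesizes one recording per patient for each diagnostic group and
#' runs [extract_recording()] on each, returning pooled feature tables
#' ready for [cross_validate()] and [compare_groups()]. Per-patient seeds
#' are drawn reproducibly from `seed`.
#'
#' @param n named integer vector of patients per group, e.g.
#'   `c(IPF = 39, CHF = 95, PN = 123)`; names must be built-in profile
#'   names unless `profiles` is given.
#' @param seed integer master seed.
#' @param profiles optional named list of [disease_profile()]s overriding
#'   the built-ins.
#' @param geometry a [channel_geometry()].
#' @param duration,n_breaths recording length per patient.
#' @param detector a [detector_config()].
#' @param progress print one dot per patient.
#' @return list of class `crackle_cohort` with `crackles`, `breaths`,
#'   `patients` and `summaries` (per patient x phase, see
#'   [patient_feature_summary()]).
#' @export
simulate_cohort <- function(n, seed = 1, profiles = NULL,
                            geometry = default_geometry(),
                            duration = 20, n_breaths = 3,
                            detector = detector_config(),
                            progress = FALSE) {
  stopifnot(!is.null(names(n)), all(n >= 1))
  if (is.null(profiles))
    profiles <- stats::setNames(lapply(names(n), builtin_profile), names(n))
  set.seed(seed)
  total <- sum(n)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  crk <- list(); bre <- list(); summ <- list(); pats <- list()
  i <- 0L
  for (g in names(n)) {
    for (j in seq_len(n[[g]])) {
      i <- i + 1L
      pid <- sprintf("%s_%03d", g, j)
      ex <- simulate_patient(profiles[[g]], pid, seeds[i],
                             geometry = geometry, duration = duration,
                             n_breaths = n_breaths, detector = detector)
      crk[[i]] <- ex$crackles
      bre[[i]] <- ex$breaths
      pats[[i]] <- data.frame(patient = pid, group = g, seed = seeds[i])
      for (ph in c("inspiration", "expiration")) {
        s <- patient_feature_summary(ex$crackles, ph, n_breaths = ex$n_breaths)
        s$patient <- pid; s$group <- g
        summ[[length(summ) + 1L]] <- s
      }
      if (progress) cat(".")
    }
  }
  if (progress) cat("\n")
  structure(list(
    crackles = do.call(rbind, crk[vapply(crk, NROW, 1L) > 0]),
    breaths = do.call(rbind, bre),
    patients = do.call(rbind, pats),
    summaries = do.call(rbind, summ)),
    class = "crackle_cohort")
}
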