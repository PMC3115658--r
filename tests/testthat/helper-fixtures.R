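# Shared fixtures. The acceptance-scale cohort is expensive, so it is
# built lazily once per test run and reused by every file that needs it.

.fixture_env <- new.env(parent = emptyenv())

# simple symmetric two-side geometry used by unit tests: 3 channels per
# side in a vertical line, 8 cm apart
toy_geometry <- function(n_per_side = 3, sound_speed = 3) {
  z <- seq(2, by = 8, length.out = n_per_side)
  channel_geometry(data.frame(
    channel = seq_len(2 * n_per_side),
    x = rep(c(-8, 8), each = n_per_side),
    y = 0,
    z = rep(z, 2),
    side = rep(c("left", "right"), each = n_per_side),
    quadrant = paste0(ifelse(rep(z, 2) >= 14, "top-", "bottom-"),
                      rep(c("left", "right"), each = n_per_side))),
    sound_speed = sound_speed)
}

# one breath: inspiration 0-1 s, expiration 1-3 s
toy_segment <- function() {
  data.frame(breath = 1L, insp_start = 0, insp_end = 1, exp_end = 3)
}

# a crackle family table as produced by grouping, from explicit amplitudes
make_family <- function(channels, amplitudes, peak_s = NULL,
                        mother = which.max(amplitudes)) {
  data.frame(channel = channels, peak_amplitude = amplitudes,
             peak_s = peak_s %||% rep(0.5, length(channels)),
             is_mother = seq_along(channels) == mother)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# study-scale synthetic cohort (Table-3-profiled group sizes), built once
acceptance_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- simulate_cohort(
      c(IPF = 39, CHF = 95, PN = 123), seed = 20250901,
      geometry = default_geometry(14))
  }
  .fixture_env$cohort
}

# replicate same-profile two-group comparisons (type-I calibration),
# built once and shared
null_comparison_flags <- function() {
  if (is.null(.fixture_env$null_flags)) {
    geo <- default_geometry(14)
    prof <- builtin_profile("CHF")
    flags <- c()
    for (rep in 1:6) {
      co <- simulate_cohort(c(A = 8, B = 8), seed = 9000 + rep,
                            profiles = list(A = prof, B = prof),
                            geometry = geo, duration = 12, n_breaths = 3)
      cmp <- compare_groups(co$summaries, ref = "A", comparisons = "B")
      flags <- c(flags, cmp$sig_B)
    }
    .fixture_env$null_flags <- flags
  }
  .fixture_env$null_flags
}

# small mixed cohort for cheaper integration tests
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      c(IPF = 5, CHF = 5), seed = 404, geometry = default_geometry(14))
  }
  .fixture_env$small
}
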