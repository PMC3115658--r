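#' Group per-channel detections into crackle families
#'
#' A crackle family is the set of detections, across ipsilateral channels,
#' produced by one physical crackling event. Grouping is greedy: the
#' largest-amplitude unassigned event becomes a mother crackle; every
#' unassigned ipsilateral event whose peak lies within the grouping window
#' of the mother's peak joins its family, at most one per channel (nearest
#' in time wins). Every event ends up in exactly one family.
#'
#' @param events event table from [detect_all_channels()] (needs `event`,
#'   `channel`, `peak_s`, `peak_amplitude`).
#' @param geometry a [channel_geometry()].
#' @param window_ms grouping half-window in ms around the mother's peak.
#' @return `events` with added `family` and `is_mother` columns, ordered
#'   as the input.
#' @export
group_families <- function(events, geometry, window_ms = 10) {
  ev <- as.data.frame(events)
  if (nrow(ev) == 0L) {
    ev$family <- integer(0); ev$is_mother <- logical(0)
    return(ev)
  }
  side <- channel_side(geometry, ev$channel)
  ord <- order(-ev$peak_amplitude)
  fam <- rep(NA_integer_, nrow(ev))
  mother <- rep(FALSE, nrow(ev))
  fid <- 0L
  for (i in ord) {
    if (!is.na(fam[i])) next
    fid <- fid + 1L
    fam[i] <- fid
    mother[i] <- TRUE
    cand <- which(is.na(fam) & side == side[i] &
                    abs(ev$peak_s - ev$peak_s[i]) <= window_ms / 1000)
    if (length(cand)) {
      # one member per channel: nearest in time to the mother
      dt <- abs(ev$peak_s[cand] - ev$peak_s[i])
      best <- tapply(seq_along(cand), ev$channel[cand],
                     function(j) cand[j][which.min(dt[j])])
      keep <- unlist(best, use.names = FALSE)
      keep <- keep[ev$channel[keep] != ev$channel[i]]
      fam[keep] <- fid
    }
  }
  ev$family <- fam
  ev$is_mother <- mother
  ev
}

#' Crackle transmission coefficient of a family
#'
#' CTC measures how strongly a crackle's sound reaches the other
#' ipsilateral channels: with N channels on the mother's side,
#' `ctc = 100 / (N - 1) * sum over the N - 1 non-mother channels of
#' min(A_c / A_mother, 1)`, a channel without a family member
#' contributing 0. It is 0% when nothing is transmitted and 100% when
#' every ipsilateral channel receives the mother's amplitude.
#'
#' @param family data.frame of one family's members with `channel` and
#'   `peak_amplitude` columns and a logical `is_mother` column (exactly
#'   one TRUE).
#' @param geometry a [channel_geometry()].
#' @return CTC in percent, in [0, 100].
#' @examples
#' geo <- default_geometry(14)
#' fam <- data.frame(channel = 1, peak_amplitude = 1, is_mother = TRUE)
#' compute_ctc(fam, geo)  # 0: no transmission
#' @export
compute_ctc <- function(family, geometry) {
  stopifnot(sum(family$is_mother) == 1L)
  m <- family[family$is_mother, ]
  ips <- ipsilateral_channels(geometry, m$channel)
  n_side <- length(ips)
  if (n_side < 2)
    stop("CTC undefined: fewer than 2 channels on the mother's side",
         call. = FALSE)
  others <- setdiff(ips, m$channel)
  ratio <- rep(0, length(others))
  ch <- family$channel[!family$is_mother]
  amp <- family$peak_amplitude[!family$is_mother]
  idx <- match(ch, others)
  ok <- !is.na(idx)
  ratio[idx[ok]] <- pmin(amp[ok] / m$peak_amplitude, 1)
  100 * sum(ratio) / (n_side - 1L)
}

#' Localize a crackle source from arrival-time differences
#'
#' With at least three family members, the source position is found by
#' least squares over candidate positions inside the chest volume,
#' minimizing the squared mismatch between observed peak-time delays
#' (relative to the mother) and delays predicted as
#' distance / sound_speed. Families with fewer members fall back to the
#' mother microphone's position projected a default depth into the chest.
#'
#' @param family one family's member rows (`channel`, `peak_s`,
#'   `is_mother`).
#' @param geometry a [channel_geometry()].
#' @param default_depth fallback projection depth in cm.
#' @return numeric `c(x, y, z)` in cm with attribute `method`
#'   (`"multilateration"` or `"fallback"`).
#' @export
localize_crackle <- function(family, geometry, default_depth = 6) {
  stopifnot(sum(family$is_mother) == 1L)
  m <- family[family$is_mother, ]
  mpos <- drop(channel_position(geometry, m$channel))
  inward <- if (mpos[2] < 10) default_depth else -default_depth
  fallback <- function() {
    structure(c(mpos[1], mpos[2] + inward, mpos[3]), method = "fallback",
              names = c("x", "y", "z"))
  }
  if (nrow(family) < 3) return(fallback())
  pos <- channel_position(geometry, family$channel)
  obs <- (family$peak_s - m$peak_s) * 1000          # ms
  v <- geometry$sound_speed
  ssq <- function(s) {
    d <- sqrt(colSums((t(pos) - s)^2))
    dm <- sqrt(sum((mpos - s)^2))
    sum((obs - (d - dm) / v)^2)
  }
  ch <- geometry$channels
  lower <- c(min(ch$x) - 5, min(ch$y), min(ch$z) - 4)
  upper <- c(max(ch$x) + 5, max(ch$y) + ifelse(max(ch$y) == 0, 20, 0),
             max(ch$z) + 4)
  start <- pmin(pmax(c(mpos[1], mpos[2] + inward, mpos[3]), lower), upper)
  fit <- tryCatch(
    stats::optim(start, ssq, method = "L-BFGS-B", lower = lower, upper = upper),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback())
  structure(fit$par, method = "multilateration", names = c("x", "y", "z"))
}

#' Build the family table of a recording
#'
#' Runs [group_families()], then per family computes the transmission
#' coefficient and (optionally) the source location, and extracts the
#' mother crackle's waveform features via [decompose_half_periods()] and
#' [compute_features()]. Families whose mother waveform yields fewer than
#' four half-periods are discarded and counted.
#'
#' @param events event table from [detect_all_channels()].
#' @param geometry a [channel_geometry()].
#' @param sample_rate Hz (for the feature decomposition).
#' @param window_ms grouping window, see [group_families()].
#' @param localize compute source locations (needed for aggregate
#'   spatial features).
#' @param floor_frac amplitude floor for [decompose_half_periods()].
#' @return list with `crackles` (one row per family: features + `ctc`,
#'   `x`, `y`, `z`, `mother_channel`, `n_members`, `breath`, `phase`),
#'   `events` (the grouped event table) and `n_discarded`.
#' @export
family_table <- function(events, geometry, sample_rate, window_ms = 10,
                         localize = TRUE, floor_frac = 0.1) {
  ev <- group_families(events, geometry, window_ms)
  if (nrow(ev) == 0L)
    return(list(crackles = data.frame(), events = ev, n_discarded = 0L))
  discarded <- 0L
  rows <- lapply(split(seq_len(nrow(ev)), ev$family), function(ii) {
    fam <- ev[ii, ]
    m <- fam[fam$is_mother, ]
    d <- decompose_half_periods(m$waveform[[1]], sample_rate,
                                floor_frac = floor_frac)
    if (!d$valid) { discarded <<- discarded + 1L; return(NULL) }
    feat <- compute_features(d, m$timing_code)
    feat$ctc <- compute_ctc(fam, geometry)
    loc <- if (localize) localize_crackle(fam, geometry) else
      rep(NA_real_, 3)
    feat$x <- loc[1]; feat$y <- loc[2]; feat$z <- loc[3]
    feat$family <- fam$family[1]
    feat$mother_channel <- m$channel
    feat$n_members <- nrow(fam)
    feat$breath <- m$breath
    feat$peak_s <- m$peak_s
    feat$phase <- if (m$timing_code <= 3L) "inspiration" else "expiration"
    feat
  })
  crackles <- do.call(rbind, rows)
  if (is.null(crackles)) crackles <- data.frame()
  rownames(crackles) <- NULL
  list(crackles = crackles, events = ev, n_discarded = discarded)
}
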