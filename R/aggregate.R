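QUADRANTS <- c("top-left", "top-right", "bottom-left", "bottom-right")
QUADRANT_PAIRS <- utils::combn(QUADRANTS, 2)

#' Per-breath aggregate crackle features
#'
#' Summarizes the spatial distribution of one breath's crackles: the total
#' count, the count per chest quadrant (quadrant of the mother channel, so
#' single-channel families still contribute), the six pairwise percentage
#' differences between quadrant counts
#' `100 * (n_i - n_j) / max(n_i + n_j, 1)` in the fixed order
#' (TL,TR), (TL,BL), (TL,BR), (TR,BL), (TR,BR), (BL,BR), the maximum
#' distances between localized crackles along each axis and overall
#' (Euclidean), and the same distance features computed from the mother
#' microphone positions ("channel distances"). A breath with no crackles
#' yields zero counts, zero distances and zero percentage differences.
#'
#' @param crackles rows of a family-level crackle table for one breath
#'   (needs `mother_channel` and, for the spatial distances, `x`, `y`,
#'   `z`).
#' @param geometry a [channel_geometry()].
#' @return one-row data.frame of aggregate features.
#' @export
aggregate_breath <- function(crackles, geometry) {
  n <- if (is.null(crackles) || nrow(crackles) == 0L) 0L else nrow(crackles)
  counts <- stats::setNames(integer(4), QUADRANTS)
  if (n > 0) {
    q <- channel_quadrant(geometry, crackles$mother_channel)
    tq <- table(factor(q, levels = QUADRANTS))
    counts[names(tq)] <- as.integer(tq)
  }
  out <- data.frame(crackles_per_breath = n,
                    q_top_left = counts[1], q_top_right = counts[2],
                    q_bottom_left = counts[3], q_bottom_right = counts[4])
  for (k in seq_len(ncol(QUADRANT_PAIRS))) {
    a <- counts[QUADRANT_PAIRS[1, k]]
    b <- counts[QUADRANT_PAIRS[2, k]]
    nm <- paste0("pctdiff_", gsub("-", "", QUADRANT_PAIRS[1, k]), "_",
                 gsub("-", "", QUADRANT_PAIRS[2, k]))
    out[[nm]] <- 100 * (a - b) / max(a + b, 1)
  }
  dist_feats <- function(xyz) {
    if (nrow(xyz) < 2 || anyNA(xyz))
      return(c(dx = 0, dy = 0, dz = 0, overall = 0))
    dx <- max(xyz[, 1]) - min(xyz[, 1])
    dy <- max(xyz[, 2]) - min(xyz[, 2])
    dz <- max(xyz[, 3]) - min(xyz[, 3])
    c(dx = dx, dy = dy, dz = dz,
      overall = max(stats::dist(xyz)))
  }
  src <- if (n > 0) as.matrix(crackles[, c("x", "y", "z")]) else
    matrix(numeric(), 0, 3)
  mic <- if (n > 0) channel_position(geometry, crackles$mother_channel) else
    matrix(numeric(), 0, 3)
  ds <- dist_feats(src)
  dc <- dist_feats(mic)
  out$max_distance_x <- ds["dx"]; out$max_distance_y <- ds["dy"]
  out$max_distance_z <- ds["dz"]; out$max_distance_overall <- ds["overall"]
  out$channel_distance_x <- dc["dx"]; out$channel_distance_y <- dc["dy"]
  out$channel_distance_z <- dc["dz"]; out$channel_distance_overall <- dc["overall"]
  rownames(out) <- NULL
  out
}

aggregate_feature_cols <- function() {
  c("crackles_per_breath", "q_top_left", "q_top_right", "q_bottom_left",
    "q_bottom_right",
    paste0("pctdiff_", c("topleft_topright", "topleft_bottomleft",
                         "topleft_bottomright", "topright_bottomleft",
                         "topright_bottomright", "bottomleft_bottomright")),
    "max_distance_x", "max_distance_y", "max_distance_z",
    "max_distance_overall",
    "channel_distance_x", "channel_distance_y", "channel_distance_z",
    "channel_distance_overall")
}
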