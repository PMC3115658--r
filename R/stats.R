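#' Group comparison report
#'
#' Produces a per-feature, per-phase comparison of per-patient feature
#' summaries between a reference group and each comparison group:
#' group means and SDs plus an unpaired two-sample t-test p-value per
#' comparison. Welch's unequal-variance form is the default; the pooled
#' classic form is available via `var_equal = TRUE`. No multiple-testing
#' correction is applied; rows with p < 0.05 are flagged. Degenerate
#' variance (both groups constant) yields p = 1 with a flag.
#'
#' @param summaries per-patient summary table (one row per patient and
#'   phase) with `group` and `phase` columns, as produced by
#'   [simulate_cohort()].
#' @param features character vector of summary columns to compare
#'   (defaults to the per-patient mean of each individual crackle feature
#'   plus the crackle rate and polarity percentage).
#' @param ref reference group label.
#' @param comparisons groups to compare against `ref`.
#' @param var_equal use the pooled-variance t-test.
#' @return data.frame with one row per feature x phase: per-group
#'   `mean_<g>` / `sd_<g>`, and per comparison `p_<g>` and
#'   `sig_<g>` flags.
#' @export
compare_groups <- function(summaries, features = NULL, ref = "IPF",
                           comparisons = setdiff(unique(summaries$group), ref),
                           var_equal = FALSE) {
  if (is.null(features)) {
    features <- c("crackle_rate",
                  paste0("mean_", c("pitch", "t1", "zxs", "t2_over_t1",
                                    "duration_variability", "timing_code",
                                    "ctc", "amplitude", "a2_over_a1",
                                    "a3_over_a1", "amplitude_variability")),
                  "positive_polarity_pct")
  }
  groups <- c(ref, comparisons)
  for (g in groups) {
    ng <- sum(summaries$group == g & !summaries$missing) / 2
    if (ng < 2) stop("need at least 2 patients with crackles in group ", g,
                     call. = FALSE)
  }
  rows <- list()
  for (ph in unique(summaries$phase)) {
    sph <- summaries[summaries$phase == ph & !summaries$missing, ]
    for (feat in features) {
      row <- data.frame(feature = feat, phase = ph)
      vals <- lapply(groups, function(g) {
        v <- sph[[feat]][sph$group == g]
        v[is.finite(v)]
      })
      names(vals) <- groups
      for (g in groups) {
        row[[paste0("mean_", g)]] <- mean(vals[[g]])
        row[[paste0("sd_", g)]] <- stats::sd(vals[[g]])
      }
      for (g in comparisons) {
        a <- vals[[ref]]; b <- vals[[g]]
        degenerate <- length(a) < 2 || length(b) < 2 ||
          (stats::sd(a) == 0 && stats::sd(b) == 0)
        if (degenerate) {
          row[[paste0("p_", g)]] <- 1
          row[[paste0("flag_degenerate_", g)]] <- TRUE
        } else {
          row[[paste0("p_", g)]] <-
            stats::t.test(a, b, var.equal = var_equal)$p.value
          row[[paste0("flag_degenerate_", g)]] <- FALSE
        }
        row[[paste0("sig_", g)]] <- row[[paste0("p_", g)]] < 0.05
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a group comparison as a markdown table
#'
#' @param comparison output of [compare_groups()].
#' @param digits significant digits for means/SDs.
#' @return character vector of markdown lines.
#' @export
comparison_markdown <- function(comparison, digits = 3) {
  gcols <- grep("^mean_", names(comparison), value = TRUE)
  groups <- sub("^mean_", "", gcols)
  pcols <- grep("^p_", names(comparison), value = TRUE)
  hdr <- c("feature", "phase", groups, sub("^p_", "p ", pcols))
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"), "|"))
  for (i in seq_len(nrow(comparison))) {
    cells <- c(comparison$feature[i], comparison$phase[i],
               vapply(groups, function(g) sprintf(
                 "%s ± %s",
                 signif(comparison[[paste0("mean_", g)]][i], digits),
                 signif(comparison[[paste0("sd_", g)]][i], digits)),
                 character(1)),
               vapply(pcols, function(p) format.pval(comparison[[p]][i],
                                                     digits = 2),
                      character(1)))
    lines <- c(lines, paste0("| ", paste(cells, collapse = " | "), " |"))
  }
  lines
}
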