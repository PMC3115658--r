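sep_toy <- function(n = 60, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n * 3), ncol = 3),
             matrix(stats::rnorm(n * 3, mean = gap), ncol = 3))
  list(x = x, y = rep(c("A", "B"), each = n))
}

test_that("both classifier kinds separate a separable toy problem perfectly", {
  toy <- sep_toy()
  for (kind in c("svm", "nn")) {
    clf <- train_crackle_classifier(toy$x, toy$y, kind = kind, seed = 2)
    pred <- predict(clf, toy$x)
    expect_equal(mean(pred$label == toy$y), 1, label = kind)
    expect_true(all(abs(pred$score_A + pred$score_B - 1) < 1e-6))
  }
})

test_that("training is deterministic given a seed and rejects single-class data", {
  toy <- sep_toy(gap = 1)
  m1 <- train_crackle_classifier(toy$x, toy$y, "nn", seed = 7)
  m2 <- train_crackle_classifier(toy$x, toy$y, "nn", seed = 7)
  expect_identical(predict(m1, toy$x)$score_A, predict(m2, toy$x)$score_A)
  expect_error(train_crackle_classifier(toy$x, rep("A", nrow(toy$x))),
               "two classes")
})

test_that("majority voting picks the modal label, with score and priority tie-breaks", {
  # worked example: 6 breaths, 3 IPF / 2 CHF / 1 PN
  v <- vote(c("IPF", "IPF", "IPF", "CHF", "CHF", "PN"))
  expect_equal(v$winner, "IPF")
  expect_false(v$tie_flag)
  # unanimity at any size
  for (n in c(1, 2, 9)) {
    expect_equal(vote(rep("CHF", n))$winner, "CHF")
  }
  # tie broken by larger summed score
  v2 <- vote(c("IPF", "CHF"), scores = c(0.9, 0.6))
  expect_equal(v2$winner, "IPF")
  expect_true(v2$tie_flag)
  # then by priority order
  v3 <- vote(c("PN", "CHF"), priority = c("CHF", "PN"))
  expect_equal(v3$winner, "CHF")
  expect_true(v3$tie_flag)
  expect_error(vote(character(0)), "empty")
})

test_that("breath classification votes over crackles or fuses aggregates", {
  pred <- data.frame(label = factor(c("A", "A", "B"), levels = c("A", "B")),
                     score_A = c(0.8, 0.7, 0.4), score_B = c(0.2, 0.3, 0.6))
  expect_equal(classify_breath(pred, mode = "crackle_only"), "A")
  expect_error(classify_breath(pred, mode = "crackle_plus_aggregate"),
               "breath model")
  expect_error(classify_breath(pred[0, ], mode = "crackle_only"),
               "no crackles")
})

test_that("confusion metrics follow their definitions", {
  truth <- c(rep("IPF", 10), rep("PN", 10))
  pred <- c(rep("IPF", 9), "PN", rep("PN", 8), "IPF", "IPF")
  m <- eval_metrics(truth, pred, positive = "IPF")
  expect_equal(m$tp, 9); expect_equal(m$fn, 1)
  expect_equal(m$tn, 8); expect_equal(m$fp, 2)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$accuracy, 0.85)
})

test_that("folds are stratified and never split a patient", {
  pat <- data.frame(patient = sprintf("p%02d", 1:23),
                    group = rep(c("IPF", "CHF"), c(8, 15)))
  f <- make_patient_folds(pat, k = 5, seed = 3)
  expect_equal(f$k, 5)
  expect_true(all(table(f$fold, pat$group)[, "IPF"] >= 1))
  # patient-level assignment is a function: one fold per patient
  expect_equal(length(f$fold), nrow(pat))
  expect_warning(make_patient_folds(pat[c(1, 9:23), ], k = 5), "reducing folds")
})

test_that("cross-validation never leaks a patient across folds and scores an oracle perfectly", {
  co <- small_cohort()
  # leakage guard: reconstruct folds and check patient partition
  pat <- unique(co$crackles[, c("patient", "group")])
  f <- make_patient_folds(pat, k = 3, seed = 5)
  co$crackles$fold_chk <- f$fold[match(co$crackles$patient, pat$patient)]
  expect_true(all(tapply(co$crackles$fold_chk, co$crackles$patient,
                         function(v) length(unique(v))) == 1))
  # oracle upper bound: make one feature equal the class label
  co2 <- co
  co2$crackles$pitch <- ifelse(co2$crackles$group == "IPF", 1000, 100)
  cv <- cross_validate(co2, "IPF_vs_CHF", k = 3, seed = 5, kinds = "svm")
  m <- cv$metrics
  expect_equal(m$accuracy[m$level == "patient" & m$mode == "crackle_only"], 1)
  expect_equal(m$sensitivity[m$level == "crackle"], 1)
  expect_equal(m$specificity[m$level == "crackle"], 1)
})

test_that("permuted labels collapse accuracy to chance", {
  co <- acceptance_cohort()
  sub <- co
  # balance the two classes first so that chance level is one half
  pat0 <- unique(sub$crackles[sub$crackles$group %in% c("IPF", "CHF"),
                              c("patient", "group")])
  set.seed(314)
  keep_pat <- c(pat0$patient[pat0$group == "IPF"],
                sample(pat0$patient[pat0$group == "CHF"],
                       sum(pat0$group == "IPF")))
  sub$crackles <- sub$crackles[sub$crackles$patient %in% keep_pat, ]
  pat <- unique(sub$crackles[, c("patient", "group")])
  relab <- stats::setNames(sample(pat$group), pat$patient)  # permute patients
  sub$crackles$group <- unname(relab[sub$crackles$patient])
  sub$breaths$group <- unname(relab[sub$breaths$patient])
  sub$breaths <- sub$breaths[!is.na(sub$breaths$group), ]
  cv <- cross_validate(sub, "IPF_vs_CHF", k = 5, seed = 9, kinds = "svm")
  acc <- cv$metrics$accuracy[cv$metrics$level == "patient" &
                               cv$metrics$mode == "crackle_plus_aggregate"]
  n_pat <- nrow(pat)
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_pat) + 0.08)
})
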