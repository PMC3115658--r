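CRACKLE_FEATURE_COLS <- c("zxs", "t1", "pitch", "t2_over_t1",
                          "duration_variability", "timing_code", "ctc",
                          "amplitude", "a2_over_a1", "a3_over_a1",
                          "amplitude_variability", "polarity")

#' Train a binary crackle-level classifier
#'
#' Fits either an RBF-kernel support vector machine or a single-hidden-
#' layer backpropagation neural network on per-crackle feature vectors.
#' Features are standardized using training statistics only; the fitted
#' object carries the scaler so predictions standardize identically.
#'
#' @param x numeric matrix/data.frame of per-crackle features.
#' @param y class labels (2 levels; both must be present).
#' @param kind `"svm"` or `"nn"`.
#' @param seed integer seed making the fit deterministic.
#' @param size,decay,maxit neural-network hyperparameters.
#' @return an object of class `crackle_classifier`.
#' @export
train_crackle_classifier <- function(x, y, kind = c("svm", "nn"), seed = 1,
                                     size = 16, decay = 0.5, maxit = 300) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2L || any(table(y) == 0))
    stop("training data must contain exactly two classes, both non-empty",
         call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- 1
  xs <- scale(x, center = mu, scale = sd_)
  set.seed(seed)
  model <- if (kind == "svm") {
    e1071::svm(xs, y, kernel = "radial", probability = TRUE, scale = FALSE)
  } else {
    nnet::nnet(xs, stats::model.matrix(~ y - 1)[, 1, drop = FALSE],
               size = size, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE)
  }
  structure(list(model = model, kind = kind, levels = levels(y),
                 center = mu, scale = sd_),
            class = "crackle_classifier")
}

#' Predict classes and scores for crackle feature vectors
#'
#' @param object a `crackle_classifier`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return data.frame with `label` and a `score` column per class
#'   (probability-like, summing to 1 per row).
#' @export
predict.crackle_classifier <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center,
              scale = object$scale)
  lv <- object$levels
  if (object$kind == "svm") {
    pr <- stats::predict(object$model, xs, probability = TRUE)
    p <- attr(pr, "probabilities")[, lv, drop = FALSE]
  } else {
    p1 <- as.numeric(stats::predict(object$model, xs))
    p <- cbind(p1, 1 - p1)
    colnames(p) <- lv
  }
  lab <- lv[max.col(p, ties.method = "first")]
  out <- data.frame(label = factor(lab, levels = lv))
  out[[paste0("score_", lv[1])]] <- p[, 1]
  out[[paste0("score_", lv[2])]] <- p[, 2]
  out
}

#' Majority vote over constituent units
#'
#' The winner is the modal label; ties are broken by the larger summed
#' score, then by the configured class priority (order of `priority`, or
#' the factor/sort order of the labels). `tie_flag` records whether the
#' maximal count was shared.
#'
#' @param member_labels character/factor labels of the members.
#' @param scores optional numeric per-member score supporting its label.
#' @param priority optional character vector giving the tie-break class
#'   order.
#' @return list of class `vote_tally`: `votes`, `winner`, `tie_flag`.
#' @examples
#' vote(c("IPF", "IPF", "IPF", "CHF", "CHF", "PN"))$winner
#' @export
vote <- function(member_labels, scores = NULL, priority = NULL) {
  labs <- as.character(member_labels)
  if (length(labs) == 0L) stop("cannot vote over an empty member list",
                               call. = FALSE)
  lev <- if (!is.null(priority)) priority else
    if (is.factor(member_labels)) levels(member_labels) else sort(unique(labs))
  lev <- union(lev, unique(labs))
  votes <- table(factor(labs, levels = lev))
  top <- names(votes)[votes == max(votes)]
  tie_flag <- length(top) > 1L
  winner <- if (!tie_flag) top[1] else {
    if (!is.null(scores)) {
      ssum <- vapply(top, function(l) sum(scores[labs == l]), numeric(1))
      cand <- top[ssum == max(ssum)]
      cand[1]                         # summed score, then priority order
    } else top[1]
  }
  structure(list(votes = votes, winner = winner, tie_flag = tie_flag),
            class = "vote_tally")
}

#' Train the breath-level fusion classifier
#'
#' Second stage for the crackle-plus-aggregate mode: a classifier of the
#' same kind fitted on per-breath vectors made of the crackle vote
#' fractions and mean per-class scores concatenated with the aggregate
#' spatial features.
#'
#' @param breath_x per-breath fused feature matrix.
#' @param y per-breath labels.
#' @inheritParams train_crackle_classifier
#' @return a `crackle_classifier` fitted on breath vectors.
#' @export
train_breath_classifier <- function(breath_x, y, kind = c("svm", "nn"),
                                    seed = 1) {
  train_crackle_classifier(breath_x, y, kind = kind, seed = seed, size = 8)
}

breath_fusion_vector <- function(crackle_pred, positive, aggregates = NULL) {
  frac <- mean(crackle_pred$label == positive)
  msc <- mean(crackle_pred[[paste0("score_", positive)]])
  v <- c(vote_fraction = frac, mean_score = msc)
  if (!is.null(aggregates)) v <- c(v, unlist(aggregates))
  v
}

#' Classify one breath from its crackle predictions
#'
#' In `crackle_only` mode the breath label is the majority vote over the
#' breath's predicted crackle labels (score-weighted tie-break). In
#' `crackle_plus_aggregate` mode a trained breath-level model is applied
#' to the vote fractions fused with the breath's aggregate features.
#'
#' @param crackle_pred prediction table for the breath's crackles (from
#'   [predict.crackle_classifier()]).
#' @param aggregates one-row aggregate feature vector (required in
#'   aggregate mode).
#' @param mode `"crackle_only"` or `"crackle_plus_aggregate"`.
#' @param model_b trained breath model (required in aggregate mode).
#' @return predicted class label (character).
#' @export
classify_breath <- function(crackle_pred, aggregates = NULL,
                            mode = c("crackle_only", "crackle_plus_aggregate"),
                            model_b = NULL) {
  mode <- match.arg(mode)
  if (nrow(crackle_pred) == 0L)
    stop("breath has no crackles; exclude it from voting", call. = FALSE)
  if (mode == "crackle_only") {
    lv <- levels(crackle_pred$label)
    sc <- vapply(seq_len(nrow(crackle_pred)), function(i)
      crackle_pred[[paste0("score_", crackle_pred$label[i])]][i], numeric(1))
    return(vote(crackle_pred$label, scores = sc, priority = lv)$winner)
  }
  if (is.null(model_b))
    stop("crackle_plus_aggregate mode needs a trained breath model",
         call. = FALSE)
  lv <- model_b$levels
  v <- breath_fusion_vector(crackle_pred, lv[1], aggregates)
  as.character(predict(model_b, matrix(v, 1,
                                       dimnames = list(NULL, names(v))))$label)
}

#' Sensitivity, specificity and accuracy
#'
#' Confusion-matrix metrics with a designated positive class.
#'
#' @param truth,pred class labels.
#' @param positive the positive class (default `"IPF"`).
#' @return one-row data.frame with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
eval_metrics <- function(truth, pred, positive = "IPF") {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  data.frame(tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             accuracy = (tp + tn) / length(truth))
}

#' Stratified patient-level folds
#'
#' Splits patients into k folds, stratified by class, so that no
#' patient's crackles ever span the train/test boundary. A class with
#' fewer than k patients reduces k with a warning.
#'
#' @param patients data.frame with `patient` and `group` columns (one row
#'   per patient).
#' @param k number of folds.
#' @param seed integer seed.
#' @return list with `fold` (integer per patient row) and `k`.
#' @export
make_patient_folds <- function(patients, k = 5, seed = 1) {
  stopifnot(k >= 2)
  kmin <- min(table(patients$group))
  if (kmin < k) {
    warning("a class has fewer than ", k, " patients; reducing folds to ", kmin)
    k <- kmin
  }
  set.seed(seed)
  fold <- integer(nrow(patients))
  for (g in unique(patients$group)) {
    idx <- sample(which(patients$group == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  list(fold = fold, k = k)
}

#' Cross-validated hierarchical classification
#'
#' Evaluates a binary task (IPF vs CHF or IPF vs PN) with patient-level
#' stratified k-fold cross-validation. Per fold, a crackle-level
#' classifier is trained on the training patients' crackles; held-out
#' crackles are classified; breaths are labelled by majority voting over
#' their crackles (`crackle_only`) and by a second-stage model fusing
#' vote fractions with the breath's aggregate spatial features
#' (`crackle_plus_aggregate`); patients are labelled by majority voting
#' over their breaths. Breaths with no detected crackles are excluded
#' from voting and counted in the diagnostics.
#'
#' @param cohort a cohort list as returned by [simulate_cohort()]:
#'   `crackles` (per-crackle features with `patient`, `breath`, `group`),
#'   `breaths` (per-breath aggregates keyed by `patient`, `breath`) and
#'   `patients`.
#' @param task `"IPF_vs_CHF"` or `"IPF_vs_PN"`.
#' @param k folds.
#' @param seed integer seed (folds and classifier fits).
#' @param kinds classifier kinds to evaluate.
#' @param positive positive class for the metrics.
#' @return list with `metrics` (one row per kind x level x mode),
#'   `predictions` (held-out patient-level predictions) and
#'   `n_breaths_excluded`.
#' @export
cross_validate <- function(cohort, task = c("IPF_vs_CHF", "IPF_vs_PN"),
                           k = 5, seed = 1, kinds = c("svm", "nn"),
                           positive = "IPF") {
  task <- match.arg(task)
  classes <- strsplit(task, "_vs_")[[1]]
  crk <- cohort$crackles[cohort$crackles$group %in% classes, ]
  bre <- cohort$breaths[cohort$breaths$group %in% classes, ]
  pat <- unique(crk[, c("patient", "group")])
  folds <- make_patient_folds(pat, k, seed)
  crk$fold <- folds$fold[match(crk$patient, pat$patient)]
  agg_cols <- intersect(aggregate_feature_cols(), names(bre))
  excluded <- sum(bre$crackles_per_breath == 0)

  res <- list(); preds <- list()
  for (kind in kinds) {
    pooled <- list(crackle = NULL, breath_co = NULL, breath_agg = NULL,
                   patient_co = NULL, patient_agg = NULL)
    for (f in seq_len(folds$k)) {
      tr <- crk[crk$fold != f, ]
      te <- crk[crk$fold == f, ]
      if (nrow(te) == 0L || length(unique(tr$group)) < 2) next
      clf <- train_crackle_classifier(tr[, CRACKLE_FEATURE_COLS], tr$group,
                                      kind = kind, seed = seed + f)
      # breath-level training set for the fusion model
      tr_pred <- predict(clf, tr[, CRACKLE_FEATURE_COLS])
      positive_b <- sort(classes)[1]   # factor level order used by the models
      tr_key <- paste(tr$patient, tr$breath)
      btr <- unique(data.frame(patient = tr$patient, breath = tr$breath,
                               group = tr$group, key = tr_key))
      bx <- t(vapply(seq_len(nrow(btr)), function(i) {
        sel <- tr_key == btr$key[i]
        ag <- bre[bre$patient == btr$patient[i] & bre$breath == btr$breath[i],
                  agg_cols]
        breath_fusion_vector(tr_pred[sel, ], positive_b, ag[1, ])
      }, numeric(2 + length(agg_cols))))
      model_b <- train_breath_classifier(bx, btr$group, kind = kind,
                                         seed = seed + f)

      te_pred <- predict(clf, te[, CRACKLE_FEATURE_COLS])
      pooled$crackle <- rbind(pooled$crackle,
                              data.frame(truth = te$group,
                                         pred = as.character(te_pred$label)))
      te_key <- paste(te$patient, te$breath)
      bte <- unique(data.frame(patient = te$patient, breath = te$breath,
                               group = te$group, key = te_key))
      bte$pred_co <- bte$pred_agg <- NA_character_
      for (i in seq_len(nrow(bte))) {
        sel <- te_key == bte$key[i]
        ag <- bre[bre$patient == bte$patient[i] & bre$breath == bte$breath[i],
                  agg_cols]
        bte$pred_co[i] <- classify_breath(te_pred[sel, ], mode = "crackle_only")
        bte$pred_agg[i] <- classify_breath(te_pred[sel, ], aggregates = ag[1, ],
                                           mode = "crackle_plus_aggregate",
                                           model_b = model_b)
      }
      pooled$breath_co <- rbind(pooled$breath_co,
                                data.frame(truth = bte$group, pred = bte$pred_co))
      pooled$breath_agg <- rbind(pooled$breath_agg,
                                 data.frame(truth = bte$group, pred = bte$pred_agg))
      for (pt in unique(bte$patient)) {
        sel <- bte$patient == pt
        pooled$patient_co <- rbind(pooled$patient_co, data.frame(
          truth = bte$group[sel][1], pred = vote(bte$pred_co[sel])$winner,
          patient = pt, kind = kind))
        pooled$patient_agg <- rbind(pooled$patient_agg, data.frame(
          truth = bte$group[sel][1], pred = vote(bte$pred_agg[sel])$winner,
          patient = pt, kind = kind))
      }
    }
    lvl <- list(c("crackle", "crackle_only", "crackle"),
                c("breath_co", "crackle_only", "breath"),
                c("breath_agg", "crackle_plus_aggregate", "breath"),
                c("patient_co", "crackle_only", "patient"),
                c("patient_agg", "crackle_plus_aggregate", "patient"))
    for (L in lvl) {
      m <- eval_metrics(pooled[[L[1]]]$truth, pooled[[L[1]]]$pred, positive)
      m$kind <- kind; m$level <- L[3]; m$mode <- L[2]; m$task <- task
      res[[length(res) + 1L]] <- m
    }
    preds[[kind]] <- pooled$patient_agg
  }
  list(metrics = do.call(rbind, res), predictions = do.call(rbind, preds),
       n_breaths_excluded = excluded)
}
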