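#' Repeated random-split specification
#'
#' The evaluation protocol: `n_trials` independent patient-level random
#' splits. The test set defaults to 17 bronchitis and 15 pneumonia
#' patients per trial. Augmented chunk
#' copies always follow their source patient's side of the split, so no
#' augmented view of a test patient can leak into training.
#'
#' @param n_trials Number of random test experiments (default 45).
#' @param test_bronchitis,test_pneumonia Per-class test-set patient
#'   counts.
#' @param seed Base seed; trial `t` derives its split from
#'   `(seed, t)`.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(n_trials = 45, test_bronchitis = 17,
                       test_pneumonia = 15, seed = 1L) {
  stopifnot(n_trials > 0, test_bronchitis > 0, test_pneumonia > 0)
  structure(list(n_trials = n_trials, test_bronchitis = test_bronchitis,
                 test_pneumonia = test_pneumonia, seed = as.integer(seed)),
            class = "split_spec")
}

#' Patient-level random split
#'
#' @param patient_ids Character vector of patient ids (one per patient).
#' @param labels Labels in \{-1, +1\} aligned with `patient_ids`.
#' @param spec A [split_spec()].
#' @param trial Trial index (1-based); the split is reproducible from
#'   `(spec$seed, trial)`.
#' @return A list with character vectors `train` and `test`.
#' @export
split_patients <- function(patient_ids, labels, spec = split_spec(), trial = 1L) {
  stopifnot(length(patient_ids) == length(labels), all(labels %in% c(-1, 1)))
  neg <- patient_ids[labels == -1]
  pos <- patient_ids[labels == 1]
  if (spec$test_bronchitis > length(neg) || spec$test_pneumonia > length(pos)) {
    stop("requested test counts exceed class sizes")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed((spec$seed * 10007L + trial) %% .Machine$integer.max)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  test <- c(sample(neg, spec$test_bronchitis), sample(pos, spec$test_pneumonia))
  list(train = setdiff(patient_ids, test), test = test)
}

#' Classification metrics for a label pair
#'
#' Accuracy, per-class precision/recall/F1 and the 2x2 confusion
#' matrix. A zero denominator (e.g. a class never predicted) yields
#' `NA` ("undefined"), never a silent zero.
#'
#' @param y_true,y_pred Equal-length label vectors in \{-1, +1\}.
#' @return A list with `accuracy`, `confusion` (rows = true, cols =
#'   predicted, in class order -1, +1) and a `per_class` data.frame of
#'   precision/recall/f1 for bronchitis (-1) and pneumonia (+1).
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty label vectors")
  stopifnot(length(y_true) == length(y_pred),
            all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  classes <- c(-1, 1)
  confusion <- matrix(0L, 2, 2,
                      dimnames = list(true = c("-1", "1"), pred = c("-1", "1")))
  for (i in 1:2) for (j in 1:2) {
    confusion[i, j] <- sum(y_true == classes[i] & y_pred == classes[j])
  }
  per_class <- do.call(rbind, lapply(1:2, function(i) {
    tp <- confusion[i, i]
    fp <- sum(confusion[-i, i])
    fn <- sum(confusion[i, -i])
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
          else 2 * prec * rec / (prec + rec)
    data.frame(class = c("bronchitis", "pneumonia")[i],
               precision = prec, recall = rec, f1 = f1)
  }))
  list(accuracy = mean(y_true == y_pred), confusion = confusion,
       per_class = per_class)
}

#' F1 score from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`, on whatever scale precision and
#' recall share (fractions or percentages).
#'
#' @param precision,recall Non-negative numbers.
#' @return The F1 score on the same scale.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties cross the
#' threshold simultaneously) and integrates the curve with the
#' trapezoidal rule. Equivalent to the Mann-Whitney U statistic with
#' ties counted 1/2.
#'
#' @param scores Continuous classifier scores, larger = more positive.
#' @param y_true Labels in \{-1, +1\}; both classes must be present.
#' @return A list with `roc` (data.frame of `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  stopifnot(length(scores) == length(y_true), all(y_true %in% c(-1, 1)))
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for ROC")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y_true == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y_true == -1) / n_neg, numeric(1))
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  if (utils::tail(roc$fpr, 1) < 1 || utils::tail(roc$tpr, 1) < 1) {
    roc <- rbind(roc, data.frame(fpr = 1, tpr = 1, threshold = -Inf))
  }
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Repeated random-split evaluation
#'
#' Runs `spec$n_trials` split/train/test cycles of either classifier on
#' a per-patient feature table and aggregates the reported metrics:
#' accuracy mean and sample (n-1) standard deviation across trials,
#' per-class precision/recall/F1 and confusion matrix of the last
#' trial, per-trial AUC, and a pooled ROC over the concatenated
#' (score, label) pairs of all trials.
#'
#' @param features A data.frame from [patient_features()] (columns
#'   `patient_id`, `label`, `f1..`), with `attr(,"sequences")` present
#'   when `model = "lstm"`.
#' @param model `"svm"` or `"lstm"`.
#' @param spec A [split_spec()].
#' @param model_cfg An [svm_config()] or [sequence_model_config()].
#' @param standardize Standardize features before the SVM (fit on the
#'   training split only)?
#' @return An object of class `eval_report`.
#' @export
repeated_eval <- function(features, model = c("svm", "lstm"),
                          spec = split_spec(), model_cfg = NULL,
                          standardize = TRUE) {
  model <- match.arg(model)
  if (is.null(model_cfg)) {
    model_cfg <- if (model == "svm") svm_config() else sequence_model_config()
  }
  feat_cols <- grep("^f[0-9]+$", names(features), value = TRUE)
  X <- as.matrix(features[, feat_cols])
  y <- features$label
  ids <- features$patient_id
  seqs <- attr(features, "sequences")
  if (model == "lstm" && is.null(seqs)) {
    stop("features table lacks sequences; rerun patient_features(sequences = TRUE)")
  }

  accs <- numeric(spec$n_trials)
  aucs <- numeric(spec$n_trials)
  pooled_scores <- numeric(0)
  pooled_labels <- numeric(0)
  last <- NULL
  for (trial in seq_len(spec$n_trials)) {
    sp <- split_patients(ids, y, spec, trial)
    tr <- ids %in% sp$train
    te <- ids %in% sp$test
    if (model == "svm") {
      fit <- train_svm(X[tr, , drop = FALSE], y[tr], model_cfg,
                       standardize = standardize)
      pred <- predict_svm(fit, X[te, , drop = FALSE])
    } else {
      cfg <- model_cfg
      cfg$seed <- (cfg$seed + trial) %% .Machine$integer.max
      fit <- train_sequence_model(seqs[tr], y[tr], cfg)
      pred <- predict_sequence(fit, seqs[te])
    }
    m <- compute_metrics(y[te], pred$labels)
    accs[trial] <- m$accuracy
    aucs[trial] <- if (length(unique(y[te])) == 2) {
      roc_auc(pred$scores, y[te])$auc
    } else NA_real_
    pooled_scores <- c(pooled_scores, pred$scores)
    pooled_labels <- c(pooled_labels, y[te])
    last <- m
  }
  pooled <- roc_auc(pooled_scores, pooled_labels)
  structure(list(
    model = model,
    per_trial_accuracy = accs,
    mean_accuracy = mean(accs),
    sd_accuracy = stats::sd(accs),
    per_trial_auc = aucs,
    per_class = last$per_class,
    confusion = last$confusion,
    roc = pooled$roc,
    auc = pooled$auc,
    n_trials = spec$n_trials
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s, %d trials\n", x$model, x$n_trials))
  cat(sprintf("  accuracy: %.2f%% +/- %.2f%%\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy))
  cat(sprintf("  pooled AUC: %.3f\n", x$auc))
  pc <- x$per_class
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-10s P=%s R=%s F1=%s\n", pc$class[i],
                fmt_pct(pc$precision[i]), fmt_pct(pc$recall[i]),
                fmt_pct(pc$f1[i])))
  }
  cat("  confusion (last trial, rows true / cols predicted):\n")
  print(x$confusion)
  invisible(x)
}

fmt_pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
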