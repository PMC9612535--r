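test_that("patient splits honor per-class counts and reproducibility", {
  ids <- c(sprintf("B%02d", 1:91), sprintf("P%02d", 1:82))
  labs <- c(rep(-1, 91), rep(1, 82))
  spec <- split_spec(seed = 4)
  sp <- split_patients(ids, labs, spec, trial = 1)
  expect_length(sp$test, 32)
  expect_length(sp$train, 141)
  expect_equal(sum(sp$test %in% ids[labs == -1]), 17)
  expect_equal(sum(sp$test %in% ids[labs == 1]), 15)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_patients(ids, labs, spec, 1), sp)
  expect_false(identical(split_patients(ids, labs, spec, 2)$test, sp$test))
  expect_error(split_patients(ids[1:20], labs[1:20], spec), "exceed")
})

test_that("metrics match hand counts and flag undefined cases", {
  y_true <- c(-1, -1, 1, 1)
  m <- compute_metrics(y_true, c(-1, 1, 1, 1))
  expect_equal(m$accuracy, 0.75)
  expect_equal(sum(m$confusion), 4)
  expect_equal(m$accuracy, sum(diag(m$confusion)) / sum(m$confusion))
  pc <- m$per_class
  expect_equal(pc$precision[pc$class == "pneumonia"], 2 / 3)
  expect_equal(pc$recall[pc$class == "pneumonia"], 1)
  # all-positive predictor on balanced labels
  m2 <- compute_metrics(y_true, rep(1, 4))
  pc2 <- m2$per_class
  expect_equal(pc2$recall[pc2$class == "pneumonia"], 1)
  expect_equal(pc2$precision[pc2$class == "pneumonia"], 0.5)
  expect_true(is.na(pc2$precision[pc2$class == "bronchitis"]))  # never predicted
  expect_error(compute_metrics(numeric(0), numeric(0)), "empty")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(round(f1_score(87.5, 93.33), 2), 90.32)
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
})

test_that("the ROC sweep equals the Mann-Whitney AUC, including ties", {
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:100, 1)
    y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)   # coarse grid forces ties
    r <- roc_auc(scores, y)
    expect_equal(r$auc, mann_whitney_auc(scores, y), tolerance = 1e-12)
    expect_true(all(r$roc$fpr >= 0 & r$roc$fpr <= 1))
  }
  expect_equal(roc_auc(c(1, 2, 3, 4), c(-1, -1, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(-1, -1, 1, 1))$auc, 0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("the ROC sweep agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- sample(c(-1, 1), 60, replace = TRUE)
  y[1:2] <- c(-1, 1)
  s <- rnorm(60) + 0.8 * y
  ours <- roc_auc(s, y)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c(-1, 1),
                                           direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("random balanced scores give AUC near one half", {
  set.seed(2)
  y <- rep(c(-1, 1), 1000)
  expect_lt(abs(roc_auc(rnorm(2000), y)$auc - 0.5), 0.03)
})

test_that("repeated_eval aggregates per-trial metrics consistently", {
  set.seed(19)
  n <- 40
  X <- matrix(rnorm(n * 20), n, 20)
  y <- rep(c(-1, 1), each = n / 2)
  X[y == 1, 1] <- X[y == 1, 1] + 6      # separable on feature 1
  ft <- data.frame(patient_id = sprintf("p%02d", 1:n), label = y)
  ft[paste0("f", 1:20)] <- X
  spec <- split_spec(n_trials = 5, test_bronchitis = 4, test_pneumonia = 4,
                     seed = 6)
  rep_ <- repeated_eval(ft, "svm", spec, svm_config("linear", C = 1))
  expect_length(rep_$per_trial_accuracy, 5)
  expect_equal(rep_$mean_accuracy, mean(rep_$per_trial_accuracy))
  expect_equal(rep_$sd_accuracy, sd(rep_$per_trial_accuracy))
  expect_equal(sum(rep_$confusion), 8)
  expect_gte(rep_$auc, 0.95)            # separable by construction
  one <- repeated_eval(ft, "svm", split_spec(1, 4, 4, seed = 6),
                       svm_config("linear", C = 1))
  expect_equal(one$mean_accuracy, one$per_trial_accuracy[1])
})
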