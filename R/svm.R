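#' SVM configuration
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Soft-margin regularization parameter (> 0). Larger values
#'   penalize slack (misclassification) more heavily.
#' @param gamma RBF kernel width `exp(-gamma * ||x - x'||^2)`; ignored
#'   for the linear kernel. The defaults (`C = 1e4`, `gamma = 1e-6`)
#'   are the reference operating point for standardized 20-dimensional
#'   cough features.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(kernel = c("rbf", "linear"), C = 1e4, gamma = 1e-6) {
  kernel <- match.arg(kernel)
  stopifnot(C > 0, gamma > 0)
  structure(list(kernel = kernel, C = C, gamma = gamma),
            class = "svm_config")
}

#' Train the soft-margin SVM classifier
#'
#' Solves `min 1/2 ||w||^2 + C * sum(xi)` subject to
#' `y_i (w . x_i + b) >= 1 - xi_i`, `xi_i >= 0` (in the dual, via
#' libsvm). Labels are -1 (bronchitis) and +1 (pneumonia). Features are
#' standardized (zero mean, unit variance, fit on the training data) by
#' default.
#'
#' @param x Numeric matrix (n x d) of features.
#' @param y Numeric labels in \{-1, +1\}, both classes present.
#' @param cfg An [svm_config()].
#' @param standardize Standardize columns before fitting?
#' @param tolerance libsvm termination tolerance.
#' @return An object of class `cough_svm`.
#' @export
train_svm <- function(x, y, cfg = svm_config(), standardize = TRUE,
                      tolerance = 1e-6) {
  x <- as.matrix(x)
  stopifnot(length(y) == nrow(x), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("both classes required to train the SVM")
  center <- rep(0, ncol(x)); scale_ <- rep(1, ncol(x))
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  }
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")
  fit <- e1071::svm(xs, factor(y, levels = c(-1, 1)),
                    type = "C-classification",
                    kernel = if (cfg$kernel == "rbf") "radial" else "linear",
                    cost = cfg$C, gamma = cfg$gamma, scale = FALSE,
                    tolerance = tolerance)
  # orient decision values so positive score <=> class +1
  dv <- attr(stats::predict(fit, xs[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  flip <- if (startsWith(colnames(dv)[1], "-1")) -1 else 1
  structure(list(fit = fit, cfg = cfg, center = center, scale = scale_,
                 flip = flip, n_features = ncol(x)),
            class = "cough_svm")
}

#' @export
print.cough_svm <- function(x, ...) {
  cat(sprintf("<cough_svm> kernel=%s C=%g%s, %d support vectors, %d features\n",
              x$cfg$kernel, x$cfg$C,
              if (x$cfg$kernel == "rbf") sprintf(" gamma=%g", x$cfg$gamma) else "",
              nrow(x$fit$SV), x$n_features))
  invisible(x)
}

#' Predict with a trained SVM
#'
#' @param model A `cough_svm`.
#' @param x Feature matrix (n x d).
#' @return A list with `labels` (-1/+1; a score of exactly 0 is broken
#'   to +1) and `scores` (signed margins `w . x + b`, usable for ROC).
#' @export
predict_svm <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) stop("feature dimension mismatch")
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  dv <- attr(stats::predict(model$fit, xs, decision.values = TRUE),
             "decision.values")
  scores <- model$flip * as.numeric(dv)
  list(labels = ifelse(scores >= 0, 1, -1), scores = scores)
}

#' @export
predict.cough_svm <- function(object, newdata, ...) predict_svm(object, newdata)

#' Primal objective value of a trained SVM
#'
#' Evaluates `1/2 ||w||^2 + C * sum(max(0, 1 - y_i f(x_i)))` in the
#' (standardized) feature space the model was fit in. For the RBF
#' kernel, `||w||^2` is the quadratic form of the dual coefficients
#' with the kernel Gram matrix.
#'
#' @param model A `cough_svm`.
#' @param x,y The training features and labels.
#' @return The primal objective value.
#' @export
svm_primal_objective <- function(model, x, y) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  sv <- model$fit$SV
  coefs <- as.numeric(model$fit$coefs)  # alpha_i * y_i, signed
  K <- if (model$cfg$kernel == "linear") {
    sv %*% t(sv)
  } else {
    d2 <- outer(rowSums(sv^2), rowSums(sv^2), "+") - 2 * sv %*% t(sv)
    exp(-model$cfg$gamma * pmax(d2, 0))
  }
  wnorm2 <- as.numeric(t(coefs) %*% K %*% coefs)
  f <- predict_svm(model, x)$scores
  slack <- pmax(0, 1 - y * f)
  0.5 * wnorm2 + model$cfg$C * sum(slack)
}

#' Total slack of a trained SVM on a dataset
#'
#' @inheritParams svm_primal_objective
#' @return `sum(max(0, 1 - y_i f(x_i)))`.
#' @export
svm_total_slack <- function(model, x, y) {
  sum(pmax(0, 1 - y * predict_svm(model, x)$scores))
}
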