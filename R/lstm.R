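#' Sequence model configuration
#'
#' A single-layer LSTM (32 hidden units) followed by a fully-connected
#' layer and a softmax over the two classes, trained with Adam on the
#' cross-entropy loss.
#'
#' @param hidden_units LSTM hidden state size.
#' @param learning_rate Adam step size.
#' @param batch_size Mini-batch size.
#' @param time_step Sequence length (number of LSTM cell unrollings).
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience: training stops when the
#'   epoch loss has not improved for this many epochs.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return A list of class `sequence_model_config`.
#' @export
sequence_model_config <- function(hidden_units = 32, learning_rate = 0.001,
                                  batch_size = 32, time_step = 50,
                                  epochs = 100, patience = 10, seed = 1L) {
  stopifnot(hidden_units > 0, learning_rate > 0, batch_size > 0,
            time_step > 0, epochs > 0)
  structure(list(hidden_units = hidden_units, learning_rate = learning_rate,
                 batch_size = batch_size, time_step = time_step,
                 epochs = epochs, patience = patience, seed = as.integer(seed)),
            class = "sequence_model_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass over a batch. X: B x T x d array. Returns final hidden
# state, class probabilities, and (optionally) the caches BPTT needs.
lstm_forward <- function(params, X, keep_cache = FALSE) {
  B <- dim(X)[1]; T_ <- dim(X)[2]
  H <- nrow(params$Wg)
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  cache <- if (keep_cache) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    xt <- X[, t, , drop = FALSE]
    dim(xt) <- c(B, dim(X)[3])
    Z <- xt %*% params$Wx + h %*% params$Wg + matrix(params$b, B, 4 * H, byrow = TRUE)
    i <- sigmoid(Z[, 1:H, drop = FALSE])
    f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, cc = cc, tc = tc, h_prev = h_prev)
    }
  }
  logits <- h %*% params$Why + matrix(params$by, B, 2, byrow = TRUE)
  probs <- softmax_rows(logits)
  list(h = h, probs = probs, cache = cache)
}

# Backward pass: mean cross-entropy gradient through the FC layer and
# the full unrolled LSTM.
lstm_backward <- function(params, X, Y, fwd) {
  B <- dim(X)[1]; T_ <- dim(X)[2]; H <- ncol(params$Wg) / 4
  dlogits <- (fwd$probs - Y) / B
  grads <- list(
    Why = t(fwd$h) %*% dlogits,
    by = colSums(dlogits),
    Wx = params$Wx * 0, Wg = params$Wg * 0, b = params$b * 0
  )
  dh <- dlogits %*% t(params$Why)
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    cch <- fwd$cache[[t]]
    do_ <- dh * cch$tc
    dc <- dc + dh * cch$o * (1 - cch$tc^2)
    di <- dc * cch$g
    df <- dc * cch$c_prev
    dg <- dc * cch$i
    dc_prev <- dc * cch$f
    dZ <- cbind(di * cch$i * (1 - cch$i),
                df * cch$f * (1 - cch$f),
                dg * (1 - cch$g^2),
                do_ * cch$o * (1 - cch$o))
    grads$Wx <- grads$Wx + t(cch$xt) %*% dZ
    grads$Wg <- grads$Wg + t(cch$h_prev) %*% dZ
    grads$b <- grads$b + colSums(dZ)
    dh <- dZ %*% t(params$Wg)
    dc <- dc_prev
  }
  grads
}

#' Train the LSTM sequence classifier
#'
#' @param seqs List of `time_step x d` numeric matrices (uniform
#'   dimensions), one per patient.
#' @param y Labels in \{-1, +1\} (-1 bronchitis, +1 pneumonia).
#' @param cfg A [sequence_model_config()].
#' @return An object of class `cough_lstm` with the fitted parameters
#'   and the per-epoch training loss trajectory.
#' @export
train_sequence_model <- function(seqs, y, cfg = sequence_model_config()) {
  stopifnot(length(seqs) == length(y), all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("both classes required")
  dims <- vapply(seqs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all sequences must share the same dimensions")
  }
  T_ <- dims[1, 1]; d <- dims[2, 1]; n <- length(seqs)
  H <- cfg$hidden_units
  X <- array(0, c(n, T_, d))
  for (k in seq_len(n)) X[k, , ] <- seqs[[k]]
  # one-hot targets: column 1 = bronchitis (-1), column 2 = pneumonia (+1)
  Y <- cbind(as.numeric(y == -1), as.numeric(y == 1))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  sc <- 0.08
  params <- list(
    Wx = matrix(stats::runif(d * 4 * H, -sc, sc), d, 4 * H),
    Wg = matrix(stats::runif(H * 4 * H, -sc, sc), H, 4 * H),
    b = c(rep(0, H), rep(1, H), rep(0, 2 * H)),  # forget-gate bias 1
    Why = matrix(stats::runif(H * 2, -sc, sc), H, 2),
    by = c(0, 0)
  )
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_history <- numeric(0)
  best <- Inf; stale <- 0L

  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
    for (bi in batches) {
      Xb <- X[bi, , , drop = FALSE]
      Yb <- Y[bi, , drop = FALSE]
      fwd <- lstm_forward(params, Xb, keep_cache = TRUE)
      grads <- lstm_backward(params, Xb, Yb, fwd)
      step <- step + 1L
      for (nm in names(params)) {
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * grads[[nm]]
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mh <- adam_m[[nm]] / (1 - beta1^step)
        vh <- adam_v[[nm]] / (1 - beta2^step)
        params[[nm]] <- params[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + eps)
      }
    }
    probs <- lstm_forward(params, X)$probs
    loss <- -mean(log(pmax(rowSums(probs * Y), 1e-12)))
    loss_history <- c(loss_history, loss)
    if (loss < best - 1e-5) { best <- loss; stale <- 0L } else stale <- stale + 1L
    if (stale >= cfg$patience) break
  }
  structure(list(params = params, cfg = cfg, loss_history = loss_history,
                 time_step = T_, n_features = d),
            class = "cough_lstm")
}

#' @export
print.cough_lstm <- function(x, ...) {
  cat(sprintf("<cough_lstm> %d hidden units, time step %d, %d epochs, final loss %.4f\n",
              x$cfg$hidden_units, x$time_step, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Predict with a trained LSTM
#'
#' @param model A `cough_lstm`.
#' @param seqs List of `time_step x d` matrices.
#' @return A list with `labels` (-1/+1; an exact 0.5/0.5 tie goes to
#'   bronchitis, -1), `probs` (n x 2: bronchitis, pneumonia confidence)
#'   and `scores` (pneumonia probability, usable for ROC).
#' @export
predict_sequence <- function(model, seqs) {
  dims <- vapply(seqs, dim, integer(2))
  if (any(dims[1, ] != model$time_step) || any(dims[2, ] != model$n_features)) {
    stop("sequence dimensions do not match the trained model")
  }
  n <- length(seqs)
  X <- array(0, c(n, model$time_step, model$n_features))
  for (k in seq_len(n)) X[k, , ] <- seqs[[k]]
  probs <- lstm_forward(model$params, X)$probs
  colnames(probs) <- c("bronchitis", "pneumonia")
  list(labels = ifelse(probs[, 2] > probs[, 1], 1, -1),
       probs = probs, scores = probs[, 2])
}

#' @export
predict.cough_lstm <- function(object, newdata, ...) predict_sequence(object, newdata)
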