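make_toy_seqs <- function(n_per_class = 4, time_step = 50, d = 4, noise = 0.1,
                          seed = 5) {
  set.seed(seed)
  mk <- function(s) {
    matrix(s * seq(-1, 1, length.out = time_step), time_step, d) +
      matrix(rnorm(time_step * d, 0, noise), time_step, d)
  }
  list(seqs = c(replicate(n_per_class, mk(1), simplify = FALSE),
                replicate(n_per_class, mk(-1), simplify = FALSE)),
       y = rep(c(1, -1), each = n_per_class))
}

test_that("output probabilities are a softmax over two classes", {
  toy <- make_toy_seqs()
  m <- train_sequence_model(toy$seqs, toy$y,
                            sequence_model_config(hidden_units = 8, epochs = 3,
                                                  batch_size = 8))
  p <- predict_sequence(m, toy$seqs)
  expect_true(all(p$probs >= 0 & p$probs <= 1))
  expect_equal(rowSums(p$probs), rep(1, 8), tolerance = 1e-6)
  expect_true(all(p$labels %in% c(-1, 1)))
})

test_that("a separable toy set is fit perfectly within 200 epochs", {
  toy <- make_toy_seqs()
  cfg <- sequence_model_config(hidden_units = 16, epochs = 200,
                               patience = 200, batch_size = 8, seed = 2)
  m <- train_sequence_model(toy$seqs, toy$y, cfg)
  expect_equal(mean(predict_sequence(m, toy$seqs)$labels == toy$y), 1)
})

test_that("training is reproducible from the seed and mostly monotone", {
  toy <- make_toy_seqs()
  cfg <- sequence_model_config(hidden_units = 16, epochs = 80,
                               patience = 80, batch_size = 8, seed = 2)
  m1 <- train_sequence_model(toy$seqs, toy$y, cfg)
  m2 <- train_sequence_model(toy$seqs, toy$y, cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  d <- diff(m1$loss_history)
  expect_gte(mean(d <= 1e-9), 0.95)
})

test_that("analytic gradients match finite differences", {
  set.seed(13)
  T_ <- 5; d <- 3; H <- 4; B <- 2
  X <- array(rnorm(B * T_ * d), c(B, T_, d))
  Y <- rbind(c(1, 0), c(0, 1))
  sc <- 0.3
  params <- list(Wx = matrix(rnorm(d * 4 * H, 0, sc), d, 4 * H),
                 Wg = matrix(rnorm(H * 4 * H, 0, sc), H, 4 * H),
                 b = rnorm(4 * H, 0, sc),
                 Why = matrix(rnorm(H * 2, 0, sc), H, 2),
                 by = rnorm(2, 0, sc))
  loss_fn <- function(p) {
    pr <- coughclass:::lstm_forward(p, X)$probs
    -mean(log(pmax(rowSums(pr * Y), 1e-12)))
  }
  fwd <- coughclass:::lstm_forward(params, X, keep_cache = TRUE)
  grads <- coughclass:::lstm_backward(params, X, Y, fwd)
  eps <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(5, length(params[[nm]])))
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("sequence inputs are validated", {
  toy <- make_toy_seqs()
  expect_error(train_sequence_model(toy$seqs, rep(1, 8)), "both classes")
  bad <- toy$seqs; bad[[1]] <- bad[[1]][1:10, ]
  expect_error(train_sequence_model(bad, toy$y), "same dimensions")
  m <- train_sequence_model(toy$seqs, toy$y,
                            sequence_model_config(hidden_units = 4,
                                                  epochs = 2, batch_size = 8))
  expect_error(predict_sequence(m, list(matrix(0, 10, 4))), "dimensions")
})
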