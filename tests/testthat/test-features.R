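test_that("the feature matrix is T x 20 with the expected frame count", {
  ch <- make_noise_chunk(dur = 1, sr = 16000)
  m <- compute_mfcc(ch)
  expect_equal(ncol(m), 20)
  expect_equal(nrow(m), floor((1000 - 25) / 10) + 1)   # 98 frames
  expect_true(all(is.finite(m)))
  expect_error(compute_mfcc(make_noise_chunk(dur = 0.01, sr = 8000)),
               "shorter")
})

test_that("the DCT drops the constant term: flat log-mel gives zero c1..c19", {
  d <- coughclass:::dct_matrix(40, 19)
  expect_equal(as.numeric(d %*% rep(3.7, 40)), rep(0, 19), tolerance = 1e-12)
})

test_that("amplitude gain moves only the log-energy column", {
  ch <- make_noise_chunk(dur = 0.5, sr = 16000, amp = 0.2)
  g <- 2
  ch2 <- ch; ch2$samples <- g * ch$samples
  m1 <- compute_mfcc(ch); m2 <- compute_mfcc(ch2)
  expect_equal(m2[, 1] - m1[, 1], rep(20 * log10(g), nrow(m1)),
               tolerance = 1e-6)
  expect_equal(m2[, -1], m1[, -1], tolerance = 1e-6)
})

test_that("mfcc extraction is deterministic", {
  ch <- make_noise_chunk(dur = 0.3, sr = 16000)
  expect_identical(compute_mfcc(ch), compute_mfcc(ch))
})

test_that("chunk_feature is the frame mean", {
  m <- rbind(c(1, rep(0, 19)), c(3, rep(2, 19)))
  expect_equal(chunk_feature(m), c(2, rep(1, 19)))
  expect_equal(chunk_feature(m[1, , drop = FALSE]), m[1, ])
  expect_equal(chunk_feature(m[2:1, , drop = FALSE]), chunk_feature(m))
  expect_error(chunk_feature(m[0, , drop = FALSE]), "empty")
})

test_that("aggregate_patient averages componentwise and guards patients", {
  v0 <- rep(0, 20); v2 <- rep(2, 20)
  expect_equal(aggregate_patient(list(v0, v2)), rep(1, 20))
  expect_equal(aggregate_patient(list(v2)), v2)
  expect_equal(aggregate_patient(list(v2, v2, v2)), v2)
  expect_error(aggregate_patient(list()), "no chunk")
  expect_error(aggregate_patient(list(v0, v2), patient_ids = c("a", "b")),
               "different patients")
})

test_that("the aggregate lies in the componentwise convex hull", {
  set.seed(31)
  for (rep in 1:10) {
    feats <- lapply(1:sample(2:6, 1), function(i) rnorm(20))
    agg <- aggregate_patient(feats)
    lo <- do.call(pmin, feats); hi <- do.call(pmax, feats)
    expect_true(all(agg >= lo - 1e-12 & agg <= hi + 1e-12))
  }
})

test_that("patient_sequence truncates, pads, and preserves order", {
  m1 <- matrix(1, 30, 20); m2 <- matrix(2, 90, 20)
  s <- patient_sequence(list(m1, m2), time_step = 50)
  expect_equal(dim(s), c(50, 20))
  expect_equal(s[1:30, 1], rep(1, 30))
  expect_equal(s[31:50, 1], rep(2, 20))
  s_rev <- patient_sequence(list(m2, m1), time_step = 50)
  expect_false(identical(s, s_rev))
  short <- patient_sequence(list(m1), time_step = 50)
  expect_equal(short[31:50, ], matrix(0, 20, 20))
})

test_that("patient_features aggregates chunks by patient", {
  chunks <- c(
    lapply(1:2, function(i) make_noise_chunk(0.3, 16000, "pA", -1, seed = i)),
    lapply(3:4, function(i) make_noise_chunk(0.3, 16000, "pB", 1, seed = i))
  )
  ft <- patient_features(chunks, sequences = TRUE, time_step = 20)
  expect_equal(nrow(ft), 2)
  expect_equal(sort(ft$patient_id), c("pA", "pB"))
  expect_equal(ft$label[ft$patient_id == "pA"], -1)
  expect_length(grep("^f[0-9]+$", names(ft)), 20)
  # the table row equals the mean of the chunk features
  mA <- aggregate_patient(lapply(chunks[1:2],
                                 function(c) chunk_feature(compute_mfcc(c))))
  expect_equal(as.numeric(ft[ft$patient_id == "pA", paste0("f", 1:20)]), mA,
               tolerance = 1e-12)
  seqs <- attr(ft, "sequences")
  expect_equal(dim(seqs[[1]]), c(20, 20))
})
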