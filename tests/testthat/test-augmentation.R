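test_that("time_shift preserves duration and fills with the given tone", {
  ch <- make_noise_chunk(dur = 1, sr = 8000)
  same <- time_shift(ch, 0, "begin")
  expect_identical(same$samples, ch$samples)
  sh <- time_shift(ch, 0.05, "begin", fill_freq_hz = 440)
  expect_length(sh$samples, length(ch$samples))
  expect_equal(sh$provenance, "time_shift")
  fill <- sh$samples[1:400]
  expect_equal(dominant_freq(fill, 8000), 440, tolerance = 0.05)
  # deleted at the start: remaining head equals the original head shifted
  expect_identical(sh$samples[401:8000], ch$samples[1:7600])
  expect_error(time_shift(ch, 0.2, "begin"), "0.1")
  expect_error(time_shift(make_noise_chunk(dur = 0.05), 0.08), "duration")
})

test_that("pitch_shift scales frequency by 2^(semitones/12)", {
  ch <- make_tone_chunk(440, dur = 1, sr = 16000)
  for (s in c(2, 5)) {
    out <- pitch_shift(ch, s)
    expect_equal(length(out$samples), length(ch$samples))  # duration kept
    expect_equal(dominant_freq(out$samples, 16000), 440 * 2^(s / 12),
                 tolerance = 0.02)
    expect_equal(out$provenance, "pitch_shift")
  }
  expect_error(pitch_shift(ch, 6), "5")
  expect_error(pitch_shift(ch, 0), "5")
})

test_that("small pitch shifts stay close to the input", {
  ch <- make_tone_chunk(440, dur = 0.5, sr = 16000)
  out <- pitch_shift(ch, 0.01)
  expect_equal(dominant_freq(out$samples, 16000),
               dominant_freq(ch$samples, 16000), tolerance = 0.01)
})

test_that("add_noise hits the requested SNR within 0.5 dB", {
  ch <- make_noise_chunk(dur = 0.5, sr = 8000, seed = 3)
  set.seed(4)
  for (snr in c(0, 10, 20)) {
    for (col in c("white", "pink")) {
      out <- add_noise(ch, col, snr)
      measured <- 10 * log10(mean(ch$samples^2) /
                             mean((out$samples - ch$samples)^2))
      expect_equal(measured, snr, tolerance = 0.5)
      expect_equal(out$provenance, paste0("noise_", col))
    }
  }
  # vanishing-noise limit
  out <- add_noise(ch, "white", 100)
  expect_lt(sqrt(mean((out$samples - ch$samples)^2)), 1e-4)
  expect_error(add_noise(cough_chunk(rep(0, 100), 8000), "white", 10),
               "silent")
})

test_that("pink noise has a ~ -10 dB/decade PSD slope", {
  set.seed(5)
  sr <- 44100
  x <- gen_noise(2^17, "pink")
  p <- Mod(stats::fft(x))[2:(2^16)]^2
  f <- (1:(2^16 - 1)) * sr / 2^17
  sel <- f >= 100 & f <= 8000
  # average log-power in log-spaced bands, regress on log-frequency
  bands <- cut(log10(f[sel]), 20)
  pw <- tapply(p[sel], bands, mean)
  fq <- tapply(f[sel], bands, mean)
  slope <- coef(lm(10 * log10(pw) ~ log10(fq)))[2]
  expect_equal(unname(slope), -10, tolerance = 1.5)
})

test_that("build_dataset obeys the count law and keeps provenance", {
  chunks <- lapply(1:5, function(i) {
    make_noise_chunk(dur = 0.3, sr = 8000, patient_id = paste0("p", i %% 2),
                     seed = i)
  })
  counts <- c(RAW = 5, AR = 10, BR = 10, CR = 10, DR = 15, ER = 20)
  for (nm in names(counts)) {
    out <- build_dataset(chunks, augmentation_spec(nm, seed = 2))
    expect_length(out, counts[[nm]])
    # augmented copies keep their source patient
    expect_equal(vapply(out, function(c) c$patient_id, character(1)),
                 rep(vapply(chunks, function(c) c$patient_id, character(1)),
                     counts[[nm]] / 5))
  }
  raw_out <- build_dataset(chunks[1], augmentation_spec("RAW"))
  expect_identical(raw_out[[1]]$samples, chunks[[1]]$samples)
})

test_that("a fixed seed reproduces the augmented corpus bit-for-bit", {
  chunks <- lapply(1:3, function(i) make_noise_chunk(dur = 0.3, seed = i))
  a <- build_dataset(chunks, augmentation_spec("ER", seed = 42))
  b <- build_dataset(chunks, augmentation_spec("ER", seed = 42))
  expect_identical(lapply(a, `[[`, "samples"), lapply(b, `[[`, "samples"))
  c2 <- build_dataset(chunks, augmentation_spec("ER", seed = 43))
  expect_false(identical(lapply(a, `[[`, "samples"),
                         lapply(c2, `[[`, "samples")))
})
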