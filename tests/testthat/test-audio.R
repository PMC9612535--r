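test_that("write_wav / read_wav round-trips 16-bit samples exactly", {
  set.seed(42)
  x <- round(runif(5000, -0.8, 0.8) * 32768) / 32768
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(x, 44100), f)
  r <- read_wav(f)
  expect_equal(r$sample_rate, 44100)
  expect_identical(r$samples, x)
})

test_that("16-bit integer samples scale by 1/32768", {
  # hand-built minimal mono WAV holding the single sample 32767
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(38L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")
  writeBin(c(8000L, 16000L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(2L, con, size = 4, endian = "little")
  writeBin(32767L, con, size = 2, endian = "little")
  close(con)
  r <- read_wav(f)
  expect_equal(r$samples, 32767 / 32768)
})

test_that("stereo input is downmixed by channel averaging", {
  f <- withr::local_tempfile(fileext = ".wav")
  l <- round(0.2 * 32768); rr <- round(0.4 * 32768)
  con <- file(f, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + 8L, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(c(8000L, 32000L), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(8L, con, size = 4, endian = "little")
  writeBin(as.integer(c(l, rr, l, rr)), con, size = 2, endian = "little")
  close(con)
  r <- read_wav(f)
  expect_length(r$samples, 2)
  expect_equal(r$samples, rep((l + rr) / 2 / 32768, 2), tolerance = 1e-9)
})

test_that("read_wav rejects non-WAV and missing files", {
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio at all, just text padding to some length", f)
  expect_error(read_wav(f), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
})

test_that("resample_audio preserves duration and spectral content", {
  s <- make_tone(1000, dur = 1, sr = 22050)
  same <- resample_audio(s, 22050)
  expect_identical(same$samples, s$samples)
  up <- resample_audio(s, 44100)
  expect_equal(up$sample_rate, 44100)
  expect_length(up$samples, 44100)
  expect_equal(dominant_freq(up$samples, 44100), 1000, tolerance = 0.01)
})

test_that("peak_normalize hits the target level and is idempotent", {
  s <- make_tone(440, dur = 0.25, amp = 0.5)
  n1 <- peak_normalize(s)
  expect_equal(max(abs(n1$samples)), 10^(-0.1 / 20), tolerance = 1e-6)
  n2 <- peak_normalize(n1)
  expect_equal(n2$samples, n1$samples, tolerance = 1e-6)
  # shape unchanged: pure scaling
  expect_equal(cor(n1$samples, s$samples), 1, tolerance = 1e-12)
})

test_that("peak_normalize leaves silence untouched with a warning", {
  z <- audio_signal(rep(0, 100), 8000)
  expect_warning(out <- peak_normalize(z), "all-zero")
  expect_identical(out$samples, z$samples)
})
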