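#' Construct an audio signal
#'
#' The basic carrier of all DSP stages: a mono sample sequence in
#' \[-1, 1\] together with its sample rate, optionally tagged with the
#' source patient and a disease label (-1 = bronchitis, +1 = pneumonia).
#'
#' @param samples Numeric vector of amplitudes, nominally in \[-1, 1\].
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param patient_id Optional patient identifier (character scalar).
#' @param label Optional class label, -1 (bronchitis) or +1 (pneumonia).
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate, patient_id = NULL, label = NULL) {
  stopifnot(is.numeric(samples), length(sample_rate) == 1L, sample_rate > 0)
  if (!is.null(label) && !label %in% c(-1, 1)) {
    stop("label must be -1 (bronchitis) or +1 (pneumonia)")
  }
  structure(
    list(
      samples = as.numeric(samples),
      sample_rate = as.numeric(sample_rate),
      patient_id = patient_id,
      label = label
    ),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal> %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$sample_rate, duration(x),
    if (!is.null(x$patient_id)) paste0(" patient=", x$patient_id) else ""
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal` or `cough_chunk`.
#' @return Duration in seconds.
#' @export
duration <- function(x) length(x$samples) / x$sample_rate

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE container and returns the samples scaled to
#' \[-1, 1\]. 16-bit PCM is the primary format; 8-bit and 32-bit integer
#' PCM and 32/64-bit IEEE float are tolerated. Multi-channel audio is
#' downmixed to mono by averaging the channels.
#'
#' @param path Path to a WAV file.
#' @param patient_id,label Optional metadata attached to the result.
#' @return An `audio_signal`.
#' @export
read_wav <- function(path, patient_id = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0L) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing fmt/data chunk): ", path)

  bits <- fmt$bits
  x <- if (fmt$audio_format == 1L) {
    if (bits == 16L) {
      readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
              endian = "little") / 32768
    } else if (bits == 32L) {
      readBin(data_raw, "integer", length(data_raw) / 4L, size = 4,
              endian = "little") / 2147483648
    } else if (bits == 8L) {
      (readBin(data_raw, "integer", length(data_raw), size = 1,
               endian = "little", signed = FALSE) - 128) / 128
    } else stop("unsupported PCM bit depth: ", bits)
  } else if (fmt$audio_format == 3L) {
    readBin(data_raw, "double", length(data_raw) / (bits / 8L),
            size = bits / 8L, endian = "little")
  } else stop("unsupported WAV audio format code: ", fmt$audio_format)

  if (length(x) == 0L) stop("empty audio in ", path)
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_signal(x, fmt$sample_rate, patient_id = patient_id, label = label)
}

#' Write an audio signal as 16-bit PCM WAV
#'
#' @param signal An `audio_signal` (or `cough_chunk`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path) {
  x <- signal$samples
  q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(signal$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(signal$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample an audio signal
#'
#' Polyphase resampling to a new rate. Integer rates are reduced to a
#' rational ratio; the duration is preserved to within one sample period.
#'
#' @param signal An `audio_signal`.
#' @param target_rate Target sampling frequency in Hz.
#' @return An `audio_signal` at `target_rate`.
#' @export
resample_audio <- function(signal, target_rate) {
  stopifnot(target_rate > 0)
  if (signal$sample_rate == target_rate) return(signal)
  g <- gcd_int(round(target_rate), round(signal$sample_rate))
  p <- round(target_rate) / g
  q <- round(signal$sample_rate) / g
  y <- signal::resample(signal$samples, p, q)
  n_out <- round(length(signal$samples) * target_rate / signal$sample_rate)
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(0, n_out - length(y)))
  audio_signal(pmax(-1, pmin(1, y)), target_rate,
               patient_id = signal$patient_id, label = signal$label)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Peak-normalize an audio signal
#'
#' Scales the waveform so its peak absolute amplitude sits at
#' `target_db` dBFS (0 dBFS = amplitude 1.0). The default of -0.1 dBFS
#' leaves a small headroom below digital full scale. An all-zero signal
#' is returned unchanged with a warning.
#'
#' @param signal An `audio_signal` or `cough_chunk`.
#' @param target_db Target peak level in dBFS (default -0.1).
#' @return The rescaled signal.
#' @export
peak_normalize <- function(signal, target_db = -0.1) {
  peak <- max(abs(signal$samples))
  if (peak == 0) {
    warning("all-zero signal: peak normalization skipped")
    return(signal)
  }
  signal$samples <- signal$samples * (10^(target_db / 20) / peak)
  signal
}
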