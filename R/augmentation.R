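#' Augmentation specification
#'
#' Describes one of the six dataset variants and the parameter ranges
#' the augmentation operators draw from. `RAW` is the untouched chunk
#' set; `AR`/`BR`/`CR` add exactly one time-shifted / pitch-shifted /
#' noise-mixed copy per raw chunk; `DR` combines the pitch and noise
#' copies; `ER` combines all three.
#'
#' @param dataset_name One of `"RAW"`, `"AR"`, `"BR"`, `"CR"`, `"DR"`,
#'   `"ER"`.
#' @param time_shift_max_s Maximum deleted span for time shifting (s).
#' @param pitch_shift_max_semitones Maximum upward pitch shift.
#' @param noise_colors Noise colors to draw from.
#' @param snr_db_range Interval the mixing SNR is drawn from (dB).
#' @param fill_freq_hz Tone frequency used to fill the deleted span.
#' @param seed Integer seed making the built corpus reproducible.
#' @return A list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(dataset_name = c("RAW", "AR", "BR", "CR", "DR", "ER"),
                              time_shift_max_s = 0.1,
                              pitch_shift_max_semitones = 5,
                              noise_colors = c("white", "pink"),
                              snr_db_range = c(10, 20),
                              fill_freq_hz = 440,
                              seed = 1L) {
  dataset_name <- match.arg(dataset_name)
  stopifnot(time_shift_max_s > 0, pitch_shift_max_semitones > 0,
            length(snr_db_range) == 2, diff(snr_db_range) >= 0)
  structure(list(dataset_name = dataset_name,
                 time_shift_max_s = time_shift_max_s,
                 pitch_shift_max_semitones = pitch_shift_max_semitones,
                 noise_colors = noise_colors,
                 snr_db_range = snr_db_range,
                 fill_freq_hz = fill_freq_hz,
                 seed = as.integer(seed)),
            class = "augmentation_spec")
}

#' Time-shift a cough chunk
#'
#' Deletes `amount_s` seconds from the beginning or end of the chunk and
#' fills the gap with a fixed-frequency tone so the duration is
#' unchanged. The fill tone's amplitude is 10% of the chunk RMS.
#'
#' @param chunk A `cough_chunk`.
#' @param amount_s Deleted span in seconds, in \[0, `max_s`\] and less
#'   than the chunk duration.
#' @param side `"begin"` or `"end"`.
#' @param fill_freq_hz Fill tone frequency (Hz).
#' @param max_s Upper limit on `amount_s` (default 0.1 s).
#' @return A `cough_chunk` with provenance `"time_shift"`.
#' @export
time_shift <- function(chunk, amount_s, side = c("begin", "end"),
                       fill_freq_hz = 440, max_s = 0.1) {
  side <- match.arg(side)
  if (amount_s < 0 || amount_s > max_s) {
    stop("amount_s must lie in [0, ", max_s, "] s")
  }
  if (amount_s >= duration(chunk)) stop("amount_s must be below the chunk duration")
  out <- chunk
  n <- round(amount_s * chunk$sample_rate)
  if (n > 0) {
    amp <- 0.1 * sqrt(mean(chunk$samples^2))
    tone <- amp * sin(2 * pi * fill_freq_hz * (0:(n - 1)) / chunk$sample_rate)
    x <- chunk$samples
    if (side == "begin") {
      out$samples <- c(tone, x[seq_len(length(x) - n)])
    } else {
      out$samples <- c(x[(n + 1):length(x)], tone)
    }
  }
  out$provenance <- "time_shift"
  out
}

# --- phase vocoder internals -------------------------------------------------

stft_frames <- function(x, n_fft, hop) {
  win <- hann_periodic(n_fft)
  starts <- seq(1L, max(1L, length(x) - n_fft + 1L), by = hop)
  vapply(starts, function(s) stats::fft(x[s:(s + n_fft - 1L)] * win),
         complex(n_fft))
}

istft_frames <- function(S, hop) {
  n_fft <- nrow(S)
  win <- hann_periodic(n_fft)
  n_frames <- ncol(S)
  n_out <- (n_frames - 1L) * hop + n_fft
  y <- numeric(n_out)
  wsum <- numeric(n_out)
  for (j in seq_len(n_frames)) {
    idx <- ((j - 1L) * hop + 1L):((j - 1L) * hop + n_fft)
    y[idx] <- y[idx] + Re(stats::fft(S[, j], inverse = TRUE)) / n_fft * win
    wsum[idx] <- wsum[idx] + win^2
  }
  nz <- wsum > 1e-8
  y[nz] <- y[nz] / wsum[nz]
  y
}

# Time-stretch a short-time spectrogram by 1/rate (rate < 1 lengthens),
# interpolating magnitudes and accumulating phase by the deviation of the
# measured inter-frame phase advance from the nominal hop advance.
phase_vocoder <- function(S, rate, hop) {
  n_fft <- nrow(S)
  phi_adv <- 2 * pi * hop * (0:(n_fft - 1)) / n_fft
  t_idx <- seq(1, ncol(S), by = rate)
  out <- matrix(0 + 0i, n_fft, length(t_idx))
  phase <- Arg(S[, 1])
  for (j in seq_along(t_idx)) {
    t <- t_idx[j]
    i0 <- floor(t)
    i1 <- min(i0 + 1L, ncol(S))
    frac <- t - i0
    mag <- (1 - frac) * Mod(S[, i0]) + frac * Mod(S[, i1])
    out[, j] <- mag * exp(1i * phase)
    dphi <- Arg(S[, i1]) - Arg(S[, i0]) - phi_adv
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    phase <- phase + phi_adv + dphi
  }
  out
}

#' Pitch-shift a cough chunk upward
#'
#' Raises the pitch by `semitones` half-tones (frequency ratio
#' `2^(semitones/12)`) while preserving the duration: the chunk is
#' time-stretched with a phase vocoder and then resampled back to the
#' original length.
#'
#' @param chunk A `cough_chunk`.
#' @param semitones Upward shift in half-tones, in (0, `max_semitones`\].
#' @param max_semitones Upper limit (default 5).
#' @return A `cough_chunk` with provenance `"pitch_shift"`.
#' @export
pitch_shift <- function(chunk, semitones, max_semitones = 5) {
  if (semitones <= 0 || semitones > max_semitones) {
    stop("semitones must lie in (0, ", max_semitones, "]")
  }
  r <- 2^(semitones / 12)
  x <- chunk$samples
  n <- length(x)
  n_fft <- min(2048L, 2^floor(log2(max(n / 2, 64))))
  hop <- n_fft %/% 4L
  S <- stft_frames(x, n_fft, hop)
  if (is.null(dim(S))) S <- matrix(S, ncol = 1)
  y <- istft_frames(phase_vocoder(S, 1 / r, hop), hop)  # length ~ n * r
  # resample the stretched signal back to n samples (raising pitch by r)
  pos <- seq(1, by = r, length.out = n)
  pos <- pmin(pos, length(y))
  out <- chunk
  out$samples <- stats::approx(seq_along(y), y, xout = pos, rule = 2)$y
  out$provenance <- "pitch_shift"
  out
}

#' Generate white or pink noise
#'
#' Pink noise is shaped in the frequency domain with amplitude
#' proportional to `1/sqrt(f)`, giving a power spectral density
#' proportional to `1/f` (about -3 dB per octave). Uses the current R
#' RNG state.
#'
#' @param n Number of samples.
#' @param color `"white"` or `"pink"`.
#' @return Numeric vector of unit-variance noise.
#' @export
gen_noise <- function(n, color = c("white", "pink")) {
  color <- match.arg(color)
  w <- stats::rnorm(n)
  if (color == "white") return(w)
  m <- stats::nextn(n, 2)       # power-of-two FFT, truncated to n
  W <- stats::fft(c(w, stats::rnorm(m - n)))
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k)           # symmetric frequency index
  shape <- ifelse(f == 0, 0, 1 / sqrt(f))
  y <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

#' Mix noise into a cough chunk at a target SNR
#'
#' @param chunk A non-silent `cough_chunk`.
#' @param color `"white"` or `"pink"`.
#' @param snr_db Target signal-to-noise ratio in dB:
#'   `10*log10(P_signal / P_noise)`.
#' @return A `cough_chunk` with provenance `"noise_white"` or
#'   `"noise_pink"`.
#' @export
add_noise <- function(chunk, color = c("white", "pink"), snr_db = 15) {
  color <- match.arg(color)
  p_sig <- mean(chunk$samples^2)
  if (p_sig <= 0) stop("silent chunk: SNR undefined")
  noise <- gen_noise(length(chunk$samples), color)
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  out <- chunk
  out$samples <- chunk$samples + noise
  out$provenance <- paste0("noise_", color)
  out
}

#' Build one of the six dataset variants
#'
#' Applies the variant's augmentation operators to every raw chunk with
#' parameters drawn from the spec's ranges under its seed, and returns
#' raw plus augmented chunks. Chunk counts follow the construction law:
#' `RAW` n, `AR`/`BR`/`CR` 2n, `DR` 3n, `ER` 4n.
#'
#' @param raw_chunks Nonempty list of `cough_chunk` objects.
#' @param spec An [augmentation_spec()].
#' @return A list of `cough_chunk` objects.
#' @export
build_dataset <- function(raw_chunks, spec = augmentation_spec("RAW")) {
  stopifnot(length(raw_chunks) > 0, inherits(spec, "augmentation_spec"))
  name <- spec$dataset_name
  wants <- switch(name,
    RAW = character(0),
    AR = "time", BR = "pitch", CR = "noise",
    DR = c("pitch", "noise"),
    ER = c("time", "pitch", "noise"))
  out <- raw_chunks
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (op in wants) {
    copies <- lapply(raw_chunks, function(ch) {
      switch(op,
        time = time_shift(ch,
          amount_s = stats::runif(1, 1e-4, spec$time_shift_max_s),
          side = sample(c("begin", "end"), 1),
          fill_freq_hz = spec$fill_freq_hz,
          max_s = spec$time_shift_max_s),
        pitch = pitch_shift(ch,
          semitones = stats::runif(1, 1e-3, spec$pitch_shift_max_semitones),
          max_semitones = spec$pitch_shift_max_semitones),
        noise = add_noise(ch,
          color = sample(spec$noise_colors, 1),
          snr_db = stats::runif(1, spec$snr_db_range[1], spec$snr_db_range[2])))
    })
    out <- c(out, copies)
  }
  out
}
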