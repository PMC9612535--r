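#' Log-MMSE enhancement configuration
#'
#' Parameters of the log-spectral-amplitude MMSE noise suppressor.
#' The noise power spectrum is initialized from the leading
#' `noise_init_ms` of the recording (assumed cough/speech-free) and
#' updated slowly on frames judged to be noise-only.
#'
#' @param frame_ms Analysis window length in ms.
#' @param hop_ms Hop between windows in ms (must be <= `frame_ms`).
#' @param noise_init_ms Leading span used for the initial noise PSD, ms.
#' @param alpha_dd Decision-directed a-priori SNR smoothing, in \[0, 1\].
#' @param gain_floor Minimum spectral gain, in (0, 1].
#' @return A list of class `enhancement_config`.
#' @export
enhancement_config <- function(frame_ms = 25, hop_ms = 12.5,
                               noise_init_ms = 120, alpha_dd = 0.98,
                               gain_floor = 0.01) {
  stopifnot(hop_ms > 0, hop_ms <= frame_ms,
            alpha_dd >= 0, alpha_dd <= 1,
            gain_floor > 0, gain_floor <= 1)
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms,
                 noise_init_ms = noise_init_ms, alpha_dd = alpha_dd,
                 gain_floor = gain_floor),
            class = "enhancement_config")
}

# Periodic Hann window; sums to a constant under 50% overlap-add.
hann_periodic <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Suppress stationary noise with the log-spectral MMSE estimator
#'
#' Short-time spectral enhancement: each frame's spectral amplitudes are
#' multiplied by the gain that minimizes the mean-square error of the
#' log spectral amplitude, with the a-priori SNR tracked by the
#' decision-directed rule. The signal is re-synthesized by overlap-add,
#' so length and sample rate are unchanged.
#'
#' @param signal An `audio_signal`.
#' @param cfg An [enhancement_config()].
#' @return The enhanced `audio_signal`.
#' @export
logmmse_enhance <- function(signal, cfg = enhancement_config()) {
  sr <- signal$sample_rate
  frame <- max(2L, round(cfg$frame_ms * sr / 1000))
  hop <- max(1L, round(cfg$hop_ms * sr / 1000))
  x <- signal$samples
  if (length(x) < frame) stop("signal shorter than one analysis frame")

  win <- hann_periodic(frame)
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  n_fft <- frame
  eps <- 1e-12

  # initial noise PSD from the leading noise_init_ms
  n_init <- max(1L, sum(starts <= cfg$noise_init_ms * sr / 1000))
  noise_psd <- rep(eps, n_fft)
  for (k in seq_len(n_init)) {
    seg <- x[starts[k]:(starts[k] + frame - 1L)] * win
    noise_psd <- noise_psd + Mod(stats::fft(seg))^2 / n_init
  }
  noise_psd <- pmax(noise_psd, eps)

  y <- numeric(length(x))
  wsum <- numeric(length(x))
  prev_amp2 <- noise_psd  # previous clean-amplitude^2 estimate
  for (k in seq_along(starts)) {
    idx <- starts[k]:(starts[k] + frame - 1L)
    X <- stats::fft(x[idx] * win)
    p <- Mod(X)^2
    gamma_k <- pmin(p / noise_psd, 1e4)          # posterior SNR, capped 40 dB
    xi <- cfg$alpha_dd * prev_amp2 / noise_psd +
      (1 - cfg$alpha_dd) * pmax(gamma_k - 1, 0)  # decision-directed prior SNR
    xi <- pmax(xi, 1e-6)
    v <- xi / (1 + xi) * gamma_k
    gain <- xi / (1 + xi) * exp(0.5 * pracma::expint(pmax(v, 1e-12)))
    gain <- pmax(cfg$gain_floor, pmin(gain, 1))
    prev_amp2 <- (gain^2) * p
    # slow noise-PSD update on frames the likelihood-ratio VAD calls noise
    vad <- mean(gamma_k * xi / (1 + xi) - log(1 + xi))
    if (vad < 0.15) {
      noise_psd <- pmax(0.98 * noise_psd + 0.02 * p, eps)
    }
    seg <- Re(stats::fft(X * gain, inverse = TRUE)) / n_fft
    y[idx] <- y[idx] + seg * win
    wsum[idx] <- wsum[idx] + win^2
  }
  nz <- wsum > 1e-8
  y[nz] <- y[nz] / wsum[nz]
  signal$samples <- pmax(-1, pmin(1, y))
  signal
}

#' One-shot preprocessing: resample, enhance, normalize
#'
#' Standardizes a recording to `target_rate`, applies log-MMSE
#' enhancement (optional) and peak normalization, in that order.
#'
#' @param signal An `audio_signal`.
#' @param target_rate Output sample rate in Hz (default 44100).
#' @param target_db Peak level in dBFS (default -0.1).
#' @param enhance Apply [logmmse_enhance()]? Default `TRUE`.
#' @param cfg An [enhancement_config()].
#' @return The preprocessed `audio_signal`.
#' @export
preprocess_audio <- function(signal, target_rate = 44100, target_db = -0.1,
                             enhance = TRUE, cfg = enhancement_config()) {
  out <- resample_audio(signal, target_rate)
  if (enhance && max(abs(out$samples)) > 0) out <- logmmse_enhance(out, cfg)
  if (max(abs(out$samples)) > 0) out <- peak_normalize(out, target_db)
  out
}
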