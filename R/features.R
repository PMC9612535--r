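#' MFCC configuration
#'
#' Parameters of the 20-dimensional per-frame feature: frame log energy
#' followed by 19 mel-frequency cepstral coefficients (c1..c19; c0 is
#' excluded, its role taken by the log-energy term).
#'
#' @param frame_ms Frame length in ms.
#' @param hop_ms Hop in ms.
#' @param n_fft FFT size (frames are zero-padded to it).
#' @param n_mels Number of triangular mel filters.
#' @param n_mfcc Cepstral coefficients kept (19 in the standard
#'   configuration).
#' @param include_log_energy Prepend the frame log energy? (`TRUE` in
#'   the standard configuration, total dimension 20.)
#' @param fmin,fmax Mel filterbank band edges in Hz; `fmax = NULL` means
#'   Nyquist.
#' @param energy_floor Floor (dB) for silent frames.
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_ms = 25, hop_ms = 10, n_fft = 2048,
                        n_mels = 40, n_mfcc = 19,
                        include_log_energy = TRUE,
                        fmin = 0, fmax = NULL, energy_floor = -120) {
  stopifnot(frame_ms > 0, hop_ms > 0, n_mels > n_mfcc, fmin >= 0)
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms, n_fft = n_fft,
                 n_mels = n_mels, n_mfcc = n_mfcc,
                 include_log_energy = include_log_energy,
                 fmin = fmin, fmax = fmax, energy_floor = energy_floor),
            class = "mfcc_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank: n_mels x (n_fft/2 + 1)
mel_filterbank <- function(sr, n_fft, n_mels, fmin, fmax) {
  if (is.null(fmax)) fmax <- sr / 2
  stopifnot(fmin < fmax, fmax <= sr / 2)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  bin_freqs <- (0:(n_fft %/% 2)) * sr / n_fft
  fb <- matrix(0, n_mels, length(bin_freqs))
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_freqs - lo) / (ce - lo)
    down <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix, rows k = 1..n_keep (the k = 0 row dropped)
dct_matrix <- function(n_in, n_keep) {
  k <- seq_len(n_keep)
  m <- outer(k, seq_len(n_in) - 0.5, function(k, j) cos(pi * k * j / n_in))
  m * sqrt(2 / n_in)
}

#' Compute the per-frame feature matrix of a chunk
#'
#' Four steps per frame: split into overlapping Hamming-windowed frames,
#' FFT to a power spectrum, log mel-filterbank energies, DCT. Each row
#' of the result is `[frame log energy, c1..c19]` (20 columns in the
#' standard configuration).
#'
#' @param chunk A `cough_chunk` or `audio_signal`.
#' @param cfg An [mfcc_config()].
#' @return A numeric matrix with `floor((dur_ms - frame_ms)/hop_ms) + 1`
#'   rows, of class `frame_feature_matrix`.
#' @export
compute_mfcc <- function(chunk, cfg = mfcc_config()) {
  sr <- chunk$sample_rate
  frame <- max(2L, round(cfg$frame_ms * sr / 1000))
  hop <- max(1L, round(cfg$hop_ms * sr / 1000))
  x <- chunk$samples
  if (length(x) < frame) stop("chunk shorter than one analysis frame")
  n_fft <- max(cfg$n_fft, frame)
  win <- signal::hamming(frame)
  fb <- mel_filterbank(sr, n_fft, cfg$n_mels, cfg$fmin, cfg$fmax)
  dct <- dct_matrix(cfg$n_mels, cfg$n_mfcc)
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  n_bins <- n_fft %/% 2 + 1L

  feats <- t(vapply(starts, function(s) {
    fr <- x[s:(s + frame - 1L)]
    rms <- sqrt(mean(fr^2))
    log_e <- if (rms <= 0) cfg$energy_floor
             else max(20 * log10(rms), cfg$energy_floor)
    padded <- c(fr * win, rep(0, n_fft - frame))
    pow <- Mod(stats::fft(padded)[seq_len(n_bins)])^2
    mel_e <- pmax(as.numeric(fb %*% pow), 1e-10)
    cc <- as.numeric(dct %*% log(mel_e))
    if (cfg$include_log_energy) c(log_e, cc) else cc
  }, numeric(cfg$n_mfcc + as.integer(cfg$include_log_energy))))
  structure(feats, class = c("frame_feature_matrix", class(feats)))
}

#' Reduce a frame feature matrix to a chunk feature vector
#'
#' Column-wise mean over frames, giving one 20-dimensional vector per
#' chunk.
#'
#' @param matrix A `frame_feature_matrix` (T x 20).
#' @return Numeric vector of length `ncol(matrix)`.
#' @export
chunk_feature <- function(matrix) {
  if (is.null(dim(matrix)) || nrow(matrix) < 1) stop("empty feature matrix")
  colMeans(matrix)
}

#' Aggregate chunk features into a patient feature
#'
#' The patient's disease feature is the componentwise mean of its cough
#' chunks' feature vectors: `x_k = (1/n) * sum_i x_ki`. Some chunks
#' carry the disease signature and others do not; averaging over all of
#' them sidesteps the missing per-chunk labels.
#'
#' @param features List of equal-length numeric vectors (one per chunk).
#' @param patient_ids Optional vector of source patient ids; if given,
#'   all must agree.
#' @return Numeric vector, the mean feature.
#' @export
aggregate_patient <- function(features, patient_ids = NULL) {
  if (length(features) == 0) stop("no chunk features to aggregate")
  if (!is.null(patient_ids) && length(unique(patient_ids)) > 1) {
    stop("chunk features from different patients cannot be aggregated")
  }
  Reduce(`+`, features) / length(features)
}

#' Concatenate chunk features along the time axis
#'
#' The rejected aggregation baseline: chunks are laid end to end on the
#' time sequence and their frame features concatenated, rather than
#' averaged.
#'
#' @param matrices List of `frame_feature_matrix` objects in time order.
#' @return A single stacked matrix.
#' @export
concat_chunks <- function(matrices) {
  if (length(matrices) == 0) stop("no chunks to concatenate")
  do.call(rbind, matrices)
}

#' Build a fixed-length per-patient frame sequence
#'
#' Concatenates the frame rows of a patient's chunks in chunk time
#' order, then truncates to the first `time_step` rows or zero-pads at
#' the end, for input to the LSTM classifier.
#'
#' @param matrices Ordered list of `frame_feature_matrix` objects.
#' @param time_step Target number of rows (default 50).
#' @return A `time_step` x d numeric matrix.
#' @export
patient_sequence <- function(matrices, time_step = 50) {
  all_rows <- concat_chunks(matrices)
  d <- ncol(all_rows)
  if (nrow(all_rows) >= time_step) {
    out <- all_rows[seq_len(time_step), , drop = FALSE]
  } else {
    out <- rbind(all_rows, matrix(0, time_step - nrow(all_rows), d))
  }
  unclass(out)
}

#' Per-patient feature table from a chunk list
#'
#' Runs [compute_mfcc()] and [chunk_feature()] on every chunk and
#' aggregates per patient. Optionally also builds the per-patient frame
#' sequences used by the sequence classifier.
#'
#' @param chunks List of `cough_chunk` objects with `patient_id` and
#'   `label` set.
#' @param cfg An [mfcc_config()].
#' @param sequences Also return per-patient `time_step` x 20 sequences?
#' @param time_step Sequence length when `sequences = TRUE`.
#' @return A data.frame with columns `patient_id`, `label`, `f1..f20`;
#'   when `sequences = TRUE` it carries a list of matrices in
#'   `attr(, "sequences")`, named by patient.
#' @export
patient_features <- function(chunks, cfg = mfcc_config(),
                             sequences = FALSE, time_step = 50) {
  stopifnot(length(chunks) > 0)
  ids <- vapply(chunks, function(ch) as.character(ch$patient_id), character(1))
  mats <- lapply(chunks, compute_mfcc, cfg = cfg)
  by_patient <- split(seq_along(chunks), ids)
  rows <- lapply(names(by_patient), function(pid) {
    idx <- by_patient[[pid]]
    v <- aggregate_patient(lapply(mats[idx], chunk_feature))
    lab <- chunks[[idx[1]]]$label
    c(list(patient_id = pid, label = if (is.null(lab)) NA_real_ else lab),
      as.list(stats::setNames(v, paste0("f", seq_along(v)))))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  if (sequences) {
    seqs <- lapply(names(by_patient), function(pid) {
      idx <- by_patient[[pid]]
      ord <- idx[order(vapply(chunks[idx], function(ch) ch$start_s, numeric(1)))]
      patient_sequence(mats[ord], time_step)
    })
    names(seqs) <- names(by_patient)
    attr(out, "sequences") <- seqs[out$patient_id]
  }
  out
}
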