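#' Segmentation configuration
#'
#' Frame log-energy thresholding parameters used to cut cough chunks out
#' of a patient recording. Frames are non-overlapping by default; frame
#' `k` covers the half-open span `[k*hop, k*hop + frame)` seconds.
#'
#' @param frame_ms Energy frame length in ms.
#' @param hop_ms Hop between frames in ms.
#' @param threshold_db Log-energy threshold in dBFS: frames at or above
#'   it belong to an event. The default of -36 dBFS (on peak-normalized
#'   audio) separates near-full-scale coughs recorded at 20-40 cm from
#'   quieter background speech.
#' @param min_event_s Minimum event duration; shorter events are dropped.
#' @param max_event_s Maximum event duration; longer events are split.
#' @param max_silence_s Sub-threshold gap tolerated inside an event.
#' @return A list of class `segmentation_config`.
#' @export
segmentation_config <- function(frame_ms = 10, hop_ms = 10,
                                threshold_db = -36, min_event_s = 0.2,
                                max_event_s = 10, max_silence_s = 0.3) {
  stopifnot(frame_ms > 0, hop_ms > 0, min_event_s < max_event_s,
            is.finite(threshold_db))
  structure(list(frame_ms = frame_ms, hop_ms = hop_ms,
                 threshold_db = threshold_db, min_event_s = min_event_s,
                 max_event_s = max_event_s, max_silence_s = max_silence_s),
            class = "segmentation_config")
}

#' Frame log energy in dBFS
#'
#' Energy of frame contents `a_1..a_N` is `20 * log10(sqrt(mean(a_i^2)))`,
#' i.e. 20 log10 of the frame RMS. All-zero frames are floored at
#' -120 dB.
#'
#' @param signal An `audio_signal` or `cough_chunk`.
#' @param cfg A [segmentation_config()].
#' @return Numeric vector, one dB value per frame position.
#' @export
frame_log_energy <- function(signal, cfg = segmentation_config()) {
  sr <- signal$sample_rate
  frame <- max(1L, round(cfg$frame_ms * sr / 1000))
  hop <- max(1L, round(cfg$hop_ms * sr / 1000))
  x <- signal$samples
  if (length(x) < frame) stop("signal shorter than one energy frame")
  starts <- seq(1L, length(x) - frame + 1L, by = hop)
  vapply(starts, function(s) {
    rms <- sqrt(mean(x[s:(s + frame - 1L)]^2))
    if (rms <= 0) -120 else max(20 * log10(rms), -120)
  }, numeric(1))
}

#' Detect audio events from a frame energy sequence
#'
#' Valid events are maximal runs of frames whose log energy is at or
#' above `threshold_db`. Sub-threshold gaps up to `max_silence_s` are
#' absorbed into an event; events shorter than `min_event_s` are
#' dropped; events longer than `max_event_s` are split at `max_event_s`
#' boundaries (trailing pieces below `min_event_s` are dropped too).
#' Events are disjoint, time-ordered, half-open `[start, end)` spans in
#' seconds.
#'
#' @param energies Numeric vector of per-frame log energies (dB).
#' @param cfg A [segmentation_config()].
#' @return A data.frame with columns `start_s`, `end_s`.
#' @export
detect_events <- function(energies, cfg = segmentation_config()) {
  stopifnot(length(energies) > 0)
  hop_s <- cfg$hop_ms / 1000
  frame_s <- cfg$frame_ms / 1000
  active <- energies >= cfg$threshold_db
  max_gap <- floor(cfg$max_silence_s / hop_s)

  # merge active runs separated by <= max_gap inactive frames
  runs <- rle(active)
  if (any(runs$values)) {
    inactive_runs <- which(!runs$values)
    interior <- inactive_runs[inactive_runs > 1L &
                              inactive_runs < length(runs$values)]
    runs$values[interior[runs$lengths[interior] <= max_gap]] <- TRUE
    active <- inverse.rle(runs)
  }

  runs <- rle(active)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- ends_idx - runs$lengths + 1L
  keep <- which(runs$values)
  out_start <- numeric(0)
  out_end <- numeric(0)
  for (r in keep) {
    s <- (starts_idx[r] - 1L) * hop_s
    e <- (ends_idx[r] - 1L) * hop_s + frame_s
    # split over-long events at max_event_s boundaries
    while (e - s > cfg$max_event_s + 1e-9) {
      out_start <- c(out_start, s)
      out_end <- c(out_end, s + cfg$max_event_s)
      s <- s + cfg$max_event_s
    }
    if (e - s >= cfg$min_event_s - 1e-9) {
      out_start <- c(out_start, s)
      out_end <- c(out_end, e)
    }
  }
  # drop pieces below the minimum duration (split remainders included)
  keep2 <- (out_end - out_start) >= cfg$min_event_s - 1e-9
  data.frame(start_s = out_start[keep2], end_s = out_end[keep2])
}

#' Construct a cough chunk
#'
#' A segmented audio event: samples cut from a source recording plus its
#' provenance (raw, or which augmentation produced it).
#'
#' @param samples Amplitude vector.
#' @param sample_rate Hz.
#' @param patient_id Source patient identifier.
#' @param start_s,end_s Span in the source audio, seconds.
#' @param label Optional class label (-1/+1).
#' @param provenance One of `"raw"`, `"time_shift"`, `"pitch_shift"`,
#'   `"noise_white"`, `"noise_pink"`.
#' @return An object of class `cough_chunk` (also `audio_signal`).
#' @export
cough_chunk <- function(samples, sample_rate, patient_id = NA_character_,
                        start_s = 0, end_s = length(samples) / sample_rate,
                        label = NULL, provenance = "raw") {
  provenance <- match.arg(provenance,
    c("raw", "time_shift", "pitch_shift", "noise_white", "noise_pink"))
  if (end_s <= start_s) stop("end_s must exceed start_s")
  obj <- audio_signal(samples, sample_rate, patient_id = patient_id,
                      label = label)
  obj$start_s <- start_s
  obj$end_s <- end_s
  obj$provenance <- provenance
  class(obj) <- c("cough_chunk", class(obj))
  obj
}

#' Cut detected events out of a recording
#'
#' @param signal The source `audio_signal`.
#' @param events A data.frame with `start_s`, `end_s` (from
#'   [detect_events()]).
#' @return A list of `cough_chunk` objects with provenance `"raw"`.
#' @export
extract_chunks <- function(signal, events) {
  dur <- duration(signal)
  lapply(seq_len(nrow(events)), function(i) {
    s <- events$start_s[i]
    e <- events$end_s[i]
    if (s < 0 || e > dur + 1e-9) stop("event outside signal bounds")
    i0 <- floor(s * signal$sample_rate) + 1L
    i1 <- min(length(signal$samples), ceiling(e * signal$sample_rate))
    cough_chunk(signal$samples[i0:i1], signal$sample_rate,
                patient_id = if (is.null(signal$patient_id)) NA_character_
                             else signal$patient_id,
                start_s = s, end_s = e, label = signal$label,
                provenance = "raw")
  })
}

#' Segment a recording into cough chunks
#'
#' Convenience wrapper: frame log energy, event detection, chunk
#' extraction.
#'
#' @inheritParams frame_log_energy
#' @return A list of `cough_chunk` objects.
#' @export
segment_audio <- function(signal, cfg = segmentation_config()) {
  extract_chunks(signal, detect_events(frame_log_energy(signal, cfg), cfg))
}
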