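#' Synthetic corpus specification
#'
#' Describes a seeded generator of synthetic patient recordings with
#' the structure of a small hospital cough-sound corpus: 173 patients
#' (91 bronchitis, 82 pneumonia), mean recording duration 3.92 s, one
#' to six cough bursts per recording (mean 2.37, matching 410 chunks
#' over 173 patients), low-level speech-like distractors from
#' accompanying family members, and stationary background noise.
#'
#' Each cough is a band-filtered noise burst with a fast attack and an
#' exponential decay; the class effect is injected by shifting the
#' band center by `class_effect_hz/2` down (bronchitis) or up
#' (pneumonia). This is a test harness with a controllable effect size,
#' not a model of real cough acoustics.
#'
#' @param n_bronchitis,n_pneumonia Patients per class.
#' @param mean_duration_s Mean recording duration (s); durations are
#'   Gamma-distributed around it.
#' @param coughs_min,coughs_max,coughs_mean Coughs per recording:
#'   `coughs_min + Binomial(coughs_max - coughs_min, p)` with `p` set
#'   by `coughs_mean`.
#' @param sample_rate Hz.
#' @param cough_dur_range Cough burst duration range (s).
#' @param attack_ms,decay_ms Burst attack ramp and exponential decay
#'   time constant.
#' @param base_center_hz Spectral band center shared by both classes.
#' @param class_effect_hz Band-center separation between the classes
#'   (0 = null effect, classes indistinguishable).
#' @param band_width_hz Gaussian band width (2 sigma).
#' @param center_jitter_hz Per-cough standard deviation of the band
#'   center.
#' @param distractor_db Distractor RMS level in dB relative to the
#'   cough peak.
#' @param background_snr_db Cough-to-background SNR in dB.
#' @param seed Integer seed.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_bronchitis = 91, n_pneumonia = 82,
                        mean_duration_s = 3.92,
                        coughs_min = 1, coughs_max = 6, coughs_mean = 2.37,
                        sample_rate = 44100,
                        cough_dur_range = c(0.3, 0.45),
                        attack_ms = 10, decay_ms = 150,
                        base_center_hz = 1500, class_effect_hz = 300,
                        band_width_hz = 800, center_jitter_hz = 50,
                        distractor_db = -50, background_snr_db = 35,
                        seed = 1L) {
  stopifnot(n_bronchitis > 0, n_pneumonia > 0, mean_duration_s > 0,
            coughs_min >= 0, coughs_max > coughs_min,
            coughs_mean >= coughs_min, coughs_mean <= coughs_max,
            class_effect_hz >= 0, sample_rate > 0)
  structure(list(n_bronchitis = n_bronchitis, n_pneumonia = n_pneumonia,
                 mean_duration_s = mean_duration_s,
                 coughs_min = coughs_min, coughs_max = coughs_max,
                 coughs_mean = coughs_mean, sample_rate = sample_rate,
                 cough_dur_range = cough_dur_range,
                 attack_ms = attack_ms, decay_ms = decay_ms,
                 base_center_hz = base_center_hz,
                 class_effect_hz = class_effect_hz,
                 band_width_hz = band_width_hz,
                 center_jitter_hz = center_jitter_hz,
                 distractor_db = distractor_db,
                 background_snr_db = background_snr_db,
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# Gaussian band-filtered white noise, peak-normalized. The FFT is done
# at the next power of two and truncated, keeping it fast for any n.
band_noise <- function(n, sr, fc, bw) {
  m <- stats::nextn(n, 2)
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  k <- seq_len(m) - 1L
  f <- pmin(k, m - k) * sr / m
  shape <- exp(-0.5 * ((f - fc) / (bw / 2))^2)
  y <- Re(stats::fft(W * shape, inverse = TRUE))[seq_len(n)] / m
  y / max(abs(y))
}

#' Generate one synthetic cough burst
#'
#' @param label Class label, -1 (bronchitis) or +1 (pneumonia).
#' @param spec A [corpus_spec()]. Uses the current R RNG state.
#' @return A `cough_chunk` with a near-full-scale band-noise burst.
#' @export
synth_cough <- function(label, spec = corpus_spec()) {
  stopifnot(label %in% c(-1, 1))
  sr <- spec$sample_rate
  dur <- stats::runif(1, spec$cough_dur_range[1], spec$cough_dur_range[2])
  n <- round(dur * sr)
  fc <- spec$base_center_hz + label * spec$class_effect_hz / 2 +
    stats::rnorm(1, 0, spec$center_jitter_hz)
  fc <- max(fc, spec$band_width_hz / 2 + 50)
  x <- band_noise(n, sr, fc, spec$band_width_hz)
  t <- (seq_len(n) - 1) / sr
  ta <- spec$attack_ms / 1000
  env <- ifelse(t < ta, t / ta, exp(-(t - ta) / (spec$decay_ms / 1000)))
  cough_chunk(0.9 * x * env, sr, label = label, provenance = "raw")
}

# Speech-like distractor: decaying harmonic complex with vibrato-free
# fundamental in the voiced-speech range.
synth_distractor <- function(sr, rms_target) {
  dur <- stats::runif(1, 0.3, 0.8)
  n <- round(dur * sr)
  f0 <- stats::runif(1, 180, 300)
  t <- (seq_len(n) - 1) / sr
  x <- numeric(n)
  for (h in 1:4) x <- x + sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi)) / h
  env <- sin(pi * t / dur)^2  # smooth on/off
  x <- x * env
  x * rms_target / sqrt(mean(x^2))
}

#' Generate one synthetic patient recording
#'
#' A silence bed with `k` cough bursts at distinct positions, low-level
#' harmonic "speech" distractors and stationary background noise. The
#' ground-truth cough intervals are recorded in the result's
#' `cough_intervals` field.
#'
#' @param label Class label, -1 or +1.
#' @param spec A [corpus_spec()]. Uses the current R RNG state.
#' @param patient_id Optional identifier.
#' @return An `audio_signal` with an extra `cough_intervals` data.frame
#'   (`start_s`, `end_s`).
#' @export
synth_patient_audio <- function(label, spec = corpus_spec(), patient_id = NULL) {
  sr <- spec$sample_rate
  p <- (spec$coughs_mean - spec$coughs_min) / (spec$coughs_max - spec$coughs_min)
  k <- spec$coughs_min + stats::rbinom(1, spec$coughs_max - spec$coughs_min, p)
  k <- max(k, 1L)
  dur <- stats::rgamma(1, shape = 12, rate = 12 / spec$mean_duration_s)
  dur <- max(dur, 0.85 * k + 0.3, 1.2)
  n <- round(dur * sr)

  # background noise scaled off the typical cough RMS
  cough_rms <- 0.3
  x <- stats::rnorm(n) * cough_rms * 10^(-spec$background_snr_db / 20)

  slot <- dur / k
  starts <- numeric(k); ends <- numeric(k)
  for (j in seq_len(k)) {
    burst <- synth_cough(label, spec)
    bd <- duration(burst)
    lo <- (j - 1) * slot + 0.05
    hi <- j * slot - bd - 0.35
    s <- if (hi > lo) stats::runif(1, lo, hi) else max((j - 1) * slot + (slot - bd) / 2, 0)
    i0 <- floor(s * sr) + 1L
    i1 <- min(n, i0 + length(burst$samples) - 1L)
    x[i0:i1] <- x[i0:i1] + burst$samples[seq_len(i1 - i0 + 1L)]
    starts[j] <- (i0 - 1L) / sr
    ends[j] <- i1 / sr
  }

  d_rms <- 0.9 * 10^(spec$distractor_db / 20)
  for (dd in seq_len(sample(1:3, 1))) {
    dx <- synth_distractor(sr, d_rms)
    s0 <- sample.int(max(n - length(dx), 1L), 1)
    i1 <- min(n, s0 + length(dx) - 1L)
    x[s0:i1] <- x[s0:i1] + dx[seq_len(i1 - s0 + 1L)]
  }

  out <- audio_signal(pmax(-1, pmin(1, x)), sr,
                      patient_id = patient_id, label = label)
  out$cough_intervals <- data.frame(start_s = starts, end_s = ends)
  out
}

#' Generate a full synthetic labeled corpus
#'
#' @param spec A [corpus_spec()]; generation is reproducible from
#'   `(spec, spec$seed)`.
#' @return An object of class `cough_corpus`: a list with `audios`
#'   (list of `audio_signal`s carrying ground-truth cough intervals),
#'   `patient_id`, and `label` vectors.
#' @export
synth_corpus <- function(spec = corpus_spec()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(spec$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  labels <- c(rep(-1, spec$n_bronchitis), rep(1, spec$n_pneumonia))
  ids <- c(sprintf("B%03d", seq_len(spec$n_bronchitis)),
           sprintf("P%03d", seq_len(spec$n_pneumonia)))
  audios <- lapply(seq_along(labels), function(i) {
    synth_patient_audio(labels[i], spec, patient_id = ids[i])
  })
  structure(list(audios = audios, patient_id = ids, label = labels,
                 spec = spec),
            class = "cough_corpus")
}

#' @export
print.cough_corpus <- function(x, ...) {
  durs <- vapply(x$audios, duration, numeric(1))
  n_coughs <- sum(vapply(x$audios, function(a) nrow(a$cough_intervals), numeric(1)))
  cat(sprintf("<cough_corpus> %d patients (%d bronchitis / %d pneumonia)\n",
              length(x$audios), sum(x$label == -1), sum(x$label == 1)))
  cat(sprintf("  mean duration %.2f s, %d cough bursts total\n",
              mean(durs), n_coughs))
  invisible(x)
}

#' Interval-overlap F1 between ground truth and detected events
#'
#' Greedily matches each truth interval to an unmatched detected event
#' with intersection-over-union above `iou_min`, then reports precision
#' (matched / detected), recall (matched / truth) and their harmonic
#' mean.
#'
#' @param truth,detected Data.frames with `start_s`, `end_s`.
#' @param iou_min Minimum IoU for a match (default 0.4).
#' @return A list with `precision`, `recall`, `f1`.
#' @export
interval_f1 <- function(truth, detected, iou_min = 0.4) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    best <- 0; best_j <- 0L
    for (j in seq_len(nrow(detected))) {
      if (used[j]) next
      inter <- max(0, min(truth$end_s[i], detected$end_s[j]) -
                      max(truth$start_s[i], detected$start_s[j]))
      uni <- max(truth$end_s[i], detected$end_s[j]) -
             min(truth$start_s[i], detected$start_s[j])
      iou <- if (uni > 0) inter / uni else 0
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best >= iou_min) { tp <- tp + 1L; used[best_j] <- TRUE }
  }
  prec <- if (nrow(detected) == 0) NA_real_ else tp / nrow(detected)
  rec <- if (nrow(truth) == 0) NA_real_ else tp / nrow(truth)
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  list(precision = prec, recall = rec, f1 = f1)
}
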