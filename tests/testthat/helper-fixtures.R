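# Shared fixtures: small, cheap signals built in code.

make_tone <- function(freq, dur = 1, sr = 8000, amp = 0.5) {
  audio_signal(amp * sin(2 * pi * freq * (0:(round(dur * sr) - 1)) / sr), sr)
}

make_noise_chunk <- function(dur = 0.5, sr = 8000, patient_id = "p1",
                             label = -1, amp = 0.3, seed = 1) {
  set.seed(seed)
  cough_chunk(amp * stats::rnorm(round(dur * sr)), sr,
              patient_id = patient_id, label = label)
}

make_tone_chunk <- function(freq, dur = 1, sr = 16000, amp = 0.5,
                            patient_id = "p1", label = -1) {
  cough_chunk(amp * sin(2 * pi * freq * (0:(round(dur * sr) - 1)) / sr), sr,
              patient_id = patient_id, label = label)
}

dominant_freq <- function(x, sr) {
  sp <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  (which.max(sp) - 1) * sr / length(x)
}

# A small corpus spec for fast pipeline tests (not the study defaults).
tiny_corpus_spec <- function(n = 8, effect = 600, seed = 1, sr = 16000) {
  corpus_spec(n_bronchitis = n, n_pneumonia = n, sample_rate = sr,
              class_effect_hz = effect, seed = seed)
}

# Independent brute-force event detector: frame-by-frame state machine,
# then straightforward split/min filtering. Used as the oracle for
# detect_events.
oracle_events <- function(energies, cfg) {
  hop_s <- cfg$hop_ms / 1000
  frame_s <- cfg$frame_ms / 1000
  active <- energies >= cfg$threshold_db
  max_gap <- floor(cfg$max_silence_s / hop_s)
  n <- length(active)
  raw <- list()
  i <- 1L
  while (i <= n) {
    if (!active[i]) { i <- i + 1L; next }
    start <- i; last <- i; j <- i + 1L
    while (j <= n) {
      if (active[j]) { last <- j; j <- j + 1L } else {
        g <- 0L; jj <- j
        while (jj <= n && !active[jj]) { g <- g + 1L; jj <- jj + 1L }
        if (jj <= n && g <= max_gap) j <- jj else break
      }
    }
    raw[[length(raw) + 1L]] <- c((start - 1L) * hop_s, (last - 1L) * hop_s + frame_s)
    i <- j
  }
  out <- NULL
  for (ev in raw) {
    s <- ev[1]; e <- ev[2]
    while (e - s > cfg$max_event_s + 1e-9) {
      out <- rbind(out, c(s, s + cfg$max_event_s))
      s <- s + cfg$max_event_s
    }
    if (e - s >= cfg$min_event_s - 1e-9) out <- rbind(out, c(s, e))
  }
  if (is.null(out)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  out <- out[(out[, 2] - out[, 1]) >= cfg$min_event_s - 1e-9, , drop = FALSE]
  data.frame(start_s = out[, 1], end_s = out[, 2])
}

# Mann-Whitney formulation of the AUC: fraction of (pos, neg) pairs
# ranked correctly, ties counted 1/2.
mann_whitney_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == -1]
  u <- 0
  for (p in pos) u <- u + sum(p > neg) + 0.5 * sum(p == neg)
  u / (length(pos) * length(neg))
}

# Dual soft-margin QP solved independently with kernlab::ipop; returns
# the optimal objective value (equal to the primal optimum).
ipop_svm_objective <- function(x, y, C, kernel = "linear", gamma = 0.5) {
  K <- if (kernel == "linear") x %*% t(x) else {
    d2 <- outer(rowSums(x^2), rowSums(x^2), "+") - 2 * x %*% t(x)
    exp(-gamma * pmax(d2, 0))
  }
  n <- length(y)
  H <- (y %*% t(y)) * K + diag(1e-8, n)
  sol <- kernlab::ipop(rep(-1, n), H, t(y), 0, rep(0, n), rep(C, n), 0,
                       sigf = 9)
  a <- kernlab::primal(sol)
  sum(a) - 0.5 * as.numeric(t(a) %*% H %*% a)
}
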