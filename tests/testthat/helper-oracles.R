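# Independent oracles used across tests. These deliberately use slow,
# direct formulations (nested loops, dense FFTs) so they share no code with
# the implementation they check.

# Dense 2-D cross-correlation with mirror (no edge repeat) padding.
brute_xcorr2_reflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  kr <- nrow(k); kc <- ncol(k)
  ro <- (kr - 1) / 2; co <- (kc - 1) / 2
  refl <- function(p, n) {
    while (p < 1 || p > n) {
      if (p < 1) p <- 2 - p
      if (p > n) p <- 2 * n - p
    }
    p
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (u in seq_len(kr)) {
        for (v in seq_len(kc)) {
          acc <- acc + m[refl(i + u - 1 - ro, nr), refl(j + v - 1 - co, nc)] *
            k[u, v]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# FFT peak frequency of a waveform (Hz).
fft_peak_freq <- function(x, fs) {
  p <- Mod(stats::fft(x))^2
  half <- seq_len(floor(length(x) / 2))
  (which.max(p[half]) - 1) * fs / length(x)
}

# FFT spectral centroid of a waveform (Hz), positive frequencies only.
fft_centroid <- function(x, fs) {
  p <- Mod(stats::fft(x))^2
  half <- seq_len(floor(length(x) / 2))
  f <- (half - 1) * fs / length(x)
  sum(f * p[half]) / sum(p[half])
}

# Per-frame STFT ridge (argmax frequency, Hz) — an independent, plain
# framing loop (no padding, no windowing subtleties).
stft_ridge <- function(x, fs, nfft = 4096, hop = 2048) {
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  vapply(starts, function(s) {
    seg <- x[s:(s + nfft - 1)]
    p <- Mod(stats::fft(seg))^2
    half <- seq_len(nfft / 2)
    (which.max(p[half]) - 1) * fs / nfft
  }, numeric(1))
}

# Pulse onset count via envelope peak detection.
count_pulse_onsets <- function(x, fs, min_gap_s = 5e-4) {
  env <- abs(x)
  thr <- 0.5 * max(env)
  above <- which(env > thr)
  if (length(above) == 0) return(0L)
  gaps <- which(diff(above) > round(min_gap_s * fs))
  length(gaps) + 1L
}

# Segment layout oracle: direct simulation of the tiling rule.
enumerate_segments <- function(start, end, window = 0.8, overlap = 0.5) {
  d <- end - start
  if (d <= window + 1e-12) {
    mid <- (start + end) / 2
    return(matrix(c(mid - window / 2, mid + window / 2), 1))
  }
  hop <- window * (1 - overlap)
  starts <- start
  while (tail(starts, 1) + window < end - 1e-9) {
    nxt <- tail(starts, 1) + hop
    if (nxt + window >= end - 1e-9) nxt <- end - window
    starts <- c(starts, nxt)
  }
  cbind(starts, starts + window)
}

# Metrics oracle: per-item counting from raw label vectors.
count_metrics <- function(true, pred, n_classes) {
  per_class <- lapply(0:(n_classes - 1), function(k) {
    tp <- sum(true == k & pred == k)
    fp <- sum(true != k & pred == k)
    fn <- sum(true == k & pred != k)
    tn <- sum(true != k & pred != k)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(accuracy = 100 * (tp + tn) / length(true), precision = 100 * prec,
      recall = 100 * rec, f1 = 100 * f1)
  })
  do.call(rbind, per_class)
}
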