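#' Spectrogram rendering parameters
#'
#' Defaults are chosen so that a 0.8 s segment at 192 kHz maps natively to
#' 300 frames (153,600 samples / 512-sample hop) before any resampling:
#' Hann window of 2048 samples, hop 512, magnitudes in dB clipped to an
#' 80 dB dynamic range, frequency rows limited to the 3-96 kHz band and
#' linearly interpolated to 150 rows.
#'
#' @param window STFT window length, samples.
#' @param hop Hop between frame centers, samples.
#' @param dynamic_range_db Dynamic range kept below the per-image maximum, dB.
#' @param band_low_hz,band_high_hz Band limits of the retained rows, Hz.
#' @param out_width,out_height Output image size (time frames x frequency rows).
#' @return A list of class `spectrogram_params`.
#' @export
spectrogram_params <- function(window = 2048, hop = 512,
                               dynamic_range_db = 80,
                               band_low_hz = 3000, band_high_hz = 96000,
                               out_width = 300, out_height = 150) {
  stopifnot(window > 0, hop > 0, dynamic_range_db > 0,
            band_low_hz >= 0, band_high_hz > band_low_hz,
            out_width > 1, out_height > 1)
  structure(list(window = window, hop = hop,
                 dynamic_range_db = dynamic_range_db,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 out_width = out_width, out_height = out_height),
            class = "spectrogram_params")
}

# Magnitude of the per-column FFT, keeping bins 1..n/2+1. Columns are real,
# so pairs are packed into one complex FFT and unpacked afterwards.
stft_magnitude <- function(fw) {
  n <- nrow(fw)
  nf <- ncol(fw)
  half <- n / 2 + 1
  odd <- seq(1, nf, by = 2)
  even <- seq(2, nf, by = 2)
  if (length(even) < length(odd)) fw <- cbind(fw, 0)
  Z <- stats::mvfft(fw[, odd, drop = FALSE] + 1i * fw[, odd + 1, drop = FALSE])
  Zc <- Conj(Z[c(1, n:2), , drop = FALSE])
  X1 <- (Z + Zc) / 2
  X2 <- (Z - Zc) / (2i)
  S <- matrix(0, half, length(odd) * 2)
  S[, odd] <- Mod(X1[seq_len(half), , drop = FALSE])
  S[, odd + 1] <- Mod(X2[seq_len(half), , drop = FALSE])
  S[, seq_len(nf), drop = FALSE]
}

# Linear-interpolation operator mapping values sampled at src positions to
# dst positions (rows sum to 1; endpoints clamped).
interp_operator <- function(src, dst) {
  m <- matrix(0, length(dst), length(src))
  for (i in seq_along(dst)) {
    x <- dst[i]
    if (x <= src[1]) { m[i, 1] <- 1; next }
    if (x >= src[length(src)]) { m[i, length(src)] <- 1; next }
    j <- findInterval(x, src)
    w <- (x - src[j]) / (src[j + 1] - src[j])
    m[i, j] <- 1 - w
    m[i, j + 1] <- w
  }
  m
}

#' Compute a band-limited grayscale spectrogram image
#'
#' Renders one fixed-length segment as the image fed to the classifier:
#' magnitude STFT (Hann window, reflect-padded frame centers) -> dB scale ->
#' clip to a fixed dynamic range below the per-image maximum -> per-image
#' min-max to \[0, 1\] -> crop rows to the 3-96 kHz band -> bilinear resample
#' to exactly `out_height` x `out_width` (150 x 300 by default, rows =
#' frequency with row 1 the lowest band, columns = time).
#'
#' Because the min-max rescale happens after the dB transform, the image is
#' invariant to any positive scaling of the waveform. An all-constant
#' segment has no contrast to stretch and yields the defined degenerate
#' output: a uniform image at 0.5.
#'
#' @param segment Numeric waveform, or one row of a [segment_event()] tibble.
#' @param sample_rate Sampling rate, Hz (taken from the segment row if
#'   present there).
#' @param params [spectrogram_params()].
#' @param class Optional class code attached to the image.
#' @return A `spectrogram_image`: numeric matrix `out_height x out_width`
#'   in \[0,1\] with attributes `freq_axis` (Hz), `time_axis` (s) and
#'   `class`.
#' @export
compute_spectrogram <- function(segment, sample_rate = 192000,
                                params = spectrogram_params(),
                                class = NULL) {
  if (is.list(segment) && !is.null(segment$samples)) {
    if (is.null(class) && !is.null(segment$class)) {
      class <- as.integer(segment$class)[1]
    }
    segment <- if (is.list(segment$samples)) segment$samples[[1]] else segment$samples
  }
  x <- as.numeric(segment)
  n <- length(x)
  stopifnot(n > 0)
  nyq <- sample_rate / 2
  band_high <- params$band_high_hz
  if (band_high > nyq) {
    warn(sprintf("band edge %.0f Hz capped at Nyquist (%.0f Hz)", band_high, nyq))
    band_high <- nyq
  }

  win <- params$window
  hop <- params$hop
  n_frames <- max(1L, floor(n / hop))
  centers <- (seq_len(n_frames) - 0.5) * hop          # sample index of frame centers
  half <- win / 2

  # reflect padding so edge frames are full-length
  pad <- ceiling(half) + 1L
  xp <- c(rev(x[seq_len(min(pad, n - 1)) + 1L]), x,
          rev(x[n - seq_len(min(pad, n - 1))]))
  offset <- min(pad, n - 1)

  idx0 <- round(centers - half) + offset
  frames <- matrix(0, win, n_frames)
  for (j in seq_len(n_frames)) {
    frames[, j] <- xp[(idx0[j] + 1L):(idx0[j] + win)]
  }
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  S <- stft_magnitude(frames * hann)

  top_s <- max(S)
  if (top_s <= 0 || !is.finite(top_s)) {
    img_uniform <- matrix(0.5, params$out_height, params$out_width)
  } else {
    # floor relative to the per-image maximum keeps the dB image exactly
    # invariant under positive amplitude scaling
    db <- 20 * log10(pmax(S, top_s * 1e-12) / top_s)
    if (max(db) - min(db) < 1e-9) {
      img_uniform <- matrix(0.5, params$out_height, params$out_width)
    } else {
      img_uniform <- NULL
      db <- pmax(db, -params$dynamic_range_db)
      db <- (db - min(db)) / (max(db) - min(db))
    }
  }

  bin_freqs <- (seq_len(win / 2 + 1) - 1) * sample_rate / win
  keep <- bin_freqs >= params$band_low_hz & bin_freqs <= band_high
  if (!any(keep)) abort("no FFT bins fall inside the requested band")
  freq_axis <- seq(params$band_low_hz, band_high, length.out = params$out_height)
  time_axis <- seq(0.5 / params$out_width, 1 - 0.5 / params$out_width,
                   length.out = params$out_width) * (n / sample_rate)

  if (is.null(img_uniform)) {
    cropped <- db[keep, , drop = FALSE]
    rows_op <- interp_operator(bin_freqs[keep], freq_axis)
    cols_op <- interp_operator(centers / sample_rate, time_axis)
    img <- rows_op %*% cropped %*% t(cols_op)
    img <- pmin(pmax(img, 0), 1)
  } else {
    img <- img_uniform
  }
  new_spectrogram_image(img, freq_axis, time_axis, class)
}

new_spectrogram_image <- function(pixels, freq_axis, time_axis, class = NULL) {
  stopifnot(is.matrix(pixels), nrow(pixels) == length(freq_axis),
            ncol(pixels) == length(time_axis))
  structure(pixels, freq_axis = freq_axis, time_axis = time_axis,
            class_code = if (is.null(class)) NA_integer_ else as.integer(class),
            class = c("spectrogram_image", "matrix", "array"))
}

#' @export
print.spectrogram_image <- function(x, ...) {
  fa <- attr(x, "freq_axis")
  cat(sprintf("<spectrogram_image> %d x %d (freq %.1f-%.1f kHz, class %s)\n",
              nrow(x), ncol(x), min(fa) / 1000, max(fa) / 1000,
              ifelse(is.na(attr(x, "class_code")), "?",
                     attr(x, "class_code"))))
  invisible(x)
}

#' Plot a spectrogram image
#'
#' @param object A `spectrogram_image`.
#' @param ... Unused.
#' @return A ggplot object (time on x, frequency on y, gray fill).
#' @export
autoplot.spectrogram_image <- function(object, ...) {
  df <- tidyr::expand_grid(time_s = attr(object, "time_axis"),
                           freq_khz = attr(object, "freq_axis") / 1000)
  df$value <- as.vector(unclass(object))      # column-major: freq varies fastest
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_khz,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = NULL) +
    ggplot2::labs(x = "time (s)", y = "frequency (kHz)") +
    ggplot2::theme_minimal()
}

#' Export a spectrogram image as 8-bit grayscale PNG
#'
#' @param image A `spectrogram_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_spectrogram_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the 'png' package is required to write PNG files")
  }
  m <- unclass(image)
  png::writePNG(m[rev(seq_len(nrow(m))), , drop = FALSE], path)  # low freq at bottom
  invisible(path)
}
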