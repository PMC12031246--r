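#' Cut a labeled event into fixed-length segments
#'
#' Implements the label-guided windowing used to build the training set:
#' events no longer than the window yield a single window centered on the
#' event midpoint; longer events are tiled with 50%-overlapping windows
#' from the event start, with the final window right-aligned to the event
#' end so the whole event is covered. Windows are clamped inside the
#' recording (shifted, never zero-padded), so every segment contains
#' `round(window * sample_rate)` real audio samples.
#'
#' For duration `d > window` the number of windows is
#' `ceiling((d - window) / (window * (1 - overlap_fraction))) + 1`.
#'
#' @param recording An `audio_recording` (see [load_recording()]).
#' @param event One annotation event: a list or one-row tibble with
#'   `start`, `end` (seconds) and `class`.
#' @param window Window length in seconds (default 0.8).
#' @param overlap_fraction Overlap between consecutive windows for long
#'   events (default 0.5).
#' @param extract_samples Attach the waveform windows as a `samples`
#'   list-column (default); `FALSE` returns the manifest only.
#' @return A tibble with one row per segment: `start`, `end`, `class`,
#'   `origin` and (unless disabled) a `samples` list-column of numeric
#'   windows.
#' @export
segment_event <- function(recording, event, window = 0.8,
                          overlap_fraction = 0.5, extract_samples = TRUE) {
  stopifnot(inherits(recording, "audio_recording"),
            window > 0, overlap_fraction > 0, overlap_fraction < 1)
  fs <- recording$sample_rate
  rec_dur <- length(recording$samples) / fs
  n_win <- round(window * fs)
  if (length(recording$samples) < n_win) {
    abort(sprintf("recording (%.3f s) is shorter than the %.3f s window",
                  rec_dur, window))
  }
  if (fs < 192000) {
    warn(sprintf("sample rate %d Hz gives Nyquist %.0f Hz, below the 96 kHz band edge; spectrograms will be capped at Nyquist",
                 fs, fs / 2))
  }
  start <- event$start
  end <- event$end
  if (start < 0 || end > rec_dur + 1e-9 || end <= start) {
    abort(sprintf("event [%.3f, %.3f] s outside recording [0, %.3f] s",
                  start, end, rec_dur))
  }
  d <- end - start
  if (d <= window + 1e-12) {
    starts <- (start + end) / 2 - window / 2
  } else {
    hop <- window * (1 - overlap_fraction)
    n <- ceiling((d - window) / hop - 1e-12) + 1
    starts <- c(start + (seq_len(n - 1) - 1) * hop, end - window)
  }
  starts <- pmin(pmax(starts, 0), rec_dur - window)
  out <- tibble::tibble(
    start = starts, end = starts + window,
    class = as.integer(event$class),
    origin = recording$source_path %||% NA_character_
  )
  if (extract_samples) {
    out$samples <- lapply(starts, function(s) {
      i0 <- min(round(s * fs), length(recording$samples) - n_win) + 1L
      recording$samples[i0:(i0 + n_win - 1L)]
    })
  }
  out
}

#' Sample noise segments from the un-annotated part of a recording
#'
#' Draws fixed-length windows uniformly at random from the portions of the
#' recording that do not intersect any annotated event (plus an optional
#' guard band). Sampled windows are mutually disjoint. If there is not
#' enough annotation-free audio, fewer windows are returned with a warning.
#'
#' @inheritParams segment_event
#' @param events Annotation tibble with `start`/`end` columns (may be empty).
#' @param count Number of noise windows requested.
#' @param seed Integer seed for reproducible placement.
#' @param guard Guard band, seconds, added around each event (default 0).
#' @return A tibble in the same shape as [segment_event()] output, all
#'   rows class 0.
#' @export
sample_noise_segments <- function(recording, events, count, seed = 1L,
                                  window = 0.8, guard = 0) {
  stopifnot(inherits(recording, "audio_recording"), count >= 0)
  fs <- recording$sample_rate
  rec_dur <- length(recording$samples) / fs
  n_win <- round(window * fs)
  if (length(recording$samples) < n_win) {
    abort("recording shorter than the noise window")
  }
  ev <- if (nrow(events) == 0) {
    tibble::tibble(start = numeric(), end = numeric())
  } else {
    tibble::tibble(start = pmax(events$start - guard, 0),
                   end = pmin(events$end + guard, rec_dur))
  }
  overlaps_any <- function(s, e, iv) {
    nrow(iv) > 0 && any(s < iv$end & e > iv$start)
  }
  withr::local_seed(seed)
  picked <- tibble::tibble(start = numeric(), end = numeric())
  attempts <- 0L
  max_attempts <- max(2000L, 200L * count)
  while (nrow(picked) < count && attempts < max_attempts) {
    attempts <- attempts + 1L
    s <- runif(1, 0, rec_dur - window)
    e <- s + window
    if (!overlaps_any(s, e, ev) && !overlaps_any(s, e, picked)) {
      picked <- dplyr::bind_rows(picked, tibble::tibble(start = s, end = e))
    }
  }
  if (nrow(picked) < count) {
    warn(sprintf("only %d of %d requested noise segments could be placed in annotation-free audio",
                 nrow(picked), count))
  }
  picked <- dplyr::arrange(picked, .data$start)
  samples <- lapply(picked$start, function(s) {
    i0 <- min(round(s * fs), length(recording$samples) - n_win) + 1L
    recording$samples[i0:(i0 + n_win - 1L)]
  })
  tibble::tibble(start = picked$start, end = picked$end, class = 0L,
                 origin = recording$source_path %||% NA_character_,
                 samples = samples)
}

#' Segment a whole labeled recording
#'
#' Applies [segment_event()] to every annotated event and optionally adds
#' noise segments, returning a single segment table ready for spectrogram
#' rendering. The table without the `samples` column is the segment
#' manifest; write it with `readr`/`write.csv` for reproducibility.
#'
#' @inheritParams segment_event
#' @inheritParams sample_noise_segments
#' @param events Annotation tibble as returned by [read_label_track()];
#'   rows with `NA` class are skipped with a warning.
#' @param noise_count Number of class-0 segments to add (0 for none).
#' @return Segment tibble (`start`, `end`, `class`, `origin`, `samples`).
#' @export
segment_recording <- function(recording, events, window = 0.8,
                              overlap_fraction = 0.5, noise_count = 0,
                              seed = 1L, guard = 0) {
  if (anyNA(events$class)) {
    warn("events with unknown class skipped")
    events <- events[!is.na(events$class), ]
  }
  seg <- purrr::map(seq_len(nrow(events)), function(i) {
    segment_event(recording, events[i, ], window, overlap_fraction)
  }) |> dplyr::bind_rows()
  if (noise_count > 0) {
    seg <- dplyr::bind_rows(
      seg,
      sample_noise_segments(recording, events, noise_count, seed = seed,
                            window = window, guard = guard))
  }
  seg
}
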