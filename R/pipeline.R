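#' Prepare a spectrogram image archive from labeled recordings
#'
#' The data-preparation pipeline: each WAV recording is loaded, min-max
#' normalized, cut into 0.8 s class-labeled segments guided by its
#' Audacity label track (long events tiled with 50% overlap), rendered as
#' band-limited grayscale spectrograms and edge-filtered according to the
#' segment class. The result is written as an image archive (`.rds`) plus
#' a plain-text manifest CSV.
#'
#' @param wav_paths Character vector of WAV files.
#' @param label_paths Matching label-track files (default: `.txt` next to
#'   each WAV). Files without labels are skipped with a warning.
#' @param outdir Output directory.
#' @param params [spectrogram_params()].
#' @param window,overlap_fraction Segmentation settings.
#' @param noise_count Noise segments sampled per recording.
#' @param sobel_size Kernel size for class-conditional filtering, or
#'   `NULL` to store raw spectrograms.
#' @param seed Seed for noise-segment placement.
#' @return Invisibly, a list with `archive` (rds path), `manifest_csv`,
#'   and the manifest tibble.
#' @export
prepare_image_archive <- function(wav_paths,
                                  label_paths = sub("\\.wav$", ".txt", wav_paths),
                                  outdir = ".",
                                  params = spectrogram_params(),
                                  window = 0.8, overlap_fraction = 0.5,
                                  noise_count = 0, sobel_size = 7,
                                  seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  images <- list(); labels <- integer(0); manifest <- list()
  for (i in seq_along(wav_paths)) {
    if (!file.exists(label_paths[i])) {
      warn(sprintf("no label track for %s; skipped", wav_paths[i]))
      next
    }
    rec <- load_recording(wav_paths[i])
    rec$samples <- minmax_normalize(rec$samples)
    events <- read_label_track(label_paths[i])
    segs <- segment_recording(rec, events, window = window,
                              overlap_fraction = overlap_fraction,
                              noise_count = noise_count, seed = seed + i)
    for (s in seq_len(nrow(segs))) {
      img <- compute_spectrogram(segs$samples[[s]], rec$sample_rate, params,
                                 class = segs$class[s])
      if (!is.null(sobel_size)) {
        img <- filter_for_class(img, segs$class[s], size = sobel_size)
      }
      images[[length(images) + 1L]] <- unclass(img)
      labels <- c(labels, segs$class[s])
      manifest[[length(manifest) + 1L]] <- tibble::tibble(
        recording = wav_paths[i], start = segs$start[s], end = segs$end[s],
        class = segs$class[s])
    }
  }
  manifest <- dplyr::bind_rows(manifest)
  manifest$index <- seq_len(nrow(manifest))
  archive <- file.path(outdir, "images.rds")
  arr <- as_image_array(images, c(params$out_height, params$out_width))
  saveRDS(list(images = arr, labels = labels, manifest = manifest,
               params = params, sobel_size = sobel_size), archive)
  manifest_csv <- file.path(outdir, "manifest.csv")
  utils::write.csv(manifest, manifest_csv, row.names = FALSE)
  invisible(list(archive = archive, manifest_csv = manifest_csv,
                 manifest = manifest, labels = labels))
}

#' Classify a recording with a sliding window
#'
#' Deployment mode: slides fixed-length windows (default 0.8 s at a 0.4 s
#' hop, the training hop) over a recording, renders each as a spectrogram,
#' applies the chosen filter direction and emits per-window class
#' probabilities. Because the training-time filter direction depends on
#' the (unknown) label, a `direction` must be chosen explicitly —
#' `"frequency"` (the whistle/noise filter), `"time"` (the impulsive-class
#' filter) or `"none"`.
#'
#' @param model A trained `whistlenet_model`.
#' @param recording An `audio_recording` or path to a WAV file.
#' @param direction Filter direction: `"time"`, `"frequency"` or `"none"`.
#' @param window Window length, seconds.
#' @param hop Hop between windows, seconds.
#' @param params [spectrogram_params()].
#' @param sobel_size Kernel size when filtering.
#' @return Tibble with `window_start`, `window_end`, probability columns
#'   and the predicted `label` per window.
#' @export
predict_recording <- function(model, recording, direction,
                              window = 0.8, hop = 0.4,
                              params = spectrogram_params(),
                              sobel_size = 7) {
  if (missing(direction) || is.null(direction)) {
    abort(paste("the edge-filter direction is label-dependent and unknown at",
                "deployment; pass direction = \"time\", \"frequency\" or \"none\""))
  }
  direction <- match.arg(direction, c("time", "frequency", "none"))
  if (is.character(recording)) recording <- load_recording(recording)
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate
  dur <- length(recording$samples) / fs
  if (dur < window) abort("recording shorter than one window")
  starts <- seq(0, dur - window + 1e-9, by = hop)
  n_win <- round(window * fs)
  imgs <- lapply(starts, function(s) {
    i0 <- min(round(s * fs), length(recording$samples) - n_win) + 1L
    img <- compute_spectrogram(recording$samples[i0:(i0 + n_win - 1L)],
                               fs, params)
    unclass(filter_for_class(img, override = direction, size = sobel_size))
  })
  out <- predict(model, imgs)
  dplyr::bind_cols(
    tibble::tibble(window_start = starts, window_end = starts + window),
    out)
}

#' Render scenes from a simulation manifest
#'
#' Takes a manifest of scene-configuration YAML files (or a directory of
#' them) and writes a WAV plus an Audacity label track per scene.
#'
#' @param config_paths Character vector of scene-config YAML files.
#' @param outdir Output directory.
#' @return Invisibly, a tibble with the written `wav` and `labels` paths.
#' @export
simulate_scenes <- function(config_paths, outdir = ".") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(config_paths, function(p) {
    cfg <- read_scene_config(p)
    scene <- render_scene(cfg)
    stem <- tools::file_path_sans_ext(basename(p))
    paths <- write_scene(scene, file.path(outdir, paste0(stem, ".wav")))
    tibble::tibble(config = p, wav = paths[["wav"]],
                   labels = paths[["labels"]],
                   n_events = nrow(scene$events))
  })
  invisible(dplyr::bind_rows(rows))
}
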