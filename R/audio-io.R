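#' Read a PCM WAV recording
#'
#' Parses a RIFF/WAVE file (16-bit integer PCM). Multi-channel files are
#' collapsed to mono by averaging the channels, matching the single-hydrophone
#' recording setup the pipeline targets.
#'
#' @param path Path to a `.wav` file.
#' @return An object of class `audio_recording`: a list with `samples`
#'   (numeric in \[-1, 1\]), `sample_rate` (Hz), `bit_depth` and
#'   `source_path`.
#' @seealso [write_wav()], [minmax_normalize()]
#' @export
load_recording <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort(sprintf("not a RIFF/WAVE file: %s", path))
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort(sprintf("not a RIFF/WAVE file: %s", path))

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bit_depth    = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      if (size > 16) invisible(readBin(con, "raw", size - 16))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    abort(sprintf("corrupt WAV: missing fmt/data chunk in %s", path))
  }
  if (fmt$audio_format != 1 || fmt$bit_depth != 16) {
    abort(sprintf("only 16-bit integer PCM WAV is supported (got format %d, %d bit)",
                  fmt$audio_format, fmt$bit_depth))
  }
  ints <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                  endian = "little", signed = TRUE)
  if (length(ints) == 0) abort(sprintf("empty audio in %s", path))
  x <- ints / 32767
  if (fmt$n_channels > 1) {
    inform(sprintf("averaging %d channels to mono", fmt$n_channels))
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  new_audio_recording(x, fmt$sample_rate, fmt$bit_depth, path)
}

new_audio_recording <- function(samples, sample_rate, bit_depth = 16L,
                                source_path = NA_character_) {
  stopifnot(sample_rate > 0, length(samples) > 0)
  structure(
    list(samples = as.numeric(samples), sample_rate = sample_rate,
         bit_depth = as.integer(bit_depth), source_path = source_path),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %.3f s at %d Hz (%d-bit, %s)\n",
              length(x$samples) / x$sample_rate, x$sample_rate, x$bit_depth,
              ifelse(is.na(x$source_path), "in memory", x$source_path)))
  invisible(x)
}

duration.audio_recording <- function(x) length(x$samples) / x$sample_rate

#' Write samples to a 16-bit PCM WAV file
#'
#' Values are expected in \[-1, 1\]; values outside are clipped with a
#' warning. Quantization is `round(x * 32767)`, so a write-read cycle is
#' bit-exact for already-quantized signals.
#'
#' @param samples Numeric vector (mono) or an `audio_recording`.
#' @param path Output file path.
#' @param sample_rate Sampling rate in Hz (ignored when `samples` is an
#'   `audio_recording`).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 192000) {
  if (inherits(samples, "audio_recording")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  if (any(abs(samples) > 1)) {
    warn("samples outside [-1, 1] clipped on write")
    samples <- pmin(1, pmax(-1, samples))
  }
  ints <- as.integer(round(samples * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- 2L * length(ints)
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_size, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

#' Min-max normalization to the unit interval
#'
#' Affine map `(x - min) / (max - min)` so that the output spans exactly
#' \[0, 1\]. Applied once per recording before segmentation; note that on
#' bipolar audio this leaves the zero level at ~0.5, which is harmless here
#' because the spectrogram band starts at 3 kHz and the DC bin is discarded.
#'
#' @param x Numeric vector; must not be constant.
#' @return Numeric vector with `min(x) == 0` and `max(x) == 1`.
#' @examples
#' minmax_normalize(c(-1, 0, 1))
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) abort("cannot normalize an empty vector")
  r <- range(x)
  if (r[1] == r[2]) abort("cannot min-max normalize a constant signal (zero range)")
  (x - r[1]) / (r[2] - r[1])
}

#' Read an Audacity label track
#'
#' Parses the tab-separated label-track text format
#' (`start<TAB>end<TAB>label`, seconds). Label strings are mapped to class
#' codes through an alias table; unknown labels are kept with an `NA` code
#' and reported so the caller can extend the table.
#'
#' @param path Path to the label file.
#' @param aliases Alias table as returned by [label_aliases()].
#' @return A tibble of annotation events with columns `start`, `end`,
#'   `label`, `class` (integer code or `NA`), sorted by `start`.
#' @export
read_label_track <- function(path, aliases = label_aliases()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(start = numeric(), end = numeric(),
                          label = character(), class = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad_fields <- which(lengths(parts) < 3)
  if (length(bad_fields)) {
    abort(sprintf("label track %s: line(s) %s do not have 3 tab-separated fields",
                  path, paste(bad_fields, collapse = ", ")))
  }
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1)))
  end   <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  label <- vapply(parts, `[[`, "", 3)
  if (anyNA(start) || anyNA(end)) {
    abort(sprintf("label track %s: unparseable start/end time on line(s) %s",
                  path, paste(which(is.na(start) | is.na(end)), collapse = ", ")))
  }
  ok <- end > start & start >= 0
  if (any(!ok)) {
    warn(sprintf("label track %s: dropped line(s) %s with end <= start (or negative start)",
                 path, paste(which(!ok), collapse = ", ")))
  }
  ev <- tibble::tibble(start = start[ok], end = end[ok], label = label[ok]) |>
    dplyr::mutate(class = aliases$code[match(tolower(.data$label), aliases$alias)]) |>
    dplyr::arrange(.data$start)
  if (anyNA(ev$class)) {
    warn(sprintf("unknown label(s) kept with NA class: %s",
                 paste(unique(ev$label[is.na(ev$class)]), collapse = ", ")))
  }
  ev
}

#' Write an Audacity label track
#'
#' One event per line, `start<TAB>end<TAB>label`, seconds with 6 decimals,
#' UTF-8, LF line endings — readable by Audacity's "Import Labels".
#'
#' @param events Tibble with columns `start`, `end` and either `label` or
#'   `class` (codes are written as canonical class names).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_label_track <- function(events, path) {
  stopifnot(all(c("start", "end") %in% names(events)))
  lab <- if ("label" %in% names(events)) {
    as.character(events$label)
  } else {
    class_name(events$class)
  }
  lines <- sprintf("%.6f\t%.6f\t%s", events$start, events$end, lab)
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
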