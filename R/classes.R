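#' The five vocalization classes
#'
#' The classifier distinguishes four bottlenose-dolphin vocalization types
#' plus ambient noise. Class codes follow the labeling convention used
#' throughout the package: 0 noise, 1 whistle, 2 echolocation click,
#' 3 burst pulse, 4 feeding buzz.
#'
#' @return A tibble with columns `code` (integer 0-4) and `name` (character).
#' @examples
#' voc_classes()
#' @export
voc_classes <- function() {
  tibble::tibble(
    code = 0:4,
    name = c("noise", "whistle", "echolocation_click", "burst_pulse",
             "feeding_buzz")
  )
}

#' Default label alias table
#'
#' Annotation files written by different operators use different label
#' strings. This table maps common spellings onto the numeric class codes;
#' pass a modified copy to [read_label_track()] to accommodate local
#' conventions.
#'
#' @return A tibble with columns `alias` and `code`.
#' @export
label_aliases <- function() {
  tibble::tibble(
    alias = c("0", "noise", "n", "ambient",
              "1", "whistle", "w", "whistles",
              "2", "click", "clicks", "echolocation_click", "click_train", "c",
              "3", "burst", "burst_pulse", "burst_pulse_sound", "bp",
              "4", "buzz", "feeding_buzz", "fb"),
    code = c(rep(0L, 4), rep(1L, 4), rep(2L, 6), rep(3L, 5), rep(4L, 4))
  )
}

#' Convert between class codes and names
#'
#' @param code Integer vector of class codes in 0-4.
#' @param name Character vector of class names.
#' @return `class_name()` returns the canonical name for each code;
#'   `class_code()` the code for each canonical name.
#' @examples
#' class_name(c(0, 4))
#' class_code("whistle")
#' @export
class_name <- function(code) {
  stopifnot(all(code %in% 0:4))
  voc_classes()$name[match(as.integer(code), voc_classes()$code)]
}

#' @rdname class_name
#' @export
class_code <- function(name) {
  idx <- match(name, voc_classes()$name)
  if (anyNA(idx)) {
    abort(paste0("unknown class name(s): ",
                 paste(name[is.na(idx)], collapse = ", ")))
  }
  voc_classes()$code[idx]
}

check_class_codes <- function(labels, arg = "labels") {
  if (!all(labels %in% 0:4)) {
    abort(sprintf("`%s` must contain class codes in 0..4", arg))
  }
  invisible(as.integer(labels))
}
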