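#' Construct an extended directional Sobel kernel
#'
#' Builds the separable extended-Sobel family: the weight matrix is the
#' outer product of a binomial (Pascal-row) smoothing vector along the
#' non-derivative axis and a smoothed central-difference vector along the
#' derivative axis, the latter obtained by convolving `c(1, 0, -1)` with
#' `(size - 3)` copies of `c(1, 1)`. Size 3 with a time derivative is the
#' canonical 3x3 Sobel.
#'
#' Axis naming follows the image layout (rows = frequency, columns = time):
#' a *time*-derivative kernel differentiates along columns, responding to
#' time-localized vertical streaks (clicks) and annihilating structures
#' constant in time (horizontal bands); a *frequency*-derivative kernel does
#' the converse. In the field's informal naming, the frequency-derivative
#' kernel is the "vertical Sobel" applied to whistle and noise images, and
#' the time-derivative kernel is the "horizontal Sobel" applied to the
#' impulsive classes — see [filter_policy()].
#'
#' @param size Odd kernel size between 3 and 11.
#' @param derivative_axis `"time"` or `"frequency"`.
#' @return An `edge_kernel`: list with `size`, `derivative_axis` and the
#'   `weights` matrix (weights sum to zero; transposing swaps the axis).
#' @examples
#' make_kernel(3, "time")$weights
#' @export
make_kernel <- function(size, derivative_axis = c("time", "frequency")) {
  derivative_axis <- match.arg(derivative_axis)
  if (length(size) != 1 || is.na(size) || size %% 2 == 0 ||
      size < 3 || size > 11) {
    abort("kernel size must be an odd integer between 3 and 11")
  }
  size <- as.integer(size)
  deriv <- c(1, 0, -1)
  for (i in seq_len(size - 3L)) deriv <- convolve_full(deriv, c(1, 1))
  smooth <- choose(size - 1L, 0:(size - 1L))
  if (derivative_axis == "time") {
    row_factor <- smooth        # smooth over frequency rows
    col_factor <- deriv         # differentiate along time columns
  } else {
    row_factor <- deriv
    col_factor <- smooth
  }
  structure(list(size = size, derivative_axis = derivative_axis,
                 weights = row_factor %o% col_factor,
                 row_factor = row_factor, col_factor = col_factor),
            class = "edge_kernel")
}

convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' @export
print.edge_kernel <- function(x, ...) {
  cat(sprintf("<edge_kernel> %dx%d, %s-derivative\n", x$size, x$size,
              x$derivative_axis))
  print(x$weights)
  invisible(x)
}

#' @export
t.edge_kernel <- function(x) {
  make_kernel(x$size,
              if (x$derivative_axis == "time") "frequency" else "time")
}

#' Class-to-direction filter policy
#'
#' Maps each vocalization class to the derivative axis of the Sobel kernel
#' applied to its spectrograms: whistles and noise get the
#' frequency-derivative ("vertical") filter, which suppresses broadband
#' vertical streaks while preserving horizontal whistle contours; the three
#' impulsive classes (clicks, burst pulses, feeding buzzes) get the
#' time-derivative ("horizontal") filter, which cancels stationary
#' horizontal bands and keeps the vertical click streaks.
#'
#' @return Named character vector indexed by class code ("0".."4").
#' @export
filter_policy <- function() {
  c(`0` = "frequency", `1` = "frequency",
    `2` = "time", `3` = "time", `4` = "time")
}

#' Apply an edge kernel to a spectrogram image
#'
#' Two-dimensional cross-correlation with reflect padding (same-size
#' output), followed by absolute value and a per-image min-max rescale so
#' the result stays a valid \[0,1\] classifier input. A constant image has
#' an all-zero response; its degenerate rescale is defined as uniform 0.5.
#'
#' @param image A `spectrogram_image` or plain numeric matrix.
#' @param kernel An [make_kernel()] result.
#' @return Filtered image of the same class and shape as `image`.
#' @export
apply_kernel <- function(image, kernel) {
  stopifnot(inherits(kernel, "edge_kernel"))
  m <- unclass(image)
  stopifnot(is.matrix(m), is.numeric(m))
  if (min(dim(m)) < kernel$size) {
    abort("image smaller than the kernel")
  }
  out <- abs(xcorr2_sep_reflect(m, kernel$row_factor, kernel$col_factor))
  r <- range(out)
  out <- if (r[2] - r[1] < 1e-300) {
    matrix(0.5, nrow(m), ncol(m))
  } else {
    (out - r[1]) / (r[2] - r[1])
  }
  if (inherits(image, "spectrogram_image")) {
    new_spectrogram_image(out, attr(image, "freq_axis"),
                          attr(image, "time_axis"),
                          attr(image, "class_code"))
  } else {
    out
  }
}

#' Filter a spectrogram according to its class
#'
#' The class-conditional edge filtering step: picks the kernel direction
#' from the [filter_policy()] for the image's (known) class and applies it
#' with [apply_kernel()]. During training and evaluation the true label is
#' available ("filter selection performed manually"); at deployment the
#' class is unknown and a direction `override` must be supplied (or
#' `"none"` to skip filtering) — the choice of direction is inherently
#' label-dependent and this function refuses to guess.
#'
#' @param image A `spectrogram_image` or numeric matrix.
#' @param class Class code 0-4, or `NULL` in deployment mode.
#' @param size Kernel size (default 7).
#' @param policy Named direction vector, see [filter_policy()].
#' @param override Optional direction: `"time"`, `"frequency"` or `"none"`.
#' @return Filtered image.
#' @export
filter_for_class <- function(image, class = NULL, size = 7,
                             policy = filter_policy(), override = NULL) {
  if (!is.null(override)) {
    override <- match.arg(override, c("time", "frequency", "none"))
    if (override == "none") return(image)
    return(apply_kernel(image, make_kernel(size, override)))
  }
  if (is.null(class) || is.na(class)) {
    abort(paste("filter direction depends on the class label;",
                "in deployment mode pass `override = \"time\"`,",
                "`\"frequency\"` or `\"none\"`"))
  }
  class <- check_class_codes(class, "class")
  apply_kernel(image, make_kernel(size, policy[[as.character(class)]]))
}
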