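#' CNN architecture configuration
#'
#' The default architecture is three convolutional layers of 32, 64 and 128
#' filters with 6x3 kernels (6 rows along frequency, 3 columns along time)
#' and ReLU activation, each followed by 2x2 max pooling, then a flatten, a
#' dense layer of 128 ReLU units, and a softmax output over the five
#' classes. Convolutions are same-padded, so each block halves both spatial
#' dimensions (floor): 150x300 -> 75x150 -> 37x75 -> 18x37.
#'
#' @param conv_filters Integer vector of filters per convolutional layer.
#' @param conv_kernel Kernel size `c(rows, cols)` = (frequency, time).
#' @param pool Max-pooling window (square).
#' @param dense_units Units in the hidden dense layer.
#' @param n_classes Number of output classes.
#' @param input_shape Image size `c(rows, cols)` fed to the network.
#' @return A list of class `model_config`.
#' @seealso [simplified_model_config()] for the sensitivity-study variant.
#' @export
model_config <- function(conv_filters = c(32, 64, 128), conv_kernel = c(6, 3),
                         pool = 2, dense_units = 128, n_classes = 5,
                         input_shape = c(150, 300)) {
  stopifnot(length(conv_filters) >= 1, all(conv_filters >= 1),
            length(conv_kernel) == 2, pool >= 1, dense_units >= 1,
            n_classes >= 2, length(input_shape) == 2)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool = as.integer(pool),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape)),
            class = "model_config")
}

#' Simplified architecture for the kernel-size sensitivity study
#'
#' Two convolutional layers of 16 and 32 filters and a dense layer of 64
#' units, used for the binary whistle-vs-rest experiment.
#'
#' @inheritParams model_config
#' @return A `model_config`.
#' @export
simplified_model_config <- function(input_shape = c(150, 300), n_classes = 2) {
  model_config(conv_filters = c(16, 32), dense_units = 64,
               n_classes = n_classes, input_shape = input_shape)
}

#' Training configuration
#'
#' Standard small-CNN training setup: categorical cross-entropy loss, Adam
#' optimizer, minibatches, a held-out validation slice for early stopping
#' with best-weight restore. A fixed seed makes initialization, the
#' validation split and batch shuffling reproducible.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param validation_fraction Fraction of the training set held out for
#'   early stopping (0 disables early stopping).
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 32,
                         max_epochs = 30, patience = 3,
                         validation_fraction = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Spatial dimensions through the convolution/pooling stack
#'
#' @param config A [model_config()].
#' @return Tibble with one row per block: `stage`, `height`, `width`,
#'   `channels` (dimensions after that block's pooling).
#' @examples
#' conv_stack_dims(model_config())
#' @export
conv_stack_dims <- function(config) {
  h <- config$input_shape[1]; w <- config$input_shape[2]
  rows <- purrr::imap(config$conv_filters, function(f, l) {
    h <<- h %/% config$pool
    w <<- w %/% config$pool
    tibble::tibble(stage = l, height = h, width = w, channels = f)
  })
  dplyr::bind_rows(rows)
}

cnn_conf <- function(config) {
  list(kh = config$conv_kernel[1], kw = config$conv_kernel[2],
       pool = config$pool, dense_units = config$dense_units,
       n_classes = config$n_classes, input_h = config$input_shape[1],
       input_w = config$input_shape[2], conv_filters = config$conv_filters)
}

#' Build (initialize) a CNN classifier
#'
#' Allocates the network weights: seeded He-normal initialization for the
#' convolutional and hidden dense layers, zeros for the softmax output
#' layer (training starts from uniform class probabilities). Images in
#' \[0, 1\] are internally centered to \[-1, 1\] by the engine. Errors if
#' the input image is too small for the pooling stack and reports the
#' minimum feasible size.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return An object of class `whistlenet_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  min_size <- config$pool^length(config$conv_filters)
  if (any(config$input_shape < min_size)) {
    abort(sprintf("input shape %dx%d too small for %d pooling stages; minimum is %dx%d",
                  config$input_shape[1], config$input_shape[2],
                  length(config$conv_filters), min_size, min_size))
  }
  dims <- conv_stack_dims(config)
  flat <- dims$height[nrow(dims)] * dims$width[nrow(dims)] *
    dims$channels[nrow(dims)]
  kh <- config$conv_kernel[1]; kw <- config$conv_kernel[2]

  withr::local_seed(seed)
  cin <- 1L
  conv <- purrr::map(config$conv_filters, function(cout) {
    fan_in <- kh * kw * cin
    W <- array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / fan_in)),
               dim = c(kh, kw, cin, cout))
    cin <<- cout
    list(W = W, b = numeric(cout))
  })
  weights <- list(
    conv = conv,
    dense1 = list(W = matrix(rnorm(config$dense_units * flat,
                                   sd = sqrt(2 / flat)),
                             config$dense_units, flat),
                  b = numeric(config$dense_units)),
    # zero-initialized output layer: training starts from uniform class
    # probabilities, which stabilizes the first epochs
    dense2 = list(W = matrix(0, config$n_classes, config$dense_units),
                  b = numeric(config$n_classes))
  )
  structure(list(config = config, weights = weights, trained = FALSE,
                 history = NULL, init_seed = as.integer(seed)),
            class = "whistlenet_model")
}

#' @export
print.whistlenet_model <- function(x, ...) {
  n_par <- sum(vapply(x$weights$conv,
                      function(l) length(l$W) + length(l$b), numeric(1))) +
    length(x$weights$dense1$W) + length(x$weights$dense1$b) +
    length(x$weights$dense2$W) + length(x$weights$dense2$b)
  cat(sprintf("<whistlenet_model> %s, input %dx%d, %s classes, %s parameters (%s)\n",
              paste(x$config$conv_filters, collapse = "-"),
              x$config$input_shape[1], x$config$input_shape[2],
              x$config$n_classes, format(n_par, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# images: list of matrices or array (H, W, N) -> numeric array H x W x N
as_image_array <- function(images, shape) {
  if (is.list(images)) {
    images <- lapply(images, unclass)
    arr <- array(0, dim = c(shape[1], shape[2], length(images)))
    for (i in seq_along(images)) {
      m <- images[[i]]
      if (!all(dim(m) == shape)) {
        abort(sprintf("image %d is %dx%d, expected %dx%d", i,
                      nrow(m), ncol(m), shape[1], shape[2]))
      }
      arr[, , i] <- m
    }
    arr
  } else {
    d <- dim(images)
    if (length(d) == 2) d <- c(d, 1L)
    if (d[1] != shape[1] || d[2] != shape[2]) {
      abort(sprintf("image array is %dx%d, expected %dx%d",
                    d[1], d[2], shape[1], shape[2]))
    }
    array(as.numeric(images), dim = d)
  }
}

#' Train a CNN classifier
#'
#' Minimizes categorical cross-entropy with Adam on minibatches. A
#' stratified-by-shuffle validation slice (`validation_fraction`) is held
#' out for early stopping; training stops after `patience` epochs without
#' validation-loss improvement and the best weights are restored.
#'
#' @param model A [build_model()] result.
#' @param images List of image matrices or an array `H x W x N`.
#' @param labels Integer class codes `0 .. n_classes-1`.
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return The fitted `whistlenet_model`, with a `history` tibble
#'   (`epoch`, `loss`, `accuracy`, `val_loss`, `val_accuracy`).
#' @export
train_model <- function(model, images, labels, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "whistlenet_model"),
            inherits(config, "train_config"))
  arr <- as_image_array(images, model$config$input_shape)
  n <- dim(arr)[3]
  labels <- as.integer(labels)
  if (n == 0 || length(labels) == 0) abort("empty training set")
  if (length(labels) != n) abort("length(labels) must match the number of images")
  if (any(labels < 0 | labels >= model$config$n_classes)) {
    abort(sprintf("labels must be in 0..%d", model$config$n_classes - 1))
  }
  if (length(unique(labels)) < 2) {
    abort("training set contains a single class; softmax/cross-entropy is degenerate")
  }

  n_val <- floor(config$validation_fraction * n)
  withr::local_seed(config$seed)
  ord <- sample.int(n)
  if (n_val > 0) {
    val_idx <- ord[seq_len(n_val)]
    tr_idx <- ord[-seq_len(n_val)]
    if (length(unique(labels[tr_idx])) < 2) {
      abort("training slice left with a single class after the validation split")
    }
    Xval <- arr[, , val_idx, drop = FALSE]
    yval <- labels[val_idx]
  } else {
    tr_idx <- ord
    Xval <- NULL; yval <- NULL
  }

  fit <- cnn_train(model$weights, cnn_conf(model$config),
                   arr[, , tr_idx, drop = FALSE], labels[tr_idx],
                   Xval, yval,
                   config$learning_rate, config$batch_size,
                   config$max_epochs, config$patience, config$seed,
                   verbose)
  model$weights <- fit$weights
  model$trained <- TRUE
  model$train_config <- config
  model$history <- tibble::tibble(
    epoch = as.integer(fit$epoch), loss = fit$loss, accuracy = fit$accuracy,
    val_loss = fit$val_loss, val_accuracy = fit$val_accuracy)
  model
}

#' Predict class probabilities and labels
#'
#' @param object A `whistlenet_model`.
#' @param images List of image matrices or an array `H x W x N` matching
#'   the model's input shape.
#' @param ... Unused.
#' @return A tibble with one row per image: probability columns `p_0` ..
#'   `p_{K-1}` (each row sums to 1) and `label`, the argmax class with
#'   lowest-index tie-break.
#' @export
predict.whistlenet_model <- function(object, images, ...) {
  arr <- as_image_array(images, object$config$input_shape)
  n <- dim(arr)[3]
  probs <- cnn_forward_probs(object$weights, cnn_conf(object$config), arr, n)
  colnames(probs) <- paste0("p_", seq_len(object$config$n_classes) - 1)
  out <- tibble::as_tibble(probs)
  out$label <- max.col(probs, ties.method = "first") - 1L
  out
}

#' @export
tidy.whistlenet_model <- function(x, ...) {
  if (is.null(x$history)) {
    abort("model has no training history; call train_model() first")
  }
  x$history
}

#' @export
glance.whistlenet_model <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = if (is.null(h)) 0L else nrow(h),
    final_loss = if (is.null(h)) NA_real_ else h$loss[nrow(h)],
    final_accuracy = if (is.null(h)) NA_real_ else h$accuracy[nrow(h)],
    best_val_loss = if (is.null(h)) NA_real_ else suppressWarnings(min(h$val_loss, na.rm = TRUE)),
    trained = x$trained
  )
}

#' Save / load a fitted model
#'
#' The weights go to an RDS file next to a small JSON manifest describing
#' the architecture and training configuration.
#'
#' @param model A `whistlenet_model`.
#' @param path Output `.rds` path (the manifest gets the same path with a
#'   `.json` extension).
#' @return `path`, invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "whistlenet_model"))
  saveRDS(model, path)
  manifest <- list(config = unclass(model$config),
                   train_config = if (!is.null(model$train_config))
                     unclass(model$train_config),
                   trained = model$trained)
  jsonlite::write_json(manifest, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "whistlenet_model"))
  model
}
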