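#' Build cross-validation folds
#'
#' Partitions `n_items` indices into `n_folds` test folds of size
#' `floor(N/k)` or `ceiling(N/k)`. With `stratify_labels`, members of each
#' class are spread across folds as evenly as possible (rotating the
#' starting fold between classes so overall fold sizes stay balanced);
#' a class with 420 members lands exactly 42 per fold.
#'
#' @param n_items Number of items.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @param stratify_labels Optional label vector of length `n_items`.
#' @return Tibble with `fold_id` (0-based) and list-columns
#'   `train_indices`, `test_indices` (1-based, disjoint, test folds
#'   partition `1:n_items`).
#' @export
make_folds <- function(n_items, n_folds = 10, seed = 1L,
                       stratify_labels = NULL) {
  if (n_folds > n_items) {
    abort(sprintf("cannot make %d folds from %d items", n_folds, n_items))
  }
  withr::local_seed(seed)
  assignment <- integer(n_items)
  if (is.null(stratify_labels)) {
    assignment[sample.int(n_items)] <- rep_len(seq_len(n_folds), n_items)
  } else {
    stopifnot(length(stratify_labels) == n_items)
    offset <- 0L
    for (lv in unique(stratify_labels)) {
      members <- which(stratify_labels == lv)
      members <- members[sample.int(length(members))]
      assignment[members] <- ((offset + seq_along(members) - 1L) %% n_folds) + 1L
      offset <- (offset + length(members)) %% n_folds
    }
  }
  purrr::map(seq_len(n_folds), function(k) {
    tibble::tibble(fold_id = k - 1L,
                   train_indices = list(which(assignment != k)),
                   test_indices = list(which(assignment == k)))
  }) |> dplyr::bind_rows()
}

#' Confusion matrix from label vectors
#'
#' @param true_labels,predicted_labels Equal-length integer vectors of
#'   class codes.
#' @param n_classes Number of classes (default 5).
#' @return A `confusion_matrix`: integer matrix with rows = true class,
#'   columns = predicted class, dimnames the class codes.
#' @export
confusion_from_predictions <- function(true_labels, predicted_labels,
                                       n_classes = 5) {
  stopifnot(length(true_labels) == length(predicted_labels))
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (any(c(true_labels, predicted_labels) < 0) ||
      any(c(true_labels, predicted_labels) >= n_classes)) {
    abort(sprintf("labels must be in 0..%d", n_classes - 1))
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = 0:(n_classes - 1),
                               predicted = 0:(n_classes - 1)))
  for (i in seq_along(true_labels)) {
    cm[true_labels[i] + 1L, predicted_labels[i] + 1L] <-
      cm[true_labels[i] + 1L, predicted_labels[i] + 1L] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Row-normalize a confusion matrix
#'
#' @param cm A confusion matrix (counts).
#' @return Matrix whose non-empty rows sum to 1.
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}

#' Per-class and aggregate metrics from a confusion matrix
#'
#' For each class `c` taken one-vs-rest: precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, accuracy `(TP+TN)/N` and F1 (harmonic mean of precision
#' and recall), all in percent. Ratios with a zero denominator are
#' reported as 0 and flagged in `undefined`. The aggregate is the
#' unweighted mean and SD over classes (macro), plus the overall
#' micro-accuracy `trace/N`.
#'
#' @param cm A [confusion_from_predictions()] result (or any square count
#'   matrix).
#' @return A `metrics_report`: list with `per_class` tibble (`class`,
#'   `accuracy`, `precision`, `recall`, `f1`, `undefined`), `macro`
#'   tibble (`metric`, `mean`, `sd`) and `micro_accuracy` (percent).
#' @examples
#' cm <- confusion_from_predictions(c(1, 1, 2), c(1, 2, 2), n_classes = 3)
#' metrics_from_confusion(cm)$per_class
#' @export
metrics_from_confusion <- function(cm) {
  cm <- unclass(cm)
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  k <- nrow(cm)
  safe_ratio <- function(num, den) {
    if (den == 0) c(0, TRUE) else c(num / den, FALSE)
  }
  per_class <- purrr::map(seq_len(k), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    tn <- total - tp - fp - fn
    p <- safe_ratio(tp, tp + fp)
    r <- safe_ratio(tp, tp + fn)
    f1 <- if (p[1] + r[1] == 0) c(0, TRUE) else
      c(2 * p[1] * r[1] / (p[1] + r[1]), FALSE)
    flagged <- as.logical(p[2] | r[2] | f1[2])
    tibble::tibble(
      class = i - 1L,
      accuracy = 100 * (tp + tn) / total,
      precision = 100 * p[1], recall = 100 * r[1], f1 = 100 * f1[1],
      undefined = flagged)
  }) |> dplyr::bind_rows()
  macro <- per_class |>
    tidyr::pivot_longer(c("accuracy", "precision", "recall", "f1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$metric, c("accuracy", "precision", "recall", "f1")))
  structure(list(per_class = per_class, macro = macro,
                 micro_accuracy = 100 * sum(diag(cm)) / total,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class)
  cat(sprintf("micro accuracy: %.1f%%\n", x$micro_accuracy))
  invisible(x)
}

#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @export
glance.metrics_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$macro, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(tibble::tibble(micro_accuracy = x$micro_accuracy), wide)
}

#' Plot a confusion matrix heatmap
#'
#' @param object A `confusion_matrix`.
#' @param normalize Row-normalize before plotting (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, normalize = TRUE, ...) {
  m <- if (normalize) normalize_confusion(object) else unclass(object)
  df <- tibble::as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("true", "predicted", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       color = "white", size = 3) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_viridis_c(limits = if (normalize) c(0, 1) else NULL) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = if (normalize) "rate" else "count") +
    ggplot2::theme_minimal()
}

# Default learner: builds and trains a CNN, returns a predictor closure.
cnn_learner <- function(model_config, train_config) {
  force(model_config); force(train_config)
  function(train_images, train_labels, test_images, test_labels) {
    model <- build_model(model_config, seed = train_config$seed)
    model <- train_model(model, train_images, train_labels, train_config)
    predict(model, test_images)$label
  }
}

#' Truth-echoing stub learner
#'
#' A degenerate "classifier" that returns the true test labels. Used to
#' validate the cross-validation bookkeeping (a perfect classifier must
#' score 100% everywhere); it learns nothing.
#'
#' @return A learner function usable as the `learner` argument of
#'   [run_cross_validation()].
#' @export
oracle_learner <- function() {
  function(train_images, train_labels, test_images, test_labels) {
    test_labels
  }
}

#' Run stratified k-fold cross-validation
#'
#' The full evaluation protocol: images are edge-filtered according to
#' their class (label-aware filtering, as in training-set preparation),
#' folds are built stratified by class, and for each fold a fresh
#' classifier is trained on the other nine folds and evaluated on the
#' held-out one — test images are never seen in training, which is
#' asserted on every fold. Performances are reported per fold and as
#' mean +/- SD, together with the entrywise mean of the row-normalized
#' confusion matrices.
#'
#' @param images List of image matrices or array `H x W x N` (raw,
#'   unfiltered spectrograms unless `sobel_size` is `NULL`).
#' @param labels Integer class codes.
#' @param model_config,train_config Architecture and training settings.
#' @param sobel_size Kernel size for the class-conditional edge filtering,
#'   or `NULL` if `images` are already filtered.
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param learner Function `(train_images, train_labels, test_images,
#'   test_labels) -> predicted labels`; defaults to the CNN. The test
#'   labels are passed only for stubs such as [oracle_learner()].
#' @param verbose Print per-fold progress.
#' @param verbose Print per-fold progress.
#' @return A `cv_result`: list with `fold_metrics` (per fold x class),
#'   `fold_summary` (per fold aggregates), `summary` (mean +/- SD over
#'   folds), `mean_confusion`, `folds`, and the configurations.
#' @export
run_cross_validation <- function(images, labels,
                                 model_config = whistlenet::model_config(),
                                 train_config = whistlenet::train_config(),
                                 sobel_size = 7, n_folds = 10, seed = 1L,
                                 learner = NULL, verbose = FALSE) {
  labels <- check_class_codes(labels)
  if (length(unique(labels)) < model_config$n_classes) {
    abort("every class must be present in the dataset")
  }
  arr <- as_image_array(images, model_config$input_shape)
  n <- dim(arr)[3]
  stopifnot(length(labels) == n)
  if (!is.null(sobel_size)) {
    arr <- filter_image_array(arr, labels, sobel_size)
  }
  learner <- learner %||% cnn_learner(model_config, train_config)
  folds <- make_folds(n, n_folds, seed = seed, stratify_labels = labels)

  fold_rows <- list()
  fold_sum <- list()
  confusions <- list()
  for (k in seq_len(nrow(folds))) {
    tr <- folds$train_indices[[k]]
    te <- folds$test_indices[[k]]
    stopifnot(length(intersect(tr, te)) == 0)   # no leakage, ever
    if (length(unique(labels[te])) < model_config$n_classes) {
      warn(sprintf("fold %d is missing at least one class; its per-class metrics are flagged",
                   folds$fold_id[k]))
    }
    pred <- learner(arr[, , tr, drop = FALSE], labels[tr],
                    arr[, , te, drop = FALSE], labels[te])
    cm <- confusion_from_predictions(labels[te], pred,
                                     n_classes = model_config$n_classes)
    rep <- metrics_from_confusion(cm)
    confusions[[k]] <- normalize_confusion(cm)
    fold_rows[[k]] <- dplyr::mutate(rep$per_class,
                                    fold_id = folds$fold_id[k],
                                    .before = 1)
    fold_sum[[k]] <- tibble::tibble(
      fold_id = folds$fold_id[k],
      micro_accuracy = rep$micro_accuracy,
      macro_precision = rep$macro$mean[rep$macro$metric == "precision"],
      macro_recall = rep$macro$mean[rep$macro$metric == "recall"],
      macro_f1 = rep$macro$mean[rep$macro$metric == "f1"])
    if (verbose) {
      inform(sprintf("fold %d: micro accuracy %.1f%%, macro F1 %.1f%%",
                     folds$fold_id[k], rep$micro_accuracy,
                     fold_sum[[k]]$macro_f1))
    }
  }
  fold_metrics <- dplyr::bind_rows(fold_rows)
  fold_summary <- dplyr::bind_rows(fold_sum)
  summary <- fold_summary |>
    tidyr::pivot_longer(-"fold_id", names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  mean_confusion <- Reduce(`+`, confusions) / length(confusions)
  structure(list(fold_metrics = fold_metrics, fold_summary = fold_summary,
                 summary = summary, mean_confusion = mean_confusion,
                 folds = folds, model_config = model_config,
                 train_config = train_config, sobel_size = sobel_size,
                 seed = seed),
            class = "cv_result")
}

filter_image_array <- function(arr, labels, size) {
  out <- array(0, dim = dim(arr))
  for (i in seq_len(dim(arr)[3])) {
    out[, , i] <- unclass(filter_for_class(arr[, , i], labels[i], size = size))
  }
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, sobel size %s\n",
              nrow(x$fold_summary),
              ifelse(is.null(x$sobel_size), "none", x$sobel_size)))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$fold_metrics

#' @export
glance.cv_result <- function(x, ...) {
  x$summary |>
    tidyr::pivot_wider(names_from = "metric", values_from = c("mean", "sd"))
}

#' Plot per-fold cross-validation metrics
#'
#' Micro accuracy and macro-averaged precision, recall and F1 for every
#' fold, in the style of a per-fold performance chart.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$fold_summary, -"fold_id",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$fold_id), .data$value,
                                   color = .data$metric,
                                   group = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "fold", y = "percent", color = NULL) +
    ggplot2::theme_minimal()
}

#' Single-split holdout evaluation
#'
#' Stratified train/validation/test split (default 65/10/25), label-aware
#' edge filtering, one model trained with early stopping on the validation
#' slice, and a [metrics_from_confusion()] report on the held-out test
#' images. The lighter-weight companion to [run_cross_validation()] for
#' end-to-end experiments.
#'
#' @inheritParams run_cross_validation
#' @param split Train/validation/test fractions, summing to 1.
#' @return A list with `report` (a `metrics_report`), the fitted `model`
#'   and the `indices` of the split.
#' @export
holdout_evaluation <- function(images, labels,
                               model_config = whistlenet::model_config(),
                               train_config = whistlenet::train_config(),
                               split = c(0.65, 0.10, 0.25),
                               sobel_size = 7, seed = 1L) {
  labels <- check_class_codes(labels)
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-9)
  arr <- as_image_array(images, model_config$input_shape)
  stopifnot(length(labels) == dim(arr)[3])
  if (!is.null(sobel_size)) {
    arr <- filter_image_array(arr, labels, sobel_size)
  }
  withr::local_seed(seed)
  idx <- split_stratified(labels, split)
  model <- build_model(model_config, seed = train_config$seed)
  model <- train_model_with_validation(
    model, arr[, , idx$train, drop = FALSE], labels[idx$train],
    arr[, , idx$val, drop = FALSE], labels[idx$val], train_config)
  pred <- predict(model, arr[, , idx$test, drop = FALSE])$label
  cm <- confusion_from_predictions(labels[idx$test], pred,
                                   n_classes = model_config$n_classes)
  list(report = metrics_from_confusion(cm), model = model, indices = idx)
}

#' Kernel-size sensitivity experiment
#'
#' Binary whistle-vs-rest experiment: for each Sobel kernel size the
#' images are filtered class-conditionally at that size, a simplified
#' network is trained on a single stratified train/validation/test split
#' (default 65/10/25, identical partition across sizes) and test-set
#' accuracy, precision, recall and F1 for the whistle class are tabulated.
#'
#' @param images Raw image list or array.
#' @param binary_labels 0/1 vector (1 = whistle).
#' @param filter_classes Original multiclass codes used to pick each
#'   image's filter direction; defaults to `binary_labels` (whistle vs
#'   noise-like filtering).
#' @param sizes Odd kernel sizes to try (default 3, 5, 7, 9, 11).
#' @param split Train/validation/test fractions, summing to 1.
#' @param model_config Architecture (default [simplified_model_config()]
#'   at the image size).
#' @param train_config Training settings; the validation slice given by
#'   `split[2]` overrides `validation_fraction`.
#' @param seed Seed for the split.
#' @param verbose Print per-size progress.
#' @return A `kernel_sweep`: tibble with one row per size (`size`,
#'   `accuracy`, `precision`, `recall`, `f1`, percentages) plus a
#'   `spread` attribute (max-min per metric).
#' @export
kernel_size_sweep <- function(images, binary_labels, filter_classes = NULL,
                              sizes = c(3, 5, 7, 9, 11),
                              split = c(0.65, 0.10, 0.25),
                              model_config = NULL, train_config = NULL,
                              seed = 1L, verbose = FALSE) {
  if (any(sizes %% 2 == 0 | sizes < 3 | sizes > 11)) {
    abort("kernel sizes must be odd integers between 3 and 11")
  }
  stopifnot(length(split) == 3, abs(sum(split) - 1) < 1e-9)
  binary_labels <- as.integer(binary_labels)
  stopifnot(all(binary_labels %in% c(0L, 1L)))
  filter_classes <- filter_classes %||% binary_labels
  arr0 <- as_image_array(images, dim_of_images(images))
  n <- dim(arr0)[3]
  mc <- model_config %||%
    simplified_model_config(input_shape = dim(arr0)[1:2])
  tc0 <- train_config %||% whistlenet::train_config()

  # one stratified split shared by all kernel sizes
  withr::local_seed(seed)
  idx <- split_stratified(binary_labels, split)

  rows <- purrr::map(sizes, function(sz) {
    arr <- filter_image_array(arr0, filter_classes, sz)
    model <- build_model(mc, seed = tc0$seed)
    tc <- tc0
    tc$validation_fraction <- 0     # explicit validation set below
    model <- train_model_with_validation(
      model, arr[, , idx$train, drop = FALSE], binary_labels[idx$train],
      arr[, , idx$val, drop = FALSE], binary_labels[idx$val], tc)
    pred <- predict(model, arr[, , idx$test, drop = FALSE])$label
    cm <- confusion_from_predictions(binary_labels[idx$test], pred,
                                     n_classes = 2)
    rep <- metrics_from_confusion(cm)
    pos <- rep$per_class[rep$per_class$class == 1L, ]
    if (verbose) {
      inform(sprintf("size %d: accuracy %.1f%%, F1 %.1f%%",
                     sz, rep$micro_accuracy, pos$f1))
    }
    tibble::tibble(size = sz, accuracy = rep$micro_accuracy,
                   precision = pos$precision, recall = pos$recall,
                   f1 = pos$f1)
  })
  out <- dplyr::bind_rows(rows)
  spread <- out |>
    tidyr::pivot_longer(-"size", names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(spread = max(.data$value) - min(.data$value),
                     .groups = "drop")
  structure(out, spread = spread, class = c("kernel_sweep", class(out)))
}

dim_of_images <- function(images) {
  if (is.list(images)) dim(images[[1]]) else dim(images)[1:2]
}

split_stratified <- function(labels, fractions) {
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (lv in unique(labels)) {
    members <- which(labels == lv)
    members <- members[sample.int(length(members))]
    n <- length(members)
    n_tr <- round(fractions[1] * n)
    n_val <- round(fractions[2] * n)
    train <- c(train, members[seq_len(n_tr)])
    val <- c(val, members[n_tr + seq_len(n_val)])
    test <- c(test, members[-seq_len(n_tr + n_val)])
  }
  list(train = train, val = val, test = test)
}

# Train with an explicit validation set (early stopping on it).
train_model_with_validation <- function(model, train_images, train_labels,
                                        val_images, val_labels, config) {
  arr <- as_image_array(train_images, model$config$input_shape)
  varr <- as_image_array(val_images, model$config$input_shape)
  fit <- cnn_train(model$weights, cnn_conf(model$config),
                   arr, as.integer(train_labels),
                   varr, as.integer(val_labels),
                   config$learning_rate, config$batch_size,
                   config$max_epochs, config$patience, config$seed,
                   FALSE)
  model$weights <- fit$weights
  model$trained <- TRUE
  model$train_config <- config
  model$history <- tibble::tibble(
    epoch = as.integer(fit$epoch), loss = fit$loss, accuracy = fit$accuracy,
    val_loss = fit$val_loss, val_accuracy = fit$val_accuracy)
  model
}

#' @export
tidy.kernel_sweep <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.kernel_sweep <- function(x, ...) {
  tidyr::pivot_wider(attr(x, "spread"), names_from = "metric",
                     values_from = "spread", names_prefix = "spread_")
}
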