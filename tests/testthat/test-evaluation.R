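test_that("folds partition the items into near-equal disjoint test sets", {
  folds <- make_folds(100, 10, seed = 1)
  test_sets <- folds$test_indices
  expect_true(all(lengths(test_sets) == 10))
  expect_setequal(unlist(test_sets), 1:100)
  for (k in 1:10) {
    expect_length(intersect(folds$train_indices[[k]], test_sets[[k]]), 0)
    expect_setequal(c(folds$train_indices[[k]], test_sets[[k]]), 1:100)
  }
  # uneven N: fold sizes floor or ceiling of N/k
  folds2 <- make_folds(103, 10, seed = 2)
  expect_true(all(lengths(folds2$test_indices) %in% c(10, 11)))
  expect_error(make_folds(5, 10), "cannot make")
})

test_that("stratified folds spread a 420-strong minority class evenly", {
  labels <- rep(c(0L, 1L, 4L), times = c(3000, 2000, 420))
  folds <- make_folds(length(labels), 10, seed = 3, stratify_labels = labels)
  for (k in 1:10) {
    te <- folds$test_indices[[k]]
    expect_identical(sum(labels[te] == 4L), 42L)
    expect_identical(sum(labels[te] == 0L), 300L)
    expect_identical(length(te), 542L)
  }
})

test_that("confusion matrices count by hand and row-normalize", {
  cm <- confusion_from_predictions(c(1, 1, 2), c(1, 2, 2), n_classes = 5)
  expect_identical(cm[2, 2], 1L)   # true 1 predicted 1
  expect_identical(cm[2, 3], 1L)   # true 1 predicted 2
  expect_identical(cm[3, 3], 1L)
  expect_identical(sum(cm), 3L)
  norm <- normalize_confusion(cm)
  nonempty <- rowSums(unclass(cm)) > 0
  expect_equal(unname(rowSums(norm)[nonempty]), c(1, 1))
  expect_error(confusion_from_predictions(c(0, 5), c(0, 0)), "labels must be")
  # perfect predictions give a diagonal matrix
  cmp <- confusion_from_predictions(0:4, 0:4)
  expect_true(all(unclass(cmp)[upper.tri(cmp) | lower.tri(cmp)] == 0))
})

test_that("a diagonal confusion matrix scores 100% on every metric", {
  cm <- confusion_from_predictions(rep(0:4, 10), rep(0:4, 10))
  rep <- metrics_from_confusion(cm)
  expect_true(all(abs(as.matrix(rep$per_class[, 2:5]) - 100) < 1e-12))
  expect_equal(rep$micro_accuracy, 100)
})

test_that("the worked 2x2 example reproduces hand-computed metrics", {
  cm <- matrix(c(50, 5, 10, 35), 2)   # rows true, cols predicted
  rep <- metrics_from_confusion(cm)
  c1 <- rep$per_class[rep$per_class$class == 1, ]
  expect_equal(c1$precision, 100 * 35 / 45, tolerance = 1e-12)
  expect_equal(c1$recall, 100 * 35 / 40, tolerance = 1e-12)
  expect_equal(c1$f1, 100 * 2 * (35 / 45) * (35 / 40) / (35 / 45 + 35 / 40),
               tolerance = 1e-12)
  expect_equal(rep$micro_accuracy, 85)
})

test_that("a class absent from the test set is flagged, not NaN", {
  cm <- confusion_from_predictions(c(0, 0, 1), c(0, 1, 1), n_classes = 3)
  rep <- metrics_from_confusion(cm)
  c2 <- rep$per_class[rep$per_class$class == 2, ]
  expect_true(c2$undefined)
  expect_identical(c2$recall, 0)
  expect_false(anyNA(rep$per_class))
  expect_error(metrics_from_confusion(matrix(0, 3, 3)), "empty")
})

test_that("metrics agree with the per-item counting oracle on random labels", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(20:60, 1)
    true <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    rep <- metrics_from_confusion(confusion_from_predictions(true, pred))
    oracle <- count_metrics(true, pred, 5)
    got <- as.matrix(rep$per_class[, c("accuracy", "precision", "recall", "f1")])
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    expect_equal(rep$micro_accuracy, 100 * mean(true == pred), tolerance = 1e-12)
  }
})

test_that("confusion row/column sums recover TP+FN and TP+FP", {
  set.seed(12)
  true <- sample(0:4, 200, replace = TRUE)
  pred <- sample(0:4, 200, replace = TRUE)
  cm <- unclass(confusion_from_predictions(true, pred))
  for (k in 0:4) {
    expect_identical(sum(cm[k + 1, ]), sum(true == k))
    expect_identical(sum(cm[, k + 1]), sum(pred == k))
  }
})

test_that("cross-validation with the truth-echo stub scores 100% on every fold", {
  set.seed(13)
  n <- 150
  images <- array(runif(10 * 12 * n), dim = c(10, 12, n))
  labels <- rep(0:4, each = 30)
  cfg <- model_config(conv_filters = 4, dense_units = 8,
                      input_shape = c(10, 12))
  cv <- run_cross_validation(images, labels, model_config = cfg,
                             sobel_size = NULL, n_folds = 10, seed = 5,
                             learner = oracle_learner())
  expect_identical(nrow(cv$fold_summary), 10L)
  expect_true(all(cv$fold_summary$micro_accuracy == 100))
  expect_true(all(cv$fold_summary$macro_f1 == 100))
  expect_true(all(cv$summary$sd == 0))   # SD of a constant metric
  expect_equal(unclass(cv$mean_confusion), diag(5), ignore_attr = TRUE)
  expect_identical(nrow(tidy(cv)), 50L)  # 10 folds x 5 classes
})

test_that("cross-validation trains real (small) models without leakage", {
  set.seed(14)
  n <- 100
  images <- array(runif(12 * 16 * n), dim = c(12, 16, n))
  labels <- rep(0:4, each = 20)
  for (k in 0:4) {
    rows <- (2 * k + 1):(2 * k + 2)
    images[rows, , labels == k] <- images[rows, , labels == k] + 2
  }
  cfg <- model_config(conv_filters = c(8), dense_units = 16,
                      input_shape = c(12, 16))
  tc <- train_config(max_epochs = 8, batch_size = 10,
                     validation_fraction = 0, seed = 2)
  cv <- run_cross_validation(images, labels, model_config = cfg,
                             train_config = tc, sobel_size = NULL,
                             n_folds = 5, seed = 6)
  expect_identical(nrow(cv$fold_summary), 5L)
  expect_gt(mean(cv$fold_summary$micro_accuracy), 80)
  g <- glance(cv)
  expect_true(all(c("mean_micro_accuracy", "sd_micro_accuracy") %in% names(g)))
})

test_that("cross-validation demands every class and consistent labels", {
  images <- array(runif(10 * 12 * 20), dim = c(10, 12, 20))
  expect_error(run_cross_validation(images, rep(0:3, each = 5),
                                    sobel_size = NULL),
               "every class")
})

test_that("the kernel-size sweep returns one row per size with spreads", {
  set.seed(15)
  n <- 60
  images <- array(runif(20 * 30 * n), dim = c(20, 30, n))
  labels <- rep(c(0L, 1L), each = n / 2)
  images[9:12, , labels == 1] <- images[9:12, , labels == 1] + 2  # contour band
  cfg <- simplified_model_config(input_shape = c(20, 30))
  tc <- train_config(max_epochs = 4, batch_size = 8, seed = 3)
  sweep <- kernel_size_sweep(images, labels, sizes = c(3, 7),
                             model_config = cfg, train_config = tc, seed = 4)
  expect_identical(nrow(tibble::as_tibble(sweep)), 2L)
  expect_named(tidy(sweep), c("size", "accuracy", "precision", "recall", "f1"))
  sp <- glance(sweep)
  expect_true(all(c("spread_accuracy", "spread_f1") %in% names(sp)))
  expect_true(all(as.matrix(tidy(sweep)[, -1]) >= 0 &
                    as.matrix(tidy(sweep)[, -1]) <= 100))
  expect_error(kernel_size_sweep(images, labels, sizes = c(4, 7)),
               "odd integers")
})
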