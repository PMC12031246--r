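# Small architectures keep the unit tests quick; the full-size default
# network is exercised in the acceptance suite.
tiny_config <- function(n_classes = 3) {
  model_config(conv_filters = c(4, 8), dense_units = 16,
               n_classes = n_classes, input_shape = c(16, 24))
}

tiny_images <- function(n, shape = c(16, 24), seed = 1) {
  withr::with_seed(seed, array(runif(prod(shape) * n), dim = c(shape, n)))
}

test_that("forward pass returns a probability simplex point", {
  m <- build_model(tiny_config(), seed = 1)
  X <- tiny_images(7)
  pr <- predict(m, X)
  probs <- as.matrix(pr[, 1:3])
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, 7), tolerance = 1e-6)
})

test_that("spatial dimensions follow floor-halving through the stack", {
  dims <- conv_stack_dims(model_config())
  expect_equal(dims$height, c(75, 37, 18))
  expect_equal(dims$width, c(150, 75, 37))
  expect_equal(dims$channels, c(32, 64, 128))
  # brute arithmetic oracle
  h <- 150; w <- 300
  for (s in 1:3) { h <- floor(h / 2); w <- floor(w / 2) }
  expect_equal(c(dims$height[3], dims$width[3]), c(h, w))
})

test_that("too-small inputs for the pooling stack error with the minimum size", {
  cfg <- model_config(conv_filters = c(4, 4, 4), input_shape = c(6, 6))
  expect_error(build_model(cfg), "minimum is 8x8")
})

test_that("the simplified sensitivity-study variant builds and trains", {
  cfg <- simplified_model_config(input_shape = c(16, 24))
  expect_equal(cfg$conv_filters, c(16L, 32L))
  expect_equal(cfg$dense_units, 64L)
  expect_equal(cfg$n_classes, 2L)
  m <- build_model(cfg, seed = 1)
  X <- tiny_images(24)
  y <- rep(0:1, 12)
  X[1:8, , y == 1] <- X[1:8, , y == 1] + 1
  fit <- train_model(m, X, y, train_config(max_epochs = 3, batch_size = 8,
                                           validation_fraction = 0))
  expect_identical(nrow(fit$history), 3L)
  expect_lt(fit$history$loss[3], fit$history$loss[1])
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(conv_filters = 3, conv_kernel = c(3, 3),
                      dense_units = 5, n_classes = 3, input_shape = c(6, 8))
  m <- build_model(cfg, seed = 4)
  # randomize the (zero-initialized) output layer so every layer's gradient
  # is informative
  m$weights$dense2$W[] <- withr::with_seed(5, rnorm(length(m$weights$dense2$W), sd = 0.3))
  X <- tiny_images(4, c(6, 8), seed = 9)
  y <- c(0L, 1L, 2L, 1L)
  conf <- whistlenet:::cnn_conf(cfg)
  g <- whistlenet:::cnn_gradients(m$weights, conf, X, y)

  # perturb one entry addressed by a recursive numeric index path:
  # weights = list(conv = list(list(W, b)), dense1 = list(W, b), dense2 = ...)
  perturbed_loss <- function(path, idx, h) {
    w <- m$weights
    w[[path]][idx] <- w[[path]][idx] + h
    whistlenet:::cnn_mean_loss(w, conf, X, y)
  }
  paths <- list(c(1, 1, 1), c(1, 1, 2),   # conv W, conv b
                c(2, 1), c(2, 2),         # dense1 W, b
                c(3, 1), c(3, 2))         # dense2 W, b
  set.seed(2)
  for (path in paths) {
    for (idx in sample(length(m$weights[[path]]), 3)) {
      numeric_g <- (perturbed_loss(path, idx, 1e-3) -
                      perturbed_loss(path, idx, -1e-3)) / 2e-3
      analytic <- g[[path]][idx]
      # float32 forward passes limit attainable agreement
      expect_lt(abs(analytic - numeric_g), max(2e-3, 0.05 * abs(numeric_g)))
    }
  }
})

test_that("training separates a linearly separable image fixture", {
  cfg <- model_config(conv_filters = c(8, 16), dense_units = 32,
                      n_classes = 2, input_shape = c(24, 48))
  n <- 200
  X <- tiny_images(n, c(24, 48), seed = 3)
  y <- rep(0:1, each = n / 2)
  X[1:12, , y == 0] <- X[1:12, , y == 0] + 1.5   # bright top half
  X[13:24, , y == 1] <- X[13:24, , y == 1] + 1.5 # bright bottom half
  m <- build_model(cfg, seed = 1)
  fit <- train_model(m, X, y, train_config(max_epochs = 10, batch_size = 16,
                                           validation_fraction = 0))
  acc <- mean(predict(fit, X)$label == y)
  expect_gt(acc, 0.95)
})

test_that("degenerate training sets are rejected", {
  m <- build_model(tiny_config(), seed = 1)
  expect_error(train_model(m, array(0, c(16, 24, 0)), integer(0)), "empty")
  X <- tiny_images(6)
  expect_error(train_model(m, X, rep(1L, 6)), "single class")
  expect_error(train_model(m, X, c(0L, 1L, 5L, 0L, 1L, 0L)), "labels must be")
})

test_that("a fixed seed reproduces the first-epoch loss exactly", {
  X <- tiny_images(20)
  y <- rep(0:1, 10)
  tc <- train_config(max_epochs = 1, batch_size = 5, validation_fraction = 0,
                     seed = 7)
  f1 <- train_model(build_model(tiny_config(2), seed = 7), X, y, tc)
  f2 <- train_model(build_model(tiny_config(2), seed = 7), X, y, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$weights, f2$weights)
})

test_that("zeroed weights give uniform probabilities and class-0 tie-break", {
  m <- build_model(tiny_config(5), seed = 1)
  m$weights <- rapply(m$weights, function(x) x * 0, how = "replace")
  # (the output layer starts at zero anyway; zero everything for the test)
  pr <- predict(m, tiny_images(3))
  expect_equal(as.matrix(pr[, 1:5]), matrix(0.2, 3, 5), ignore_attr = TRUE,
               tolerance = 1e-7)
  expect_identical(pr$label, rep(0L, 3))
})

test_that("the default network memorizes a small subset", {
  # capacity check: default layer widths at a reduced image size
  cfg <- model_config(input_shape = c(64, 128))
  ds_img <- tiny_images(50, c(64, 128), seed = 10)
  y <- rep(0:4, each = 10)
  for (k in 0:4) {   # give each class a distinct bright patch
    rows <- (k * 12 + 1):(k * 12 + 12)
    ds_img[rows, , y == k] <- ds_img[rows, , y == k] + 1
  }
  m <- build_model(cfg, seed = 2)
  fit <- train_model(m, ds_img, y, train_config(max_epochs = 15, batch_size = 10,
                                                validation_fraction = 0))
  expect_gte(mean(predict(fit, ds_img)$label == y), 0.99)
})

test_that("history tidiers and model persistence work", {
  X <- tiny_images(20)
  y <- rep(0:1, 10)
  m <- train_model(build_model(tiny_config(2), seed = 1), X, y,
                   train_config(max_epochs = 2, validation_fraction = 0))
  expect_named(tidy(m), c("epoch", "loss", "accuracy", "val_loss",
                          "val_accuracy"))
  expect_identical(glance(m)$epochs, 2L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(sub("rds$", "json", path)))
  m2 <- load_model(path)
  expect_identical(predict(m2, X), predict(m, X))
})
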