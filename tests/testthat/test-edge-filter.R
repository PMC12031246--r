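test_that("size-3 time-derivative kernel is the canonical Sobel", {
  k <- make_kernel(3, "time")
  expect_equal(k$weights,
               matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3),
               ignore_attr = TRUE)
})

test_that("the size-5 derivative vector is the double-smoothed difference", {
  k <- make_kernel(5, "time")
  expect_equal(k$col_factor, c(1, 2, 0, -2, -1))
  expect_equal(k$row_factor, c(1, 4, 6, 4, 1))
})

test_that("all kernel sizes satisfy the zero-sum and symmetry invariants", {
  for (sz in c(3, 5, 7, 9, 11)) {
    for (axis in c("time", "frequency")) {
      k <- make_kernel(sz, axis)
      expect_identical(dim(k$weights), as.integer(c(sz, sz)))
      expect_equal(sum(k$weights), 0)
      if (axis == "time") {
        # antisymmetric under column reversal, symmetric under row reversal
        expect_equal(k$weights[, sz:1], -k$weights, ignore_attr = TRUE)
        expect_equal(k$weights[sz:1, ], k$weights, ignore_attr = TRUE)
      } else {
        expect_equal(k$weights[sz:1, ], -k$weights, ignore_attr = TRUE)
        expect_equal(k$weights[, sz:1], k$weights, ignore_attr = TRUE)
      }
      # transpose swaps the derivative axis
      kt <- t(k)
      expect_equal(kt$weights, t(k$weights), ignore_attr = TRUE)
      expect_false(kt$derivative_axis == k$derivative_axis)
    }
  }
})

test_that("invalid kernel sizes are rejected", {
  for (bad in list(4, 2, 13, 1)) expect_error(make_kernel(bad), "odd integer")
})

test_that("filtering matches brute-force cross-correlation on random images", {
  set.seed(123)
  for (i in 1:25) {
    sz <- sample(c(3, 5, 7), 1)
    axis <- sample(c("time", "frequency"), 1)
    k <- make_kernel(sz, axis)
    m <- matrix(runif(20 * 20), 20)
    fast <- whistlenet:::xcorr2_sep_reflect(m, k$row_factor, k$col_factor)
    expect_lt(max(abs(fast - brute_xcorr2_reflect(m, k$weights))), 1e-9)
  }
})

test_that("a constant image filters to the defined degenerate output", {
  m <- matrix(0.7, 40, 60)
  out <- apply_kernel(m, make_kernel(7, "time"))
  expect_true(all(out == 0.5))
})

test_that("derivative filters annihilate structures constant along their axis", {
  # horizontal bands (constant along time) die under the time derivative
  bands <- matrix(rep(sin(seq(0, 6 * pi, length.out = 50)), 80), 50, 80)
  k <- make_kernel(7, "time")
  raw <- whistlenet:::xcorr2_sep_reflect(bands, k$row_factor, k$col_factor)
  r <- 3 # kernel radius
  interior <- raw[(r + 1):(50 - r), (r + 1):(80 - r)]
  expect_lt(max(abs(interior)), 1e-9)
  # dual: vertical streaks die under the frequency derivative
  streaks <- matrix(rep(runif(80), each = 50), 50, 80)
  kf <- make_kernel(7, "frequency")
  raw2 <- whistlenet:::xcorr2_sep_reflect(streaks, kf$row_factor, kf$col_factor)
  expect_lt(max(abs(raw2[(r + 1):(50 - r), (r + 1):(80 - r)])), 1e-9)
})

test_that("a bright column responds at its flanks under the time derivative", {
  m <- matrix(0, 50, 80)
  m[, 40] <- 1
  out <- apply_kernel(m, make_kernel(3, "time"))
  response_cols <- which(colSums(unclass(out)) > 0)
  expect_setequal(response_cols, c(39, 41))
})

test_that("axis duality: transposing the image swaps the effective axis", {
  set.seed(5)
  m <- matrix(runif(30 * 30), 30)
  kt <- make_kernel(5, "time")
  kf <- make_kernel(5, "frequency")
  a <- whistlenet:::xcorr2_sep_reflect(t(m), kt$row_factor, kt$col_factor)
  b <- whistlenet:::xcorr2_sep_reflect(m, kf$row_factor, kf$col_factor)
  expect_equal(a, t(b), tolerance = 1e-12)
})

test_that("the class policy picks the documented directions", {
  pol <- filter_policy()
  expect_identical(unname(pol[c("0", "1")]), c("frequency", "frequency"))
  expect_identical(unname(pol[c("2", "3", "4")]), rep("time", 3))

  # whistle image: horizontal contour survives frequency-derivative filtering
  img <- matrix(0, 50, 80)
  img[25, ] <- 1
  outw <- filter_for_class(img, class = 1L)
  expect_gt(sum(outw[c(22, 28), ]), sum(outw[c(10, 40), ]))
  # feeding buzz: the time-derivative kernel is applied (flanks of columns light up)
  imgb <- matrix(0, 50, 80)
  imgb[, 30] <- 1
  outb <- filter_for_class(imgb, class = 4L)
  expect_gt(sum(outb[, c(27, 33)]), sum(outb[, c(10, 60)]))
})

test_that("default size is 7 and deployment mode demands a direction", {
  img <- matrix(runif(30 * 30), 30)
  expect_equal(unclass(filter_for_class(img, class = 2L)),
               unclass(apply_kernel(img, make_kernel(7, "time"))))
  expect_error(filter_for_class(img), "deployment")
  expect_identical(filter_for_class(img, override = "none"), img)
})
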