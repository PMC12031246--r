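make_recording <- function(duration = 10, fs = 192000, seed = 1) {
  samples <- withr::with_seed(seed, rnorm(round(duration * fs), sd = 0.01))
  whistlenet:::new_audio_recording(samples, fs)
}

test_that("short events yield one centered full-length segment", {
  rec <- make_recording(5)
  seg <- segment_event(rec, tibble::tibble(start = 2.0, end = 2.8, class = 1L))
  expect_identical(nrow(seg), 1L)
  expect_equal(seg$start, 2.0)
  expect_equal(seg$end, 2.8)
  expect_length(seg$samples[[1]], round(0.8 * 192000))
  # sub-window event is centered on its midpoint
  seg2 <- segment_event(rec, tibble::tibble(start = 2.0, end = 2.4, class = 2L))
  expect_equal(seg2$start, 2.2 - 0.4)
  expect_equal(seg2$end, 2.2 + 0.4)
})

test_that("1.2 s and 1.3 s events tile per the 50%-overlap rule", {
  rec <- make_recording(5)
  seg <- segment_event(rec, tibble::tibble(start = 1.0, end = 2.2, class = 1L))
  expect_equal(seg$start, c(1.0, 1.4))
  expect_equal(seg$end, c(1.8, 2.2))
  seg3 <- segment_event(rec, tibble::tibble(start = 1.0, end = 2.3, class = 1L))
  expect_equal(seg3$start, c(1.0, 1.4, 1.5))
  expect_equal(seg3$end, c(1.8, 2.2, 2.3))
})

test_that("segment count and coverage match the enumeration oracle", {
  rec <- make_recording(30)
  set.seed(7)
  for (i in 1:250) {
    d <- runif(1, 0.05, 8)
    s <- runif(1, 0.5, 20)
    seg <- segment_event(rec, tibble::tibble(start = s, end = s + d, class = 3L))
    oracle <- enumerate_segments(s, s + d)
    expect_identical(nrow(seg), nrow(oracle))
    if (d > 0.8) {
      # count law n = ceil((d - w)/(w/2)) + 1
      expect_identical(nrow(seg), as.integer(ceiling((d - 0.8) / 0.4 - 1e-12) + 1))
      # exact coverage of the event interval
      expect_equal(min(seg$start), s)
      expect_equal(max(seg$end), s + d)
      ord <- order(seg$start)
      expect_true(all(seg$start[ord][-1] <= seg$end[ord][-nrow(seg)] + 1e-9))
    }
    expect_true(all(lengths(seg$samples) == round(0.8 * 192000)))
  }
})

test_that("windows are clamped inside the recording, never padded", {
  rec <- make_recording(2)
  seg <- segment_event(rec, tibble::tibble(start = 0.0, end = 0.2, class = 1L))
  expect_equal(seg$start, 0)
  expect_length(seg$samples[[1]], round(0.8 * 192000))
  seg2 <- segment_event(rec, tibble::tibble(start = 1.9, end = 2.0, class = 1L))
  expect_equal(seg2$end, 2.0)
})

test_that("events outside the recording and too-short recordings error", {
  rec <- make_recording(2)
  expect_error(segment_event(rec, tibble::tibble(start = 1.5, end = 2.5, class = 1L)),
               "outside")
  tiny <- whistlenet:::new_audio_recording(rnorm(1000), 192000)
  expect_error(segment_event(tiny, tibble::tibble(start = 0, end = 0.001, class = 1L)),
               "shorter")
})

test_that("noise segments avoid all annotated events", {
  rec <- make_recording(10)
  events <- tibble::tibble(start = c(1, 4, 7), end = c(2, 5.5, 8), class = 1L)
  seg <- sample_noise_segments(rec, events, count = 5, seed = 3)
  expect_identical(nrow(seg), 5L)
  expect_true(all(seg$class == 0L))
  for (r in seq_len(nrow(seg))) {
    expect_false(any(seg$start[r] < events$end & seg$end[r] > events$start))
  }
  # pairwise disjoint among themselves
  ord <- order(seg$start)
  expect_true(all(seg$start[ord][-1] >= seg$end[ord][-nrow(seg)] - 1e-9))
})

test_that("unconstrained noise sampling returns the requested count", {
  rec <- make_recording(10)
  empty <- tibble::tibble(start = numeric(), end = numeric())
  seg <- sample_noise_segments(rec, empty, count = 5, seed = 1)
  expect_identical(nrow(seg), 5L)
})

test_that("a fully annotated recording yields no noise segments, with warning", {
  rec <- make_recording(3)
  events <- tibble::tibble(start = 0, end = 3, class = 1L)
  expect_warning(seg <- sample_noise_segments(rec, events, count = 4, seed = 1),
                 "only 0 of 4")
  expect_identical(nrow(seg), 0L)
})

test_that("segment_recording combines events and noise and skips NA classes", {
  rec <- make_recording(10)
  events <- tibble::tibble(start = c(1, 3), end = c(1.5, 4.2),
                           class = c(1L, NA))
  expect_warning(seg <- segment_recording(rec, events, noise_count = 2),
                 "unknown class")
  expect_identical(nrow(seg), 1L + 2L)   # one short event + two noise
  expect_setequal(unique(seg$class), c(0L, 1L))
})
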