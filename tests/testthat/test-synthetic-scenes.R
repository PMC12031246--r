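test_that("constant-contour whistle concentrates energy at the contour frequency", {
  spec <- event_spec(1, duration = 0.5, contour = list(
    f_start = 10000, f_end = 10000, modulation = "linear", harmonics = 1))
  w <- synthesize_whistle(spec, 192000)
  expect_length(w, 96000)
  expect_lt(abs(fft_peak_freq(w, 192000) - 10000), 192000 / length(w) + 1)
})

test_that("zero-duration events give empty waveforms without error", {
  spec <- event_spec(1, duration = 0)
  expect_length(synthesize_whistle(spec, 192000), 0)
  spec2 <- event_spec(2, duration = 0)
  expect_length(synthesize_pulse_train(spec2, 192000), 0)
})

test_that("a linear upsweep has a monotonically increasing spectrogram ridge", {
  spec <- event_spec(1, duration = 0.5, contour = list(
    f_start = 5000, f_end = 15000, modulation = "linear", harmonics = 1))
  w <- synthesize_whistle(spec, 192000)
  ridge <- stft_ridge(w, 192000)
  ridge <- ridge[2:(length(ridge) - 1)]   # tapered ends have weak energy
  expect_true(all(diff(ridge) >= 0))
  expect_gt(tail(ridge, 1), head(ridge, 1))
})

test_that("whistle contours above Nyquist are rejected", {
  spec <- event_spec(1, duration = 0.1, contour = list(
    f_start = 50000, f_end = 50000, modulation = "linear", harmonics = 1))
  expect_error(synthesize_whistle(spec, 96000), "Nyquist")
})

test_that("a jitter-free 0.1 s train at ICI 10 ms has exactly 10 pulses", {
  spec <- event_spec(2, duration = 0.1,
                     pulse = list(ici = 0.01, ici_jitter = 0))
  w <- synthesize_pulse_train(spec, 192000)
  expect_identical(count_pulse_onsets(w, 192000), 10L)
})

test_that("default spectral centroids separate buzzes from clicks and bursts", {
  # feeding buzz: dominant frequency below 30 kHz
  buzz <- event_spec(4, duration = 0.02)
  one_click <- synthesize_pulse_train(
    event_spec(4, duration = 0.001,
               pulse = list(ici = 0.9e-3, ici_jitter = 0)), 192000)
  expect_lt(fft_centroid(one_click, 192000), 30000)
  # echolocation clicks and burst pulses: above 40 kHz
  for (klass in c(2L, 3L)) {
    ici <- class_event_defaults()[[class_name(klass)]]$pulse$ici
    w <- synthesize_pulse_train(
      event_spec(klass, duration = ici * 0.9,
                 pulse = list(ici = ici, ici_jitter = 0)), 192000)
    expect_gt(fft_centroid(w, 192000), 40000)
  }
})

test_that("invalid pulse parameters are rejected", {
  expect_error(event_spec(2, pulse = list(ici = 0)), "inter-click")
  expect_error(event_spec(3, pulse = list(ici = 1e-4, click_length = 3e-4)),
               "click length")
})

test_that("an empty scene is pure noise of the right length", {
  scene <- render_scene(scene_config(1, seed = 5))
  expect_length(scene$waveform, 192000)
  expect_identical(nrow(scene$events), 0L)
  expect_gt(stats::sd(scene$waveform), 0)
})

test_that("rendering is deterministic for a fixed seed", {
  cfg <- scene_config(0.5, seed = 99, events = list(
    event_spec(1, onset = 0.05, duration = 0.3),
    event_spec(4, onset = 0.1, duration = 0.2)))
  s1 <- render_scene(cfg)
  s2 <- render_scene(cfg)
  expect_identical(s1$waveform, s2$waveform)
  expect_identical(s1$events, s2$events)
})

test_that("an event at +20 dB SNR raises in-band RMS over the noise floor", {
  cfg0 <- scene_config(1, seed = 17)
  cfg1 <- scene_config(1, seed = 17, events = list(
    event_spec(1, onset = 0.2, duration = 0.5, snr_db = 20)))
  noise <- render_scene(cfg0)$waveform
  mixed <- render_scene(cfg1)$waveform
  idx <- (round(0.2 * 192000) + 1):round(0.7 * 192000)
  band_rms <- function(x) {
    p <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 192000 / length(x)
    f <- pmin(f, 192000 - f)
    sel <- f >= 6000 & f <= 20000
    sqrt(mean(x^2) * sum(p[sel]) / sum(p))
  }
  expect_gt(band_rms(mixed[idx]), 5 * band_rms(noise[idx]))
})

test_that("events extending past the scene are rejected", {
  cfg <- scene_config(0.5, seed = 1, events = list(
    event_spec(1, onset = 0.3, duration = 0.4)))
  expect_error(render_scene(cfg), "extends past")
})

test_that("generated trains recover their nominal ICI and centroid within 10%", {
  set.seed(42)
  for (klass in 2:4) {
    nominal <- class_event_defaults()[[class_name(klass)]]$pulse
    spec <- event_spec(klass, duration = 0.4,
                       pulse = list(ici_jitter = 0))
    w <- synthesize_pulse_train(spec, 192000)
    n_onsets <- count_pulse_onsets(w, 192000)
    ici_hat <- 0.4 / n_onsets
    expect_lt(abs(ici_hat - nominal$ici) / nominal$ici, 0.1)
    one <- synthesize_pulse_train(
      event_spec(klass, duration = nominal$ici * 0.9,
                 pulse = list(ici_jitter = 0)), 192000)
    expect_lt(abs(fft_centroid(one, 192000) - nominal$center_freq) /
                nominal$center_freq, 0.1)
  }
})

test_that("every emitted label interval contains energy above the noise floor", {
  cfg <- scene_config(1, seed = 31, events = list(
    event_spec(1, onset = 0.05, duration = 0.3, snr_db = 15),
    event_spec(2, onset = 0.5, duration = 0.4, snr_db = 15)))
  scene <- render_scene(cfg)
  noise <- render_scene(scene_config(1, seed = 31))$waveform
  for (r in seq_len(nrow(scene$events))) {
    idx <- (round(scene$events$start[r] * 192000) + 1):
      round(scene$events$end[r] * 192000)
    expect_gt(mean(scene$waveform[idx]^2), 1.5 * mean(noise[idx]^2))
  }
})

test_that("scene configs round-trip through YAML", {
  cfg <- scene_config(2, seed = 7, noise_floor_db = -40, events = list(
    event_spec(1, onset = 0.1, duration = 0.5, snr_db = 12),
    event_spec(3, onset = 1.0, duration = 0.6, snr_db = 18)))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_config(cfg, path)
  cfg2 <- read_scene_config(path)
  expect_equal(cfg2, cfg)
  expect_identical(render_scene(cfg2)$waveform, render_scene(cfg)$waveform)
})
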