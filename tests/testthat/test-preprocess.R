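test_that("band-pass preserves in-band tones and rejects out-of-band tones", {
  cfg <- preprocess_config()
  rec10 <- make_sine_recording(10)
  out10 <- bandpass_filter(rec10, cfg)
  mid <- 500:1500  # avoid edge transients
  expect_equal(sd(out10$data[1, mid]), sd(rec10$data[1, mid]), tolerance = 0.01)
  rec120 <- make_sine_recording(120)
  out120 <- bandpass_filter(rec120, cfg)
  expect_lt(sd(out120$data[1, ]) / sd(rec120$data[1, ]), 0.05)
  zero <- eeg_recording(matrix(0, 2, 1000), fs = 500)
  expect_equal(bandpass_filter(zero, cfg)$data, zero$data)
  expect_identical(dim(out10$data), dim(rec10$data))
})

test_that("band-pass rejects bad samples and bad band edges", {
  rec <- make_noise_recording(channels = 2)
  bad <- rec; bad$data[1, 5] <- NA
  expect_error(bandpass_filter(bad), "non-finite")
  lowfs <- make_noise_recording(fs = 80, channels = 2)
  expect_error(bandpass_filter(lowfs, preprocess_config(band_high_hz = 40, target_fs = 80)),
               "band edges")
})

test_that("decimation keeps every k-th sample from the first", {
  cfg <- preprocess_config()
  rec <- eeg_recording(matrix(seq_len(60000), 1, 60000), fs = 500)
  out <- downsample(rec, cfg)
  expect_equal(ncol(out$data), 12000L)
  expect_equal(out$fs, 100)
  expect_equal(out$data[1, 1:3], c(1, 6, 11))
  rec11 <- eeg_recording(matrix(seq_len(11), 1, 11), fs = 500)
  out11 <- downsample(rec11, cfg)
  expect_equal(drop(out11$data), c(1, 6, 11))
  expect_error(downsample(rec, preprocess_config(target_fs = 300, band_high_hz = 50)),
               "integer multiple")
})

test_that("edge cropping removes crop_seconds from both ends", {
  cfg <- preprocess_config()
  rec <- eeg_recording(matrix(seq_len(12000), 1, 12000), fs = 100)
  out <- crop_edges(rec, cfg)
  expect_equal(ncol(out$data), 11400L)
  expect_equal(out$data[1, 1], 301)
  expect_equal(out$data[1, 11400], 11700)
  nocrop <- preprocess_config(crop_seconds = 0)
  expect_identical(crop_edges(rec, nocrop)$data, rec$data)
  short <- eeg_recording(matrix(rnorm(500), 1, 500), fs = 100)
  expect_error(crop_edges(short, cfg), "600")
})

test_that("z-scoring centers and scales each channel, flooring flat channels", {
  cfg <- preprocess_config()
  rec <- eeg_recording(matrix(c(1, 2, 3), 1, 3), fs = 100)
  out <- zscore_normalize(rec, cfg)
  expect_equal(mean(out$data[1, ]), 0)
  expect_equal(sqrt(mean(out$data[1, ]^2)), 1)  # population convention
  flat <- eeg_recording(matrix(5, 1, 3), fs = 100)
  expect_warning(outf <- zscore_normalize(flat, cfg), "constant")
  expect_equal(drop(outf$data), c(0, 0, 0))
  # idempotence and affine invariance
  noisy <- make_noise_recording(channels = 3, seconds = 2)
  z1 <- zscore_normalize(noisy, cfg)
  expect_equal(zscore_normalize(z1, cfg)$data, z1$data, tolerance = 1e-6)
  scaled <- noisy; scaled$data <- 3.7 * noisy$data + 11
  expect_equal(zscore_normalize(scaled, cfg)$data, z1$data, tolerance = 1e-9)
})

test_that("windowing follows the floor((L-w)/s)+1 count and m x e layout", {
  cfg <- preprocess_config()
  rec <- make_noise_recording(fs = 100, seconds = 114, channels = 26)
  ws <- segment_windows(rec, cfg)
  expect_equal(n_windows(ws), 14L)
  expect_equal(dim(ws$windows)[1:2], c(1000L, 26L))
  # window content is the transposed slice at the right stride
  expect_equal(ws$windows[, , 2], t(rec$data[, 801:1800]))
  exact <- eeg_recording(matrix(rnorm(2000), 2, 1000), fs = 100)
  expect_equal(n_windows(segment_windows(exact, cfg)), 1L)
  under <- eeg_recording(matrix(rnorm(2 * 999), 2, 999), fs = 100)
  expect_warning(ws0 <- segment_windows(under, cfg), "no windows")
  expect_equal(n_windows(ws0), 0L)
})

test_that("window count matches brute-force start enumeration for random geometries", {
  set.seed(42)
  for (i in 1:1000) {
    L <- sample(1:400, 1); w <- sample(1:100, 1)
    s <- sample(seq_len(min(w, 50)), 1)  # stride cannot exceed the window (overlap >= 0)
    brute <- sum(seq(0, max(L - 1, 0)) %% s == 0 &
                 seq(0, max(L - 1, 0)) + w <= L)
    formula_n <- if (L >= w) floor((L - w) / s) + 1 else 0
    expect_equal(formula_n, brute)
    if (L >= w) {
      fs <- 1
      rec <- eeg_recording(matrix(rnorm(L), 1, L), fs = fs)
      cfg <- preprocess_config(band_low_hz = 0.01, band_high_hz = 0.4,
                               target_fs = 1, crop_seconds = 0,
                               window_seconds = w, overlap_seconds = w - s,
                               sigma_floor = 1e-8)
      expect_equal(n_windows(segment_windows(rec, cfg)), formula_n)
    }
  }
})

test_that("the full chain turns a 120 s, 500 Hz, 26-channel recording into 14 windows of 1000 x 26", {
  rec <- make_noise_recording(fs = 500, seconds = 120, channels = 26)
  ws <- run_preprocessing(rec)
  expect_equal(n_windows(ws), 14L)
  expect_equal(c(ws$m, ws$e), c(1000L, 26L))
  expect_true(all(ws$subject_id == "sub-noise"))
  # determinism
  ws2 <- run_preprocessing(rec)
  expect_identical(ws$windows, ws2$windows)
  # a 7 s raw recording dies in crop+window, not with an error
  short <- make_noise_recording(fs = 500, seconds = 7, channels = 26)
  expect_warning(wss <- run_preprocessing(short), "no windows")
  expect_equal(n_windows(wss), 0L)
})

test_that("channel count is preserved through every stage", {
  rec <- make_noise_recording(fs = 500, seconds = 20, channels = 26)
  cfg <- preprocess_config()
  r1 <- bandpass_filter(rec, cfg)
  r2 <- downsample(r1, cfg)
  r3 <- crop_edges(r2, cfg)
  r4 <- zscore_normalize(r3, cfg)
  for (r in list(r1, r2, r3, r4)) expect_equal(n_channels(r), 26L)
  expect_equal(segment_windows(r4, cfg)$e, 26L)
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(preprocess_config(band_low_hz = 0), "band_low_hz")
  expect_error(preprocess_config(band_high_hz = 60), "Nyquist")
  expect_error(preprocess_config(overlap_seconds = 10), "overlap")
})
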