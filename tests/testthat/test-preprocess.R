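rms <- function(x) sqrt(mean(x^2))

test_that("band-pass keeps in-band tones and rejects out-of-band tones", {
  in_band <- sine_recording(10, fs = 100, dur = 10)
  out_band <- sine_recording(45, fs = 100, dur = 10)
  f_in <- bandpass_filter(in_band, 0.5, 30)
  f_out <- bandpass_filter(out_band, 0.5, 30)
  expect_gte(rms(f_in$data), 0.9 * rms(in_band$data))
  expect_lte(rms(f_out$data), 0.1 * rms(out_band$data))
  # spectral oracle: dominant DFT bin unchanged for the passed tone
  peak_bin <- function(x, fs) {
    p <- Mod(fft(x))[1:(length(x) / 2)]
    (which.max(p) - 1) * fs / length(x)
  }
  expect_equal(peak_bin(f_in$data[, 1], 100), 10)
})

test_that("band-pass preserves shape, is linear at zero, validates edges", {
  rec <- make_recording(n = 500, c_ = 3)
  out <- bandpass_filter(rec, 1, 30)
  expect_equal(dim(out$data), dim(rec$data))
  expect_identical(out$channels, rec$channels)
  zero <- eeg_recording(matrix(0, 200, 2) + 0, fs = 100)
  zero$data[] <- 0
  expect_true(all(bandpass_filter(zero, 1, 30)$data == 0))
  expect_error(bandpass_filter(rec, 0, 30), "parameter error")
  expect_error(bandpass_filter(rec, 30, 1), "parameter error")
  expect_error(bandpass_filter(rec, 1, 60), "parameter error")
})

test_that("resampling halves length, keeps spectral peaks, rescales events", {
  rec <- make_recording(n = 1000, c_ = 2, fs = 200,
                        events = data.frame(sample_index = 500L, code = "e"))
  out <- resample_to(rec, 100)
  expect_equal(nrow(out$data), 500)
  expect_equal(out$fs, 100)
  expect_equal(out$events$sample_index, 250L)
  # 5 Hz tone at 500 Hz resampled to 100 Hz keeps its peak at 5 Hz
  tone <- sine_recording(5, fs = 500, dur = 4)
  down <- resample_to(tone, 100)
  p <- Mod(fft(down$data[, 1]))[1:(nrow(down$data) / 2)]
  expect_equal((which.max(p) - 1) * 100 / nrow(down$data), 5)
  # identity and error cases
  expect_identical(resample_to(rec, 200)$data, rec$data)
  expect_error(resample_to(rec, 400), "upsampling")
})

test_that("z-score normalization gives per-channel mean 0 / sd 1 and handles guards", {
  rec <- eeg_recording(cbind(c(1, 2, 3, 4), c(5, 5, 5, 5)), fs = 100)
  out <- zscore_normalize(rec)
  expect_lt(abs(mean(out$data[, 1])), 1e-6)
  n <- nrow(out$data)
  expect_lt(abs(sqrt(sum((out$data[, 1] - mean(out$data[, 1]))^2) / n) - 1), 1e-6)
  expect_identical(out$data[, 2], c(0, 0, 0, 0))       # constant channel
  # scale invariance
  rec7 <- rec; rec7$data[, 1] <- 7 * rec7$data[, 1]
  expect_equal(zscore_normalize(rec7)$data[, 1], out$data[, 1], tolerance = 1e-7)
})

test_that("window counts follow floor((T - T_w)/S) + 1", {
  rec <- make_recording(n = 5000, c_ = 2, fs = 100)
  non_overlap <- segment_windows(rec, cfg = preprocess_config())
  expect_equal(length(non_overlap), 5)
  sliding <- segment_windows(rec, cfg = preprocess_config(step_sec = 2))
  expect_equal(length(sliding), 21)
  # starts are exactly {0, S, 2S, ...}
  expect_equal(vapply(sliding$windows, function(w) w$start_index, integer(1)),
               seq(0L, 4000L, by = 200L))
  # exact-fit boundary: one window
  rec1 <- make_recording(n = 1000, c_ = 2, fs = 100)
  one <- segment_windows(rec1, cfg = preprocess_config())
  expect_equal(length(one), 1)
  expect_equal(one$windows[[1]]$start_index, 0L)
  # shorter than a window: empty dataset, not an error
  short <- segment_windows(make_recording(n = 500), cfg = preprocess_config())
  expect_equal(length(short), 0)
})

test_that("segmentation attaches interval labels and re-bases events", {
  rec <- make_recording(n = 3000, c_ = 2, fs = 100,
                        events = data.frame(sample_index = c(1500L, 2990L),
                                            code = c("e1", "e2")))
  labs <- data.frame(start = c(0, 1000), end = c(1000, 2000),
                     label = c("HCL", "S"))
  ds <- segment_windows(rec, labels = labs, cfg = preprocess_config())
  # third window has no covering interval and is dropped
  expect_equal(length(ds), 2)
  expect_equal(dataset_labels(ds), c(0L, 2L))
  expect_equal(ds$windows[[2]]$events$sample_index, 500L)
  # determinism
  ds2 <- segment_windows(rec, labels = labs, cfg = preprocess_config())
  expect_identical(dataset_labels(ds), dataset_labels(ds2))
  expect_identical(ds$windows[[1]]$data, ds2$windows[[1]]$data)
})

test_that("non-overlapping windows are pairwise disjoint", {
  rec <- make_recording(n = 3500, c_ = 1, fs = 100)
  ds <- segment_windows(rec, cfg = preprocess_config())
  starts <- vapply(ds$windows, function(w) w$start_index, integer(1))
  ends <- starts + 1000L
  for (i in seq_along(starts)) {
    for (j in seq_along(starts)) {
      if (i != j) expect_true(ends[i] <= starts[j] || ends[j] <= starts[i])
    }
  }
})

test_that("the composed conditioning pipeline resamples, normalizes and windows", {
  rec <- make_recording(n = 6000, c_ = 2, fs = 200)   # 30 s at 200 Hz
  labs <- data.frame(start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
                     label = c("HCL", "S", "A"))      # target-rate samples
  ds <- preprocess_recording(rec, labels = labs, cfg = preprocess_config())
  expect_equal(length(ds), 3)                         # 3000 samples at 100 Hz
  expect_equal(ds$fs, 100)
  expect_equal(nrow(ds$windows[[1]]$data), 1000)
  expect_equal(dataset_labels(ds), state_code(c("HCL", "S", "A")))
  # z-scored: channel means near zero over the resampled recording
  allwin <- do.call(rbind, lapply(ds$windows, function(w) w$data))
  expect_lt(abs(mean(allwin[, 1])), 0.1)
})

test_that("preprocess_config validates its invariants", {
  expect_error(preprocess_config(band_low = 0), "parameter error")
  expect_error(preprocess_config(band_high = 60), "parameter error")
  expect_error(preprocess_config(step_sec = 11), "parameter error")
  expect_error(preprocess_config(step_sec = 0), "parameter error")
})
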