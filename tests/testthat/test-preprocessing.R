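test_that("resampling preserves duration and band content", {
  fs0 <- 128
  t0 <- (0:(10 * fs0 - 1)) / fs0
  e <- ecg_signal(sin(2 * pi * 5 * t0), fs0)
  r <- resample_ecg(e, 360)
  expect_equal(r$fs, 360)
  expect_lte(abs(length(r$samples) - 3600), 1)
  expect_lt(abs(oracle_peak_freq(r$samples, 360) - 5), 0.1)

  same <- resample_ecg(e, fs0)
  expect_equal(same$samples, e$samples, tolerance = 1e-9)
  expect_error(resample_ecg(e, 0), "non-positive")
})

test_that("wavelet denoising removes baseline and power-line tones, keeps mid band", {
  fs <- 360
  t <- (0:(30 * fs - 1)) / fs
  mid <- ecg_signal(sin(2 * pi * 10 * t), fs)
  slow <- ecg_signal(sin(2 * pi * 0.3 * t), fs)
  mains <- ecg_signal(sin(2 * pi * 60 * t), fs)
  dmid <- denoise_dwt(mid)
  expect_gte(cor(dmid$samples, mid$samples), 0.99)
  att <- function(before, after, f)
    10 * log10(oracle_band_power(before$samples, fs, f) /
               oracle_band_power(after$samples, fs, f))
  expect_gte(att(slow, denoise_dwt(slow), 0.3), 20)
  expect_gte(att(mains, denoise_dwt(mains), 60), 20)
  expect_error(denoise_dwt(ecg_signal(rnorm(100), fs)), "too short")
})

test_that("Pan-Tompkins detection matches generator ground truth", {
  bt <- seq(0, 119, by = 1)
  clean <- generate_ecg(bt, fs = 360, snr_db = Inf, seed = 1)
  ann <- detect_qrs(clean$ecg)
  expect_equal(length(ann$r_peaks), length(bt))   # noise-free count is exact

  noisy <- generate_ecg(bt, fs = 360, snr_db = 20, seed = 2)
  ann20 <- detect_qrs(noisy$ecg)
  tol <- 0.050 * 360
  hits20 <- sum(vapply(noisy$truth$r_peaks,
                       function(p) any(abs(ann20$r_peaks - p) <= tol),
                       logical(1)))
  expect_gte(hits20, 118)

  hard <- generate_ecg(bt, fs = 360, snr_db = 10, seed = 3)
  ann10 <- detect_qrs(hard$ecg)
  hits10 <- sum(vapply(hard$truth$r_peaks,
                       function(p) any(abs(ann10$r_peaks - p) <= tol),
                       logical(1)))
  expect_gte(hits10 / length(bt), 0.98)

  expect_error(detect_qrs(ecg_signal(rep(0, 3600), 360)), "no QRS|flat")
})

test_that("RR extraction follows the sample-index arithmetic", {
  ann <- structure(list(r_peaks = c(1L, 361L, 721L), fs = 360),
                   class = "beat_annotations")
  expect_equal(extract_rr(ann)$rr, c(1000, 1000))
  ann2 <- structure(list(r_peaks = c(1L, 181L), fs = 360),
                    class = "beat_annotations")
  expect_equal(extract_rr(ann2)$rr, 500)
  ann1 <- structure(list(r_peaks = 5L, fs = 360), class = "beat_annotations")
  expect_error(extract_rr(ann1), "2 beats")
})

test_that("ectopic filter removes 37.5% spikes, keeps 18.75% bumps, is idempotent", {
  spike <- rr_series(c(rep(800, 5), 1100, rep(800, 5)))
  out <- correct_ectopic(spike)
  expect_length(out$rr, 10)
  expect_true(out$corrected)
  expect_false(1100 %in% out$rr)

  clean <- rr_series(rep(800, 11))
  expect_equal(correct_ectopic(clean)$rr, rep(800, 11))

  bump <- rr_series(c(rep(800, 5), 950, rep(800, 5)))
  expect_true(950 %in% correct_ectopic(bump)$rr)

  # idempotence on a random spiky series
  withr::with_seed(9, {
    x <- 800 + 20 * rnorm(120)
    x[sample(120, 6)] <- x[sample(120, 6)] * 1.4
  })
  once <- correct_ectopic(rr_series(x))
  twice <- correct_ectopic(once)
  expect_equal(twice$rr, once$rr)
})

test_that("segmentation partitions the analysed span into 2-min segments", {
  rr <- rr_series(rep(1000, 840))
  segs <- segment_rr(rr)
  expect_length(segs, 7)
  expect_equal(vapply(segs, function(s) attr(s, "interval_index"), integer(1)),
               1:7)
  lens <- vapply(segs, function(s) length(s$rr), integer(1))
  expect_true(all(abs(lens - 120) <= 1))
  durs <- vapply(segs, rr_duration, numeric(1))
  expect_true(all(abs(durs - 120) <= 1.001))
  expect_equal(sum(lens), 840)  # disjoint partition of the first 840 s

  expect_error(segment_rr(rr_series(rep(1000, 839))), "shorter than 14 min")

  long <- rr_series(rep(1000, 900))
  segs2 <- segment_rr(long)
  expect_length(segs2, 7)
  expect_equal(sum(vapply(segs2, function(s) length(s$rr), integer(1))), 840)
})

test_that("window selection anchors on the event time for SCD records", {
  rr <- rr_series(rep(1000, 1000), group = "scd")
  win <- select_window(rr, event_time = 950)
  expect_equal(rr_duration(win), 840, tolerance = 1e-9)
  expect_equal(max(win$beat_times), 950, tolerance = 1e-9)

  win2 <- select_window(rr, seed = 4)  # random window, seeded
  win3 <- select_window(rr, seed = 4)
  expect_equal(win2$beat_times, win3$beat_times)
  expect_error(select_window(rr_series(rep(1000, 500))), "shorter")
  expect_error(select_window(rr, event_time = 100), "less than")
})
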