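test_that("CSV ECG records round-trip metadata and samples", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs: 360", "# lead: I", "# group: scd", "value",
               format(sin(2 * pi * 5 * (0:719) / 360), digits = 10)), f)
  e <- read_ecg(f, format = "csv")
  expect_s3_class(e, "ecg_signal")
  expect_length(e$samples, 720)
  expect_equal(e$fs, 360)
  expect_equal(e$lead, "I")
  expect_equal(e$group, "scd")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs: 0", "value", "1", "2"), bad)
  expect_error(read_ecg(bad, format = "csv"), "non-positive sampling rate")
  expect_error(read_ecg(file.path(tempdir(), "nope.csv"), format = "csv"),
               "not found")
})

test_that("minimal WFDB reader handles formats 16 and 212 with lead selection", {
  dir <- withr::local_tempdir()
  adc1 <- as.integer(round(200 * sin(2 * pi * (0:99) / 25)))
  adc2 <- as.integer(round(100 * cos(2 * pi * (0:99) / 25)))

  # format 16: interleaved little-endian int16
  writeLines(c("rec16 2 250 100",
               "rec16.dat 16 200(0)/mV 12 0 0 0 0 ECG1",
               "rec16.dat 16 200(0)/mV 12 0 0 0 0 ECG2"),
             file.path(dir, "rec16.hea"))
  inter <- as.vector(rbind(adc1, adc2))
  writeBin(inter, file.path(dir, "rec16.dat"), size = 2L, endian = "little")
  e1 <- read_ecg(file.path(dir, "rec16"), format = "wfdb", lead = "ECG1")
  e2 <- read_ecg(file.path(dir, "rec16"), format = "wfdb", lead = "ECG2")
  expect_equal(e1$samples, adc1 / 200)
  expect_equal(e2$samples, adc2 / 200)
  expect_equal(e1$fs, 250)

  # format 212: two 12-bit samples packed into 3 bytes (single lead)
  writeLines(c("rec212 1 360 100",
               "rec212.dat 212 200(0)/mV 12 0 0 0 0 ECG1"),
             file.path(dir, "rec212.hea"))
  v <- ifelse(adc1 < 0, adc1 + 4096L, adc1)   # two's complement, 12 bit
  b <- integer(0)
  for (i in seq(1, 100, by = 2)) {
    s1 <- v[i]; s2 <- v[i + 1]
    b <- c(b, s1 %% 256L, (s1 %/% 256L) + 16L * (s2 %/% 256L), s2 %% 256L)
  }
  writeBin(as.raw(b), file.path(dir, "rec212.dat"))
  e3 <- read_ecg(file.path(dir, "rec212"), format = "wfdb")
  expect_equal(e3$samples, adc1 / 200)
  expect_equal(e3$fs, 360)
})

test_that("RR CSV reading converts units and builds beat times", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr", "0.8", "0.8", "0.8"), f)
  r <- read_rr(f, units = "s")
  expect_equal(r$rr, c(800, 800, 800))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr", "800", "850"), f2)
  r2 <- read_rr(f2, units = "ms")
  expect_equal(diff(r2$beat_times), c(0.8, 0.85))

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("rr", "-5"), f3)
  expect_error(read_rr(f3), "positive")

  out <- withr::local_tempfile(fileext = ".csv")
  write_rr(r2, out)
  expect_equal(read_rr(out)$rr, r2$rr, tolerance = 1e-12)
})

test_that("rr_series enforces its invariants", {
  expect_error(rr_series(c(800, -5)), "positive")
  expect_error(rr_series(c(800, Inf)), "positive|finite")
  expect_error(rr_series(c(800, 800), beat_times = c(0, 1)), "length")
  r <- rr_series(c(800, 850))
  expect_equal(r$beat_times, c(0, 0.8, 1.65))
})

test_that("feature tables round-trip CSV within 1e-12 with 29 columns", {
  withr::with_seed(5, {
    X <- matrix(rexp(2 * 27) * 10^runif(2 * 27, -4, 3), 2, 27)
  })
  colnames(X) <- hrv_feature_names
  tab <- feature_table(as.data.frame(X), c("normal", "scd"), c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  lines <- readLines(f)
  expect_length(strsplit(lines[1], ",")[[1]], 29)
  expect_length(lines, 3)
  back <- read_feature_table(f)
  for (fn in hrv_feature_names)
    expect_equal(back[[fn]], tab[[fn]], tolerance = 1e-12)
  expect_equal(back$label, tab$label)
  expect_equal(back$interval_index, tab$interval_index)
})

test_that("degenerate feature tables are rejected", {
  X <- matrix(1, 1, 27); colnames(X) <- hrv_feature_names
  expect_error(feature_table(as.data.frame(X)[0, ], character(0)), "empty")
  Xbad <- X; colnames(Xbad) <- rev(hrv_feature_names)
  expect_error(feature_table(as.data.frame(Xbad), "a"), "order")
})

test_that("run configs load from YAML and JSON", {
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("noise_ratio: 0.2", "ensemble_size: 50"), fy)
  expect_equal(read_run_config(fy)$ensemble_size, 50)
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"renen_q": 2, "impe_s": 3}', fj)
  expect_equal(read_run_config(fj)$impe_s, 3)
})
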