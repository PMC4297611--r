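# data model, epoch extraction, and file round trips

test_that("recording constructor enforces its invariants", {
  expect_error(eeg_recording(rnorm(100), rnorm(99)), "same length")
  expect_error(eeg_recording(rnorm(100), rnorm(100), fs = 0), "fs")
  expect_error(eeg_recording(c(1, NA, 3), c(1, 2, 3)), "finite")
  expect_error(eeg_recording(numeric(0), numeric(0)), "samples")
  rec <- eeg_recording(rnorm(1000), rnorm(1000), fs = 500, t0 = -86400)
  expect_s3_class(rec, "eeg_recording")
  expect_equal(duration_s(rec), 2)
})

test_that("epoch extraction follows the half-open sample-count convention", {
  set.seed(1)
  rec <- eeg_recording(rnorm(150000), rnorm(150000), fs = 500)
  ep <- extract_epoch(rec, "both", 0, 300)
  expect_equal(nrow(ep$x), 150000)  # 300 s at 500 Hz
  expect_equal(ncol(ep$x), 2)
  expect_error(extract_epoch(rec, "both", 10, 10), "greater")
  expect_error(extract_epoch(rec, "both", 100, 301), "outside")
  # adjacent epochs partition exactly: [0,1) + [1,2) == [0,2)
  a <- extract_epoch(rec, "ipsi", 0, 1)$x
  b <- extract_epoch(rec, "ipsi", 1, 2)$x
  ab <- extract_epoch(rec, "ipsi", 0, 2)$x
  expect_identical(rbind(a, b)[, 1], ab[, 1])
  # extraction is idempotent
  expect_identical(extract_epoch(rec, "contra", 3.2, 7.9)$x,
                   extract_epoch(rec, "contra", 3.2, 7.9)$x)
})

test_that("CSV round trip preserves data to declared precision and metadata", {
  set.seed(42)
  n <- 5000
  rec <- eeg_recording(rnorm(n, sd = 0.1), rnorm(n, sd = 0.1), fs = 500,
                       subject_id = "R7", group = "blood", t0 = -3600,
                       temperature = telemetry_series(37 + rnorm(10, 0, 0.1),
                                                      interval_s = 1,
                                                      start_s = -3600),
                       activity = telemetry_series(runif(10), interval_s = 1,
                                                   start_s = -3600))
  path <- withr::local_tempfile(fileext = ".csv")
  write_eeg_csv(rec, path)
  back <- read_eeg_csv(path)
  expect_lt(max(abs(back$ipsi - rec$ipsi)), 1e-6)      # declared precision
  expect_lt(max(abs(back$contra - rec$contra)), 1e-6)
  expect_identical(back$subject_id, "R7")
  expect_identical(back$group, "blood")
  expect_equal(back$fs, 500)
  expect_equal(back$t0, -3600)
  expect_equal(back$temperature$values, rec$temperature$values, tolerance = 1e-6)
  expect_equal(back$temperature$interval_s, 1)
  expect_equal(back$activity$start_s, -3600)
})

test_that("container round trip is bit exact", {
  set.seed(7)
  rec <- eeg_recording(rnorm(5000), rnorm(5000), fs = 500, subject_id = "X1",
                       group = "iron", t0 = 120,
                       temperature = telemetry_series(rnorm(5, 37), 60, 100))
  path <- withr::local_tempfile(fileext = ".eegrec")
  write_eeg_rec(rec, path)
  back <- read_eeg_rec(path)
  expect_identical(back$ipsi, rec$ipsi)
  expect_identical(back$contra, rec$contra)
  expect_identical(back$temperature$values, rec$temperature$values)
  expect_identical(back$subject_id, rec$subject_id)
  expect_equal(back$fs, rec$fs)
  # load_recording dispatches on extension
  expect_identical(load_recording(path)$ipsi, rec$ipsi)
})

test_that("malformed CSV inputs are rejected with format errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# fs: 500", "time_s,ipsi_mv", "0.000,0.1", "0.002,0.2"), path)
  expect_error(read_eeg_csv(path), "missing column")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,ipsi_mv,contra_mv", "0,0.1,0.1"), path2)
  expect_error(read_eeg_csv(path2), "fs")
  expect_error(read_eeg_csv(file.path(tempdir(), "nope.csv")), "not found")
  expect_error(read_eeg_rec(path), "not an EEG container")
})

test_that("generated recordings round trip with duration matching the config", {
  bg <- generate_background(synth_config(duration_s = 12, seed = 5))
  expect_equal(duration_s(bg$recording), 12)
  path <- withr::local_tempfile(fileext = ".eegrec")
  write_eeg_rec(bg$recording, path)
  expect_identical(read_eeg_rec(path)$ipsi, bg$recording$ipsi)
})
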