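test_that("CSV recordings parse with uniform spacing and validity rules", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,spo2", "0,97", "4,97", "8,96", "12,97"), p)
  rec <- read_recording(p)
  expect_s3_class(rec, "oximetry_recording")
  expect_length(rec$spo2, 4)
  expect_equal(rec$sample_interval_s, 4)
  expect_true(all(rec$valid))
  expect_equal(rec$spo2, c(97, 97, 96, 97))

  # missing-data marker and out-of-physical-range values are masked, not dropped
  writeLines(c("t_s,spo2", "0,97", "4,—", "8,130", "12,97"), p)
  rec <- read_recording(p)
  expect_length(rec$spo2, 4)
  expect_equal(rec$valid, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(rec$spo2[3], 130)  # value preserved under the mask
})

test_that("malformed files are rejected with informative errors", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_s,sat", "0,97", "4,97"), p)
  expect_error(read_recording(p), "spo2")
  writeLines(c("t_s,spo2", "0,97", "4,97", "9,96", "12,97"), p)
  expect_error(read_recording(p), "row 3")
  expect_error(read_recording(file.path(tempdir(), "nope.csv")), "no such file")
})

test_that("write/read round-trip preserves SpO2 values and the validity mask", {
  rec <- oximetry_recording(c(97, 96.5, NA, 94, 130, 97),
                            valid = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_identical(back$valid, rec$valid)
  expect_equal(back$spo2[back$valid & !is.na(back$spo2)],
               rec$spo2[rec$valid & !is.na(rec$spo2)])
  expect_equal(back$spo2[c(1, 2, 4, 6)], rec$spo2[c(1, 2, 4, 6)])
})

test_that("EDF round-trip recovers the SpO2 channel at its sampling rate", {
  x <- round(runif(160, 90, 99), 1)
  x[c(10, 50)] <- NA
  p <- withr::local_tempfile(fileext = ".edf")
  noxi:::write_edf_spo2(p, x, sample_interval_s = 4)
  rec <- read_recording(p)
  expect_equal(rec$sample_interval_s, 4)
  expect_equal(rec$spo2[rec$valid], x[!is.na(x)], tolerance = 1e-9)
  expect_false(any(rec$valid[c(10, 50)]))
})

test_that("trimming sets a half-open sleep window", {
  rec <- oximetry_recording(rep(97, 8 * 900))  # 8 h at 4 s
  trimmed <- trim_to_sleep(rec, 0.5 * 3600, 7.5 * 3600)
  expect_equal(quality_check(trimmed)$duration_h, 7.0)
  expect_error(trim_to_sleep(rec, 3600, 3600), "window")
  expect_error(trim_to_sleep(rec, -1, 3600), "window")
  # no trim: the full recording is analyzed
  expect_equal(quality_check(rec)$duration_h, 8.0)
})

test_that("quality gate applies duration and artifact thresholds", {
  ok <- oximetry_recording(rep(97, round(6.7 * 900)),
                           valid = runif(round(6.7 * 900)) > 0.004)
  q <- quality_check(ok)
  expect_true(q$passes)
  expect_length(q$reasons, 0)

  short <- oximetry_recording(rep(97, round(5.7 * 900)))
  q <- quality_check(short)
  expect_false(q$passes)
  expect_equal(q$reasons, "duration")

  n <- 7 * 900
  noisy <- oximetry_recording(rep(97, n),
                              valid = seq_len(n) > 0.032 * n)
  q <- quality_check(noisy)
  expect_false(q$passes)
  expect_equal(q$reasons, "artifact")
})

test_that("quality gate depends only on the mask and window, not values", {
  n <- 6.5 * 900
  valid <- runif(n) > 0.01
  a <- quality_check(oximetry_recording(rep(97, n), valid = valid))
  b <- quality_check(oximetry_recording(runif(n, 85, 99), valid = valid))
  expect_equal(a$duration_h, b$duration_h)
  expect_equal(a$artifact_pct, b$artifact_pct)
  expect_equal(a$passes, b$passes)
})

test_that("trimming then computing equals computing on a pre-sliced signal", {
  set.seed(11)
  g <- generate_recording(simulation_config(duration_h = 7, event_rate_per_h = 12),
                          seed = 11)
  rec <- g$recording
  trimmed <- trim_to_sleep(rec, 1800, 7 * 3600 - 1800)
  idx <- sleep_window(trimmed)
  sliced <- oximetry_recording(rec$spo2[idx], rec$sample_interval_s,
                               valid = rec$valid[idx])
  expect_equal(compute_csa(trimmed), compute_csa(sliced))
  expect_equal(as.numeric(compute_sse(trimmed)), as.numeric(compute_sse(sliced)))
})
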