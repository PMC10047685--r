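test_that("identical config and seed reproduce the recording exactly", {
  cfg <- simulation_config(duration_h = 6.2, event_rate_per_h = 12)
  a <- generate_recording(cfg, seed = 123)
  b <- generate_recording(cfg, seed = 123)
  expect_identical(a$recording$spo2, b$recording$spo2)
  expect_identical(a$recording$valid, b$recording$valid)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("zero-severity noiseless config degenerates to a flat record", {
  cfg <- simulation_config(duration_h = 6, event_rate_per_h = 0, noise_sd = 0,
                           baseline_drift_sd = 0, baseline_spo2 = 100,
                           artifact_rate = 0)
  g <- generate_recording(cfg, seed = 1)
  expect_true(all(g$recording$spo2 == 100))
  expect_equal(compute_csa(g$recording), 100)
  expect_equal(as.numeric(compute_sse(g$recording)), 0)
  expect_equal(nrow(g$truth$events), 0)
})

test_that("ground-truth events are recovered by the detector", {
  cfg <- simulation_config(duration_h = 6, event_rate_per_h = 17,
                           depth_min_pct = 4)
  g <- generate_recording(cfg, seed = 202)
  expect_equal(g$truth$true_rate_per_h * 6, nrow(g$truth$events))
  b <- track_baseline(g$recording)
  ev <- detect_desaturations(g$recording, b, 3)
  hit <- vapply(seq_len(nrow(g$truth$events)), function(k) {
    any(ev$start_s < g$truth$events$end_s[k] &
          ev$end_s > g$truth$events$start_s[k])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})

test_that("noise alone rarely produces qualifying desaturations", {
  cfg <- simulation_config(duration_h = 6, event_rate_per_h = 0)
  odi <- vapply(1:30, function(s) {
    g <- generate_recording(cfg, seed = 700 + s)
    b <- track_baseline(g$recording)
    compute_odi(detect_desaturations(g$recording, b, 3),
                valid_hours(g$recording))
  }, numeric(1))
  expect_gte(mean(odi < 1), 0.95)
})

test_that("every 4% event is also a 3% event on simulated recordings", {
  for (s in 1:5) {
    g <- generate_recording(simulation_config(duration_h = 6,
                                              event_rate_per_h = 20),
                            seed = 300 + s)
    b <- track_baseline(g$recording)
    e3 <- detect_desaturations(g$recording, b, 3)
    e4 <- detect_desaturations(g$recording, b, 4)
    expect_lte(nrow(e4), nrow(e3))
    # each 4% event lies inside some 3% event
    inside <- vapply(seq_len(nrow(e4)), function(k) {
      any(e3$start_index <= e4$start_index[k] & e3$end_index >= e4$end_index[k])
    }, logical(1))
    expect_true(all(inside))
  }
})

test_that("paired cohorts share subjects and correlate across visits", {
  co <- generate_paired_cohort(8, seed = 42)
  expect_length(co$pre, 8)
  expect_length(co$post, 8)
  expect_equal(vapply(co$pre, function(g) g$recording$visit, ""),
               rep("pre", 8))
  expect_identical(generate_paired_cohort(8, seed = 42)$pre[[3]]$recording$spo2,
                   co$pre[[3]]$recording$spo2)
  expect_error(generate_paired_cohort(1), "subjects")
})

test_that("overload that cannot be placed raises a generation error", {
  cfg <- simulation_config(duration_h = 6, event_rate_per_h = 400,
                           plateau_min_s = 120)
  expect_error(generate_recording(cfg, seed = 5), "capacity")
})
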