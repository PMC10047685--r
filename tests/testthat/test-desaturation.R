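test_that("run-length event rule: depth, duration and threshold behavior", {
  base <- rep(97, 200)

  expect_equal(nrow(detect_desaturations(oximetry_recording(base), base, 3)), 0)

  # 12 s at 93 (3 samples): exactly one event at both thresholds
  x <- base; x[50:52] <- 93
  rec <- oximetry_recording(x)
  for (thr in c(3, 4)) {
    ev <- detect_desaturations(rec, base, thr)
    expect_equal(nrow(ev), 1)
    expect_equal(ev$depth, 4)
    expect_equal(ev$duration_s, 12)
    expect_equal(ev$nadir_spo2, 93)
  }

  # 8 s at 93 (2 samples): below the 10 s minimum
  x <- base; x[50:51] <- 93
  expect_equal(nrow(detect_desaturations(oximetry_recording(x), base, 3)), 0)

  expect_error(detect_desaturations(oximetry_recording(base), base[-1], 3),
               "aligned")
})

test_that("short invalid gaps are bridged, long gaps split events", {
  base <- rep(97, 100)
  x <- base
  x[40:49] <- 93
  valid <- rep(TRUE, 100)
  valid[44:45] <- FALSE  # 8 s gap inside the event
  rec <- oximetry_recording(x, valid = valid)
  ev <- detect_desaturations(rec, base, 3, max_gap_s = 30)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 40)

  ev2 <- detect_desaturations(rec, base, 3, max_gap_s = 4)
  expect_equal(nrow(ev2), 2)
})

test_that("production detector matches the exhaustive run-scan oracle", {
  set.seed(402)
  for (i in 1:200) {
    rec <- random_short_recording()
    b <- track_baseline(rec)
    ev <- detect_desaturations(rec, b, 3, min_duration_s = 10, max_gap_s = 30)
    or <- oracle_detect(rec$spo2, rec$valid, b, 3,
                        min_samples = 3L, gmax = 7L)
    expect_equal(ev$start_index, or$start)
    expect_equal(ev$end_index - 1L, or$end)
  }
})

test_that("events and indices are invariant to a constant SpO2 shift", {
  set.seed(9)
  g <- generate_recording(simulation_config(duration_h = 6, event_rate_per_h = 15,
                                            baseline_spo2 = 94),
                          seed = 9)
  rec <- g$recording
  shifted <- oximetry_recording(pmin(rec$spo2 + 2, 100), rec$sample_interval_s,
                                valid = rec$valid)
  b1 <- track_baseline(rec)
  b2 <- track_baseline(shifted)
  e1 <- detect_desaturations(rec, b1, 3)
  e2 <- detect_desaturations(shifted, b2, 3)
  expect_equal(e1$start_index, e2$start_index)
  expect_equal(e1$end_index, e2$end_index)
  expect_equal(e1$depth, e2$depth)
})

test_that("ODI is events per analyzed hour", {
  ev <- data.frame(start_s = 1:12)
  expect_equal(compute_odi(ev, 6), 2)
  expect_equal(compute_odi(ev[0, , drop = FALSE], 6), 0)
  expect_equal(compute_odi(data.frame(x = 1:107)[1:107, , drop = FALSE], 6),
               17.83, tolerance = 1e-3)
  expect_error(compute_odi(ev, 0), "analyzed_hours")
})

test_that("cluster grouping follows the 5-events-in-a-period rule", {
  expect_equal(nrow(detect_clusters(detect_desaturations(
    oximetry_recording(rep(97, 100)), rep(97, 100), 3))), 0)

  rec5 <- make_trace(dips = dip_burst(600, 5, 92, duration_s = 20, gap_s = 160))
  b <- track_baseline(rec5)
  ev <- detect_desaturations(rec5, b, 4)
  expect_equal(nrow(ev), 5)
  cl <- detect_clusters(ev)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$event_count, 5)
  expect_true(cl$window_duration_s >= 600 && cl$window_duration_s <= 1800)

  rec4 <- make_trace(dips = dip_burst(600, 4, 92, duration_s = 20, gap_s = 120))
  ev4 <- detect_desaturations(rec4, track_baseline(rec4), 4)
  expect_equal(nrow(ev4), 4)
  expect_equal(nrow(detect_clusters(ev4)), 0)
})

test_that("McGill score follows the cluster/nadir rule table", {
  score_of <- function(rec) {
    b <- track_baseline(rec)
    ev <- detect_desaturations(rec, b, 4)
    assign_mos(ev, detect_clusters(ev))
  }
  m1 <- score_of(mos_trace("inconclusive"))
  expect_equal(m1$score, 1L)
  expect_equal(m1$n_clusters, 0L)

  m2 <- score_of(mos_trace("mild"))
  expect_equal(m2$n_clusters, 3L)
  expect_equal(m2$n_below_90, 3L)
  expect_equal(m2$n_below_85, 0L)
  expect_equal(m2$score, 2L)

  m4 <- score_of(mos_trace("severe"))
  expect_equal(m4$n_below_80, 3L)
  expect_equal(m4$score, 4L)
})

test_that("McGill score is monotone as injected nadirs deepen", {
  scores <- vapply(c(88, 83, 78), function(nadir) {
    dips <- rbind(dip_burst(600, 5, c(nadir, 92, 92, 92, 92)),
                  dip_burst(3600, 5, c(nadir, 92, 92, 92, 92)),
                  dip_burst(6600, 5, c(nadir, 92, 92, 92, 92)))
    rec <- make_trace(dips = dips)
    ev <- detect_desaturations(rec, track_baseline(rec), 4)
    assign_mos(ev, detect_clusters(ev))$score
  }, integer(1))
  expect_equal(scores, c(2L, 3L, 4L))
  expect_true(all(diff(scores) >= 0))
})
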