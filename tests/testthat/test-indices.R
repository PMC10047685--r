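test_that("CSA hand-computed values: all-100, split, constant-95", {
  expect_equal(compute_csa(oximetry_recording(rep(100, 500))), 100)
  expect_equal(compute_csa(oximetry_recording(rep(c(100, 99), 250))), 150)
  expect_equal(compute_csa(oximetry_recording(rep(95, 500))), 600)
})

test_that("CSA is minimal only at all-100 and monotone under lowering", {
  x <- rep(100, 200)
  expect_equal(compute_csa(oximetry_recording(x)), 100)
  x[1] <- 99
  expect_gt(compute_csa(oximetry_recording(x)), 100)

  set.seed(21)
  for (i in 1:20) {
    v <- sample(90:100, 150, replace = TRUE)
    before <- compute_csa(oximetry_recording(v))
    j <- sample(150, 1)
    v2 <- v
    v2[j] <- v[j] - sample(0:5, 1)
    expect_gte(compute_csa(oximetry_recording(v2)), before)
  }
})

test_that("CSA ignores invalid samples and respects the sleep window", {
  v <- c(rep(100, 50), rep(90, 10))
  valid <- c(rep(TRUE, 50), rep(FALSE, 10))
  expect_equal(compute_csa(oximetry_recording(v, valid = valid)), 100)
  expect_error(compute_csa(oximetry_recording(rep(97, 5), valid = rep(FALSE, 5))),
               "valid")
})

test_that("sample entropy: constant series is zero, short series rejected", {
  expect_equal(compute_sse(oximetry_recording(rep(96, 50))), 0)
  expect_error(compute_sse(oximetry_recording(c(96, 97, 98))), "samples")
})

test_that("optimized sample entropy equals the naive reference", {
  set.seed(33)
  for (i in 1:10) {
    x <- round(96 + cumsum(rnorm(300, 0, 0.5)) * 0.3 + rnorm(300, 0, 0.5))
    x <- pmin(pmax(x, 80), 100)
    rec <- oximetry_recording(x)
    r <- 0.2 * sd(x)
    expect_equal(as.numeric(compute_sse(rec)), naive_sampen(x, 2, r),
                 tolerance = 1e-12)
  }
})

test_that("sorting a series can only reduce its sample entropy", {
  set.seed(44)
  for (i in 1:8) {
    x <- round(runif(300, 90, 100))
    sse <- as.numeric(compute_sse(oximetry_recording(x)))
    sse_sorted <- as.numeric(compute_sse(oximetry_recording(sort(x))))
    expect_lte(sse_sorted, sse)
  }
})

test_that("unmatched extensions return the flagged finite upper bound", {
  x <- c(1, 2, 1, 2, 5) * 10  # one m-template pair, extensions diverge
  rec <- oximetry_recording(x)
  out <- compute_sse(rec)
  expect_true(isTRUE(attr(out, "upper_bounded")))
  expect_equal(as.numeric(out), -log(1 / 2))
})

test_that("sample entropy is stable across record lengths on stationary noise", {
  set.seed(55)
  d <- replicate(6, {
    x <- round(96 + rnorm(5000, 0, 0.8))
    a <- as.numeric(compute_sse(oximetry_recording(x[1:1000])))
    b <- as.numeric(compute_sse(oximetry_recording(x)))
    a - b
  })
  expect_lt(abs(mean(d)), 0.1)
})

test_that("summary of a perfect recording is fully degenerate", {
  rec <- oximetry_recording(rep(100, 6 * 900))
  s <- summarize_recording(rec)
  expect_equal(s$mean_spo2, 100)
  expect_equal(s$sd_spo2, 0)
  expect_equal(s$odi3, 0)
  expect_equal(s$odi4, 0)
  expect_equal(s$mos, 1L)
  expect_equal(s$csa, 100)
  expect_equal(s$sse, 0)
  expect_true(s$quality_pass)
})

test_that("summary recovers an injected event rate", {
  g <- generate_recording(simulation_config(duration_h = 6, event_rate_per_h = 17),
                          seed = 77)
  s <- summarize_recording(g$recording)
  expect_equal(s$odi3, g$truth$true_rate_per_h, tolerance = 0.15)
  expect_lte(s$odi4, s$odi3)
  expect_gt(s$csa, 100)
})

test_that("quality-failing recordings require force and warn", {
  rec <- oximetry_recording(rep(97, 900))  # 1 h only
  expect_error(summarize_recording(rec), "quality")
  expect_warning(s <- summarize_recording(rec, force = TRUE), "quality")
  expect_false(s$quality_pass)
})
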