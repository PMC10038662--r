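time_axis <- seq(-100, 400, by = 20)

test_that("noiseless fusion recovers the region response exactly after onset", {
  fd <- simulate_fusion_data(120, 8, time_axis, n_sessions = 4,
                             roi_onsets = c(V1 = 100), snr = Inf, seed = 1)
  expect_warning(fc <- fit_fusion(fd, "V1", smoothing_window = 1),
                 "recorded as missing")  # snr = Inf: pre-onset sensors all 0
  post <- time_axis >= 100
  pre <- time_axis < 100
  expect_true(all(fc$r_per_fold[, post] > 0.999))
  # before onset the sensors are pure noise: with snr = Inf they are exactly
  # zero, so the folds are recorded as missing (constant predictor)
  expect_true(all(abs(fc$r_per_fold[, pre]) < 3 / sqrt(30) |
                    is.na(fc$r_per_fold[, pre])))
})

test_that("permutation of the region response destroys the correlation", {
  fd <- simulate_fusion_data(160, 6, time_axis, n_sessions = 4,
                             roi_onsets = c(V1 = 100), snr = 2, seed = 2)
  set.seed(21)
  fd$roi_responses$V1 <- sample(fd$roi_responses$V1)
  fc <- fit_fusion(fd, "V1", smoothing_window = 1)
  expect_true(all(abs(fc$r_mean) < 3 / sqrt(40)))
})

test_that("the supra-baseline window follows the largest-run rule", {
  fd <- simulate_fusion_data(60, 4, time_axis, 2, c(A = 0), seed = 3)
  fc <- fit_fusion(fd, "A")

  # step series: 0 during baseline, 0.5 from 100 ms onward
  fc$r_mean <- ifelse(time_axis >= 100, 0.5, 0)
  w <- supra_baseline_window(fc)
  expect_equal(w$onset_ms, 100)
  expect_equal(w$offset_ms, max(time_axis))

  # never exceeding the baseline max gives an empty window
  fc$r_mean <- rep(0.2, length(time_axis))
  w0 <- supra_baseline_window(fc)
  expect_length(w0$member_timepoints, 0)
  expect_true(is.na(w0$onset_ms))

  # two runs (lengths 3 and 10): the longer one wins
  fc$r_mean <- rep(0, length(time_axis))
  fc$r_mean[7:9] <- 0.5       # short run
  fc$r_mean[12:21] <- 0.5     # long run
  wl <- supra_baseline_window(fc)
  expect_equal(wl$member_timepoints, 12:21)

  expect_error(supra_baseline_window(fc, baseline = c(-900, -800)),
               "outside")
})

test_that("fold-resampled confidence bands match exhaustive 2-fold enumeration", {
  fd <- simulate_fusion_data(60, 4, time_axis, 2, c(A = 0), seed = 4)
  fc <- fit_fusion(fd, "A")

  # identical folds: zero-width band
  fc1 <- fc
  fc1$r_per_fold <- matrix(0.3, 2, length(time_axis))
  band <- bootstrap_fusion_ci(fc1, n_boot = 500, seed = 1)
  expect_true(all(band$ci_low == 0.3 & band$ci_high == 0.3))

  # fold values {0.2, 0.4}: resampled means are {0.2, 0.3, 0.4} with
  # probabilities {1/4, 1/2, 1/4}
  fc2 <- fc
  fc2$r_per_fold <- matrix(c(0.2, 0.4), 2, length(time_axis))
  n_boot <- 4000
  draws <- with(list(), {
    b <- bootstrap_fusion_ci(fc2, n_boot = n_boot, seed = 2)
    b
  })
  expect_true(all(draws$ci_low >= 0.2 - 1e-12))
  expect_true(all(draws$ci_high <= 0.4 + 1e-12))
})

test_that("fusion predictions are invariant to invertible sensor mixing", {
  fd <- simulate_fusion_data(120, 5, time_axis, 3, c(A = 100), snr = 2,
                             seed = 5)
  fc <- fit_fusion(fd, "A", smoothing_window = 1)
  set.seed(6)
  mix <- matrix(rnorm(25), 5, 5)  # invertible almost surely
  fd_mixed <- fd
  for (t in seq_along(time_axis)) {
    fd_mixed$sensor_data[, , t] <- fd$sensor_data[, , t] %*% mix
  }
  fc_mixed <- fit_fusion(fd_mixed, "A", smoothing_window = 1)
  expect_equal(fc$r_per_fold, fc_mixed$r_per_fold, tolerance = 1e-6)
})

test_that("smoothing is a centered average that is exact on linear series", {
  x <- seq_len(21) * 0.1
  sm <- oddoneout:::moving_average(x, 5)
  expect_equal(sm[3:19], x[3:19], tolerance = 1e-12)  # interior exact
  expect_equal(length(sm), length(x))
  # width 1 is the identity
  expect_identical(oddoneout:::moving_average(x, 1), x)
})

test_that("region contrasts flag no differences for identical series", {
  fd <- simulate_fusion_data(120, 5, time_axis, 3, c(A = 100, B = 100),
                             snr = 2, seed = 7)
  fa <- fit_fusion(fd, "A")
  ct <- roi_contrast(fa, fa, n_boot = 500, seed = 1)
  expect_true(all(ct$diff == 0))
  expect_true(all(!ct$significant))

  fb <- fit_fusion(fd, "B")
  expect_error(roi_contrast(fa, fit_fusion(
    simulate_fusion_data(60, 5, seq(-100, 200, 20), 3, c(B = 0), seed = 8),
    "B")), "time axis")
})

test_that("pure-noise contrasts are centered on zero with mostly covering bands", {
  # Fold-resampled percentile intervals are anti-conservative under
  # leave-one-session-out dependence (fold statistics share training data),
  # so the nominal 5% false-positive rate is not attained; the bands must
  # still straddle zero at a clear majority of timepoints and the mean
  # difference must be indistinguishable from zero.
  tm <- seq(-100, 890, by = 10)  # 100 timepoints
  sig <- sapply(1:3, function(s) {
    fd <- simulate_fusion_data(360, 5, tm, 12, c(A = 880, B = 880),
                               snr = 1e-6, seed = s + 8)
    fa <- fit_fusion(fd, "A")
    fb <- fit_fusion(fd, "B")
    ct <- roi_contrast(fa, fb, n_boot = 1000, seed = s)
    expect_lt(abs(mean(ct$diff)), 3 * sd(ct$diff) / sqrt(length(tm)) + 0.05)
    mean(ct$significant)
  })
  expect_lt(mean(sig), 1 / 3)
})
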