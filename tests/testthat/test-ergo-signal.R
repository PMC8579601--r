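test_that("exercise-window selection follows the protocol rules", {
  # medium risk: the whole constant-workload exercise phase
  med <- make_session(rep(30, 90))
  wm <- select_exercise_window(med, "medium")
  expect_equal(nrow(wm$observations), 90)
  # minimal risk, 30 constant + 60 ramp points: the 60 ramp points
  pw <- make_session(c(rep(40, 30), 40 + seq_len(60)))
  wp <- select_exercise_window(pw, "minimal")
  expect_equal(nrow(wp$observations), 60)
  expect_true(all(wp$observations$workload > 40))
  # a pure ramp keeps every point
  pr <- make_session(40 + seq_len(50))
  expect_equal(nrow(select_exercise_window(pr, "small")$observations), 50)
  # exclusions
  expect_equal(select_exercise_window(pw, "high")$reason, "bad_risk")
  expect_equal(select_exercise_window(pw, "minimal", method = "Treadmill")$reason,
               "bad_method")
  expect_equal(select_exercise_window(make_session(rep(40, 50)),
                                      "minimal")$reason, "no_ramp")
})

test_that("cadence band and observation-count rules use inclusive boundaries", {
  s <- make_session(40 + seq_len(30))
  s$cadence <- c(34, 126, 35, 125, rep(60, 26))
  qc <- apply_qc_filters(s)
  expect_equal(nrow(qc$observations), 28)
  expect_equal(qc$n_removed, 2)
  expect_true(all(c(35, 125) %in% qc$observations$cadence))
  expect_null(qc$reason)
  # 19 survivors excluded, 20 retained
  s19 <- make_session(40 + seq_len(19))
  expect_equal(apply_qc_filters(s19)$reason, "low_cadence_n")
  s20 <- make_session(40 + seq_len(20))
  expect_null(apply_qc_filters(s20)$reason)
  expect_equal(apply_qc_filters(NULL)$reason, "low_cadence_n")
})

test_that("zero-phase Butterworth filter preserves trend and removes noise", {
  # DC preservation
  y <- lowpass_filter(rep(100, 50))
  expect_equal(as.numeric(y), rep(100, 50), tolerance = 1e-12)
  # affine signals pass through exactly, and re-filtering changes nothing
  line <- 70 + 0.5 * (1:60)
  f1 <- as.numeric(lowpass_filter(line))
  expect_equal(f1, line, tolerance = 1e-12)
  f2 <- as.numeric(lowpass_filter(f1))
  expect_lt(sqrt(mean((f2 - f1)^2)), 1e-6)
  # Nyquist-frequency component attenuated below 1% of its amplitude
  x <- 100 + rep(c(10, -10), 30)
  yf <- as.numeric(lowpass_filter(x, order = 4, cutoff = 0.1))
  alt_amp <- abs(2 * mean((yf - mean(yf)) * (-1)^seq_along(yf)))
  expect_lt(alt_amp, 0.1)
  # filtering brings a noisy ramp closer to its true trend
  set.seed(42)
  truth <- 70 + 0.5 * (1:90)
  noisy <- truth + rnorm(90, 0, 3)
  filt <- as.numeric(lowpass_filter(noisy))
  expect_lt(sqrt(mean((filt - truth)^2)), sqrt(mean((noisy - truth)^2)))
  # degraded mode for short sequences
  short <- lowpass_filter(rnorm(10))
  expect_false(attr(short, "filtered"))
  expect_length(short, 10)
})

test_that("age-predicted maximum heart rate follows 208 - 0.7 * age", {
  expect_equal(age_predicted_max_hr(40), 180)
  expect_equal(age_predicted_max_hr(69), 159.7)
  expect_error(age_predicted_max_hr(0), "age must be positive")
})

test_that("workload extrapolation matches the closed-form line", {
  # endpoints (90 bpm, 40 W) and (150 bpm, 100 W), age 40, weight 80
  v <- derive_vo2max(c(90, 150), c(40, 100), age = 40, weight = 80,
                     mode = "endpoints")
  expect_equal(v$wl_hr_max, 130)
  expect_equal(v$vo2max, 1.625)
  # regression mode agrees on exactly collinear input
  hr <- seq(90, 150, length.out = 20)
  wl <- 40 + (hr - 90)  # slope 1 W/bpm
  vr <- derive_vo2max(hr, wl, age = 40, weight = 80)
  expect_equal(vr$wl_hr_max, 130)
  # constant workload: degenerate extrapolation, flagged
  vd <- derive_vo2max(c(90, 110, 130), rep(40, 3), age = 50, weight = 80)
  expect_equal(vd$vo2max, 0.5)
  expect_true("degenerate_workload" %in% vd$flags)
  # vo2max scales as 1/weight
  v2 <- derive_vo2max(c(90, 150), c(40, 100), age = 40, weight = 160,
                      mode = "endpoints")
  expect_equal(v2$vo2max, v$vo2max / 2)
  # equal endpoints: undefined slope
  ve <- derive_vo2max(c(100, 100), c(40, 60), age = 40, weight = 80,
                      mode = "endpoints")
  expect_equal(ve$reason, "equal_endpoints")
})

test_that("heart-rate slope estimation is exact OLS", {
  tr <- 1:30
  s <- derive_slope(70 + 0.8 * tr, tr)
  expect_equal(s$slope, 0.8)
  expect_equal(s$intercept, 70)
  expect_false(s$negative)
  # zero slope is retained (not 'negative')
  s0 <- derive_slope(rep(80, 25), 1:25)
  expect_equal(s0$slope, 0)
  expect_false(s0$negative)
  # agreement with the explicit normal-equations oracle
  set.seed(7)
  for (k in 1:5) {
    y <- 60 + 0.3 * tr + rnorm(30, 0, 2)
    s <- derive_slope(y, tr)
    o <- oracle_ols(tr, y)
    expect_equal(s$slope, o$beta[2], tolerance = 1e-10)
    expect_equal(s$intercept, o$beta[1], tolerance = 1e-10)
  }
  expect_error(derive_slope(c(1, 2), c(5, 5)), "identical")
})

test_that("slope estimates are unbiased under AR(1) noise", {
  set.seed(99)
  errs <- replicate(300, {
    tr <- 1:60
    rho <- 0.6; sd <- 3
    e <- numeric(60); e[1] <- rnorm(1, 0, sd)
    for (i in 2:60) e[i] <- rho * e[i - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
    y <- as.numeric(lowpass_filter(70 + 0.5 * tr + e))
    derive_slope(y, tr)$slope - 0.5
  })
  expect_lt(abs(mean(errs)), 4 * sd(errs) / sqrt(length(errs)))
})

test_that("cohort derivation recovers truth and accounts for every session", {
  cfg <- quiet_config()
  sim <- simulate_cohort(100, seed = 13, cfg)
  sim$cohort$risk_category[1:10] <- "high"
  traces <- simulate_traces(sim$cohort, sim$truth, seed = 13, cfg)
  crf <- derive_crf_phenotypes(traces, sim$cohort)
  expect_equal(nrow(crf$records), 90)
  expect_equal(nrow(crf$excluded), 10)
  expect_true(all(crf$excluded$reason == "bad_risk"))
  expect_equal(nrow(crf$records) + nrow(crf$excluded), nrow(sim$cohort))
  m <- merge(crf$records, sim$truth)
  expect_lt(max(abs(m$crf_vo2max - m$true_vo2max)), 1e-6)
  expect_true(all(m$crf_vo2max > 0))
  expect_true(all(m$n_trend >= 20))
})

test_that("derived phenotypes obey scale equivariance", {
  cfg <- quiet_config()
  sim <- simulate_cohort(3, seed = 17, cfg)
  traces <- simulate_traces(sim$cohort, sim$truth, seed = 17, cfg)
  base <- derive_crf_phenotypes(traces, sim$cohort)
  # multiplying workloads by c multiplies vo2max by c
  t2 <- traces; t2$workload <- 3 * t2$workload
  r2 <- derive_crf_phenotypes(t2, sim$cohort)
  expect_equal(r2$records$crf_vo2max, 3 * base$records$crf_vo2max,
               tolerance = 1e-9)
  # adding a constant to HR shifts the intercept, not the slope
  t3 <- traces; t3$heart_rate <- t3$heart_rate + 12
  r3 <- derive_crf_phenotypes(t3, sim$cohort)
  expect_equal(r3$records$crf_slope, base$records$crf_slope, tolerance = 1e-9)
  expect_equal(r3$records$intercept, base$records$intercept + 12,
               tolerance = 1e-9)
})

test_that("negative heart-rate slopes void the slope phenotype only", {
  ses <- make_session(40 + seq_len(30), hr = 150 - seq_len(30))
  cohort <- data.frame(participant_id = "P000001", sex = "male", age = 50,
                       weight = 80, risk_category = "minimal",
                       bike_method = "Bicycle", stringsAsFactors = FALSE)
  crf <- derive_crf_phenotypes(ses, cohort)
  expect_equal(nrow(crf$records), 1)
  expect_true(grepl("negative_slope", crf$records$qc_flags))
  expect_true(is.na(crf$records$crf_slope))
})
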