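# shared fixture: one frail walk recording with known ground truth
walk_fixture <- function(seed = 1, group = "frail") {
  generate_walk_trace(subject_profile(group), cohort_config(seed = seed),
                      seed = seed)
}

test_that("stand-still calibration applies the multiplier to the measured baseline", {
  g <- walk_fixture()
  filt <- lowpass_filter(g$trace)
  c3 <- calibrate_standstill(filt, multiplier = 3)
  c5 <- calibrate_standstill(filt, multiplier = 5)
  expect_equal(c3$threshold, 3 * c3$baseline_variance)
  expect_equal(c5$baseline_variance, c3$baseline_variance)
  expect_equal(c5$threshold / c3$threshold, 5 / 3)
  expect_gte(c3$threshold, c3$baseline_variance)
})

test_that("a noiseless constant prefix is a calibration error with remediation", {
  t <- seq(0, 10, by = 1 / 50)
  flat <- acceleration_trace(t, t * 0, t * 0, t * 0 + 1)
  expect_error(calibrate_standstill(flat), "degenerate.*noise floor|noise floor")
})

test_that("calibration errors when the prefix is shorter than 4 windows", {
  g <- walk_fixture()
  expect_error(calibrate_standstill(lowpass_filter(g$trace), standstill = 1.5),
               "4 windows")
})

test_that("threshold sits strictly below the walking-segment window variances", {
  g <- walk_fixture(seed = 4)
  filt <- lowpass_filter(g$trace)
  calib <- calibrate_standstill(filt)
  r <- resultant_acceleration(filt)
  r <- r - mean(r)
  w <- round(0.5 * filt$sampling_rate)
  vr <- rollvar_oracle(r, w)
  idx <- seq_along(vr)
  centers <- (filt$time[idx] + filt$time[idx + w - 1]) / 2
  gt <- g$ground_truth
  # windows fully inside the steady (post-ramp) part of the walk
  inside <- centers - 0.25 >= gt$walk_start_s + 0.6 &
    centers + 0.25 <= gt$walk_stop_s - 0.6
  expect_lt(calib$threshold, min(vr[inside]))
})

test_that("detected bounds match the generator ground truth within 0.2 s", {
  for (seed in c(2, 9, 23)) {
    g <- walk_fixture(seed = seed)
    filt <- lowpass_filter(g$trace)
    seg <- detect_walk_bounds(filt, calibrate_standstill(filt))
    expect_lt(abs(seg$start_time - g$ground_truth$walk_start_s), 0.2)
    expect_lt(abs(seg$stop_time - g$ground_truth$walk_stop_s), 0.2)
  }
})

test_that("detection agrees with an exhaustive sliding-window-variance scan", {
  g <- walk_fixture(seed = 6)
  filt <- lowpass_filter(g$trace)
  calib <- calibrate_standstill(filt)
  seg <- detect_walk_bounds(filt, calib)

  r <- resultant_acceleration(filt)
  r <- r - mean(r)
  fs <- filt$sampling_rate
  w <- round(0.5 * fs)
  vr <- rollvar_oracle(r, w)
  idx <- seq_along(vr)
  centers <- (filt$time[idx] + filt$time[idx + w - 1]) / 2
  above <- vr > calib$threshold
  need <- ceiling(0.5 * fs) + 1L
  runs <- rle(above)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= need)
  expect_equal(seg$start_time, centers[starts[ok[1]]])
  expect_equal(seg$stop_time, centers[ends[ok[length(ok)]]])
})

test_that("an all-quiet trace yields a no-walk error", {
  set.seed(11)
  t <- seq(0, 12, by = 1 / 50)
  quiet <- acceleration_trace(t, rnorm(length(t), 0, 0.02),
                              rnorm(length(t), 0, 0.02),
                              1 + rnorm(length(t), 0, 0.02))
  filt <- lowpass_filter(quiet)
  calib <- calibrate_standstill(filt, standstill = 12)
  expect_error(detect_walk_bounds(filt, calib), "no walk detected")
})

test_that("gait speed is distance over detected duration", {
  expect_equal(gait_speed(walk_segment(2, 7, distance = 5)), 1.0)
  expect_equal(gait_speed(walk_segment(1, 1 + 7.463, distance = 5)), 0.67,
               tolerance = 1e-4)
  g <- walk_fixture(seed = 14, group = "non-frail")
  feats <- extract_gait_features(g$trace)
  expect_lt(abs(feats$velocity - 0.98) / 0.98, 0.05)
})

test_that("gait speed is invariant to quiet padding around the recording", {
  g <- walk_fixture(seed = 5)
  base <- extract_gait_features(g$trace)

  tr <- g$trace
  fs <- tr$sampling_rate
  set.seed(99)
  n_pad <- 2 * fs
  pad <- function(n) rnorm(n, 0, 0.02)
  t2 <- seq(0, by = 1 / fs, length.out = length(tr$time) + 2 * n_pad)
  padded <- acceleration_trace(
    t2,
    c(pad(n_pad), tr$ap, pad(n_pad)),
    c(pad(n_pad), tr$ml, pad(n_pad)),
    c(1 + pad(n_pad), tr$v, 1 + pad(n_pad)),
    sampling_rate = fs)
  padded_feats <- extract_gait_features(padded, standstill = 2)
  expect_equal(padded_feats$velocity, base$velocity, tolerance = 0.03)
})
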