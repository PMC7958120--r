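test_that("walk ground truth follows distance / speed and seeding is exact", {
  cfg <- cohort_config(seed = 10)
  prof <- subject_profile("non-frail", true_gait_speed = 1.0)
  g <- generate_walk_trace(prof, cfg, seed = 42)
  gt <- g$ground_truth
  expect_equal(gt$walk_stop_s - gt$walk_start_s, 5.0)
  expect_equal(gt$speed, 1.0)

  g2 <- generate_walk_trace(prof, cfg, seed = 42)
  expect_identical(g$trace, g2$trace)
  g3 <- generate_walk_trace(prof, cfg, seed = 43)
  expect_false(identical(g$trace$v, g3$trace$v))
})

test_that("a walk shorter than 4 step cycles is rejected as unusable", {
  cfg <- cohort_config(seed = 1)
  fast <- subject_profile("non-frail", true_gait_speed = 2.5,
                          true_step_time = 0.7)
  expect_error(generate_walk_trace(fast, cfg, seed = 1),
               "unusable trial.*4 step cycles")
})

test_that("stance traces have duration x rate samples and reproduce under a seed", {
  cfg <- cohort_config(seed = 9, stance_duration = 30, sampling_rate = 50)
  prof <- subject_profile("frail")
  g <- generate_stance_trace(prof, cfg, seed = 5)
  expect_identical(length(g$trace$ml), 1500L)
  g2 <- generate_stance_trace(prof, cfg, seed = 5)
  expect_identical(g$trace, g2$trace)
  expect_error(generate_stance_trace(prof, cohort_config(stance_duration = 4),
                                     seed = 1),
               ">= 5 s")
})

test_that("pure periodic stance is regular; pure noise stance is complex", {
  cfg <- cohort_config(seed = 6)
  periodic <- subject_profile("frail", sway_regularity = 1)
  noise <- subject_profile("frail", sway_regularity = 0)
  apen_p <- approximate_entropy(generate_stance_trace(periodic, cfg,
                                                      seed = 1)$trace$ml)
  expect_lt(apen_p, 0.3)
  apen_n <- vapply(1:20, function(s) approximate_entropy(
    generate_stance_trace(noise, cfg, seed = s)$trace$ml), numeric(1))
  expect_gt(mean(apen_n), 1.0)
})

test_that("stance ApEn is non-increasing in sway regularity over seeds", {
  cfg <- cohort_config(seed = 3)
  grid <- c(0, 0.5, 0.75, 0.9, 1)
  means <- vapply(grid, function(reg) {
    prof <- subject_profile("frail", sway_regularity = reg)
    mean(vapply(1:20, function(s) approximate_entropy(
      generate_stance_trace(prof, cfg, seed = s)$trace$ml), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("generator calibration: extracted speed and step time track truth", {
  cfg <- cohort_config(seed = 1)
  for (grp in c("frail", "non-frail")) {
    prof <- subject_profile(grp)
    feats <- lapply(1:10, function(s) extract_gait_features(
      generate_walk_trace(prof, cfg, seed = s)$trace))
    speeds <- vapply(feats, `[[`, numeric(1), "velocity")
    steps <- vapply(feats, `[[`, numeric(1), "mean_step_time")
    expect_lt(abs(mean(speeds) - prof$true_gait_speed) / prof$true_gait_speed,
              0.05)
    expect_lt(abs(mean(steps) - prof$true_step_time) / prof$true_step_time,
              0.05)
  }
})

test_that("cohorts have the configured group split and latent-score structure", {
  cfg <- cohort_config(n_subjects = 16, frail_fraction = 0.5, seed = 2)
  coh <- generate_cohort(cfg)
  expect_identical(sum(coh$features$group == "frail"), 8L)
  expect_identical(nrow(coh$features), 16L)

  expect_error(generate_cohort(cohort_config(n_subjects = 1)), ">= 2")

  coh2 <- generate_cohort(cfg)
  expect_identical(coh, coh2)

  # zero score noise: latent equals the published-model prediction exactly
  cfg0 <- cohort_config(n_subjects = 12, score_noise_sd = 0, seed = 4)
  coh0 <- generate_cohort(cfg0)
  expect_equal(coh0$features$latent_score,
               predict_adverse_score(coh0$features), tolerance = 1e-12)

  # frail subjects are slower and carry higher latent scores on average
  frail <- coh$features$group == "frail"
  expect_lt(mean(coh$features$smartphone_velocity[frail]),
            mean(coh$features$smartphone_velocity[!frail]))
  expect_gt(mean(coh$features$latent_score[frail]),
            mean(coh$features$latent_score[!frail]))

  # outcome table flags are consistent with the recorded scores
  w <- outcome_weights()
  recomputed <- vapply(seq_len(16), function(i)
    outcome_score(coh$outcomes[i, names(w)]), numeric(1))
  expect_equal(coh$outcomes$outcome_score, recomputed)
})

test_that("refitting a zero-noise cohort recovers the published coefficients", {
  cfg <- cohort_config(n_subjects = 20, score_noise_sd = 0, seed = 5)
  coh <- generate_cohort(cfg)
  fit <- fit_adverse_model(coh$features, coh$features$latent_score)
  pub <- published_adverse_model()
  expect_equal(fit$intercept, pub$intercept, tolerance = 1e-6)
  expect_equal(fit$coefficients, pub$coefficients, tolerance = 1e-6)
  expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-9)
})

test_that("simulate_cohort_files writes traces, tables and a manifest", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, stance_duration = 10, seed = 3)
  manifest <- simulate_cohort_files(cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "features.csv")))
  expect_true(file.exists(file.path(dir, "outcomes.csv")))
  expect_length(manifest$subjects, 2)
  tr <- read_trace(file.path(dir, manifest$subjects[[1]]$walk))
  expect_s3_class(tr, "acceleration_trace")
  expect_identical(yaml::read_yaml(file.path(dir, "manifest.yaml"))$config$seed,
                   3L)
})
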