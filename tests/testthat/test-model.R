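test_that("the published model carries the exact printed parameters", {
  pub <- published_adverse_model()
  expect_identical(pub$provenance, "published")
  expect_identical(pub$intercept, 44.13)
  expect_identical(unname(pub$coefficients),
                   c(-26.96, -28.29, 13.33, -46.85, 5.35))
  expect_identical(names(pub$coefficients),
                   c("rms_ap", "rms_v", "apen_ml_cop", "apen_r_cop",
                     "step_time"))
})

test_that("score evaluation is exactly linear and sign-monotone", {
  pub <- published_adverse_model()
  zero <- data.frame(rms_ap = 0, rms_v = 0, apen_ml_cop = 0, apen_r_cop = 0,
                     step_time = 0)
  expect_equal(predict_adverse_score(zero, pub), 44.13)

  set.seed(8)
  x <- as.data.frame(matrix(runif(10), 2, 5,
                            dimnames = list(NULL, names(pub$coefficients))))
  for (a in c(0.25, 0.5, 0.8)) {
    blend <- x[1, ] * a + x[2, ] * (1 - a)
    expect_equal(predict_adverse_score(blend, pub),
                 a * predict_adverse_score(x[1, ], pub) +
                   (1 - a) * predict_adverse_score(x[2, ], pub),
                 tolerance = 1e-12)
  }
  up <- x[1, ]; up$apen_r_cop <- up$apen_r_cop + 0.1
  expect_lt(predict_adverse_score(up, pub), predict_adverse_score(x[1, ], pub))
  up <- x[1, ]; up$apen_ml_cop <- up$apen_ml_cop + 0.1
  expect_gt(predict_adverse_score(up, pub), predict_adverse_score(x[1, ], pub))
  up <- x[1, ]; up$step_time <- up$step_time + 0.1
  expect_gt(predict_adverse_score(up, pub), predict_adverse_score(x[1, ], pub))
})

test_that("a missing predictor raises an error naming the column", {
  row <- data.frame(rms_ap = 0.1, rms_v = 0.1, apen_ml_cop = 1,
                    step_time = 0.6)
  expect_error(predict_adverse_score(row), "apen_r_cop")
  row$apen_r_cop <- NA_real_
  expect_error(predict_adverse_score(row), "finite")
})

test_that("the held-out worked examples reproduce their reported scores", {
  tp <- example_test_patients()
  scores <- predict_adverse_score(tp)
  consistent <- c("ID02", "D25")
  sel <- tp$subject_id %in% consistent
  expect_true(all(abs(scores[sel] - tp$reported_score[sel]) <= 0.06))
  # the remaining printed rows are known transcription casualties
  expect_true(all(abs(scores[!sel] - tp$reported_score[!sel]) > 0.06))
})

test_that("OLS refit recovers arbitrary coefficient vectors from noiseless data", {
  set.seed(404)
  preds <- c("rms_ap", "rms_v", "apen_ml_cop", "apen_r_cop", "step_time")
  for (i in 1:5) {
    n <- 30
    X <- as.data.frame(matrix(rnorm(n * 5, 1, 0.5), n, 5,
                              dimnames = list(NULL, preds)))
    beta <- rnorm(5, 0, 20); alpha <- rnorm(1, 0, 10)
    y <- alpha + as.matrix(X) %*% beta
    fit <- fit_adverse_model(X, as.numeric(y))
    expect_equal(fit$intercept, alpha, tolerance = 1e-6)
    expect_equal(unname(fit$coefficients), beta, tolerance = 1e-6)
    expect_equal(fit$diagnostics$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("Mallows' Cp of the full model equals its parameter count", {
  cfg <- cohort_config(n_subjects = 25, score_noise_sd = 1, seed = 7)
  coh <- generate_cohort(cfg)
  fit <- fit_adverse_model(coh$features, coh$outcomes$outcome_score)
  expect_equal(fit$diagnostics$mallows_cp, 6, tolerance = 1e-9)
  sub <- fit_adverse_model(coh$features, coh$outcomes$outcome_score,
                           predictors = c("rms_ap", "rms_v"))
  expect_identical(sub$provenance, "refitted")
  expect_true(is.finite(sub$diagnostics$mallows_cp))
})

test_that("VIF agrees with the standard regression diagnostic", {
  skip_if_not_installed("car")
  cfg <- cohort_config(n_subjects = 40, seed = 9)
  coh <- generate_cohort(cfg)
  fit <- fit_adverse_model(coh$features, coh$features$latent_score)
  lmfit <- stats::lm(latent_score ~ rms_ap + rms_v + apen_ml_cop +
                       apen_r_cop + step_time, data = coh$features)
  expect_equal(unname(fit$diagnostics$vif), unname(car::vif(lmfit)),
               tolerance = 1e-8)
})

test_that("a duplicated predictor column raises a singular-design error", {
  cfg <- cohort_config(n_subjects = 20, seed = 11)
  coh <- generate_cohort(cfg)
  feats <- coh$features
  feats$rms_v <- feats$rms_ap
  expect_error(fit_adverse_model(feats, coh$features$latent_score),
               "singular design.*VIF")
})

test_that("too few rows for the requested predictors is an error", {
  cfg <- cohort_config(n_subjects = 6, seed = 12)
  coh <- generate_cohort(cfg)
  expect_error(fit_adverse_model(coh$features, coh$features$latent_score),
               "too few rows")
})

test_that("models round-trip through the key-value text format", {
  cfg <- cohort_config(n_subjects = 20, seed = 13)
  coh <- generate_cohort(cfg)
  fit <- fit_adverse_model(coh$features, coh$outcomes$outcome_score)
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coefficients, fit$coefficients)
  expect_identical(back$provenance, "refitted")
  pub_path <- withr::local_tempfile(fileext = ".txt")
  write_model(published_adverse_model(), pub_path)
  expect_identical(read_model(pub_path)$provenance, "published")
})
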