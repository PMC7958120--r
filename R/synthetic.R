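# Run code with a local, restored-on-exit RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

#' Synthetic subject profile
#'
#' Ground-truth parameters of one simulated subject. Defaults follow the
#' clinical group structure of frail vs non-frail older cardiac-surgery
#' patients: frail subjects walk at ~0.67 m/s with ~0.654 s inter-step times
#' and lower walking RMS; non-frail at ~0.98 m/s with ~0.573 s steps.
#'
#' @param group `"frail"` or `"non-frail"`.
#' @param true_gait_speed Walking speed in m/s (> 0). Default by group:
#'   0.67 (frail) / 0.98 (non-frail).
#' @param true_step_time Inter-step time in s (> 0). Default 0.654 / 0.573.
#' @param rms_targets Length-3 numeric (AP, V, ML) walking RMS targets in g.
#'   Default frail c(0.12, 0.11, 0.11); non-frail c(0.15, 0.17, 0.15).
#' @param sway_regularity Scalar in \[0, 1\]: mix of periodic vs band-limited
#'   noise in the stance sway signal (1 = purely periodic, low ApEn).
#'   Default 0.35 (frail, more regular sway) / 0.15 (non-frail).
#' @param sway_sd_g Stance horizontal-acceleration SD in g (default 0.0065
#'   frail / 0.004 non-frail, i.e. ~6.5 / ~4 mm sway SD at 1000 mm per g).
#' @param outcome_events Character vector of postoperative event labels from
#'   [outcome_weights()] names (may be empty).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(group = c("frail", "non-frail"),
                            true_gait_speed = NULL,
                            true_step_time = NULL,
                            rms_targets = NULL,
                            sway_regularity = NULL,
                            sway_sd_g = NULL,
                            outcome_events = character(0)) {
  group <- match.arg(group)
  frail <- group == "frail"
  if (is.null(true_gait_speed)) true_gait_speed <- if (frail) 0.67 else 0.98
  if (is.null(true_step_time)) true_step_time <- if (frail) 0.654 else 0.573
  if (is.null(rms_targets)) rms_targets <- if (frail)
    c(ap = 0.12, v = 0.11, ml = 0.11) else c(ap = 0.15, v = 0.17, ml = 0.15)
  if (is.null(sway_regularity)) sway_regularity <- if (frail) 0.35 else 0.15
  if (is.null(sway_sd_g)) sway_sd_g <- if (frail) 0.0065 else 0.004
  if (true_gait_speed <= 0) stop("true_gait_speed must be positive")
  if (true_step_time <= 0) stop("true_step_time must be positive")
  rms_targets <- stats::setNames(as.numeric(rms_targets), c("ap", "v", "ml"))
  if (any(rms_targets <= 0)) stop("rms_targets must all be positive")
  if (sway_regularity < 0 || sway_regularity > 1) {
    stop("sway_regularity must lie in [0, 1]")
  }
  bad <- setdiff(outcome_events, names(outcome_weights()))
  if (length(bad) > 0) stop("unknown outcome event(s): ",
                            paste(bad, collapse = ", "))
  structure(list(group = group, true_gait_speed = true_gait_speed,
                 true_step_time = true_step_time, rms_targets = rms_targets,
                 sway_regularity = sway_regularity, sway_sd_g = sway_sd_g,
                 outcome_events = outcome_events),
            class = "subject_profile")
}

#' Synthetic cohort configuration
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param frail_fraction Proportion of frail subjects in \[0, 1\] (default 0.5).
#' @param sampling_rate Sampling rate in Hz (default 50).
#' @param stance_duration Quiet-stance duration in s (default 30).
#' @param walk_distance Walk course length in m (default 5).
#' @param noise_sd Additive accelerometer noise SD in g (default 0.02); also
#'   sets the stand-still noise floor used for detection calibration.
#' @param score_noise_sd SD of the zero-mean noise added to the latent adverse
#'   score on the score scale (default 0.75).
#' @param lead_duration Stand-still lead-in before the walk in s (default 3).
#' @param seed Integer seed making all generation reproducible.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16, frail_fraction = 0.5,
                          sampling_rate = 50, stance_duration = 30,
                          walk_distance = 5, noise_sd = 0.02,
                          score_noise_sd = 0.75, lead_duration = 3,
                          seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (frail_fraction < 0 || frail_fraction > 1) {
    stop("frail_fraction must lie in [0, 1]")
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (stance_duration <= 0 || walk_distance <= 0) {
    stop("stance_duration and walk_distance must be positive")
  }
  if (noise_sd < 0 || score_noise_sd < 0) stop("noise SDs must be >= 0")
  if (lead_duration < 2) stop("lead_duration must be >= 2 s (calibration prefix)")
  structure(list(n_subjects = as.integer(n_subjects),
                 frail_fraction = frail_fraction,
                 sampling_rate = sampling_rate,
                 stance_duration = stance_duration,
                 walk_distance = walk_distance, noise_sd = noise_sd,
                 score_noise_sd = score_noise_sd,
                 lead_duration = lead_duration,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Half-sine gait initiation/termination envelope inside [0, dur].
walk_envelope <- function(tau, dur, ramp) {
  env <- rep(1, length(tau))
  env[tau < 0 | tau > dur] <- 0
  up <- tau >= 0 & tau < ramp
  env[up] <- sin(pi * tau[up] / (2 * ramp))
  down <- tau > dur - ramp & tau <= dur
  env[down] <- sin(pi * (dur - tau[down]) / (2 * ramp))
  env
}

#' Generate a synthetic stand-still + 5-m-walk recording
#'
#' Emulates the clinical walk protocol: a quiet stand-still lead-in, a
#' quasi-periodic walking bout of duration `walk_distance / true_gait_speed`
#' (gait initiation and termination ramps included), and a short quiet tail.
#' The walking signal is a sum of harmonics at the step frequency (vertical
#' dominant, AP phase-shifted, ML at the stride frequency) with amplitudes
#' solved so that 6 Hz low-passed, mean-removed per-axis RMS over the walk
#' matches the profile's `rms_targets`; gravity appears as a constant +1 g
#' on the vertical axis; Gaussian sensor noise is added throughout.
#'
#' @param profile A [subject_profile()].
#' @param config A [cohort_config()].
#' @param seed Integer seed (all randomness flows from it).
#' @param ramp Gait initiation/termination ramp length in s (default 0.6).
#' @return A list: `trace` (an [acceleration_trace()]) and `ground_truth`
#'   (`walk_start_s`, `walk_stop_s`, `speed`, `step_times`).
#' @export
generate_walk_trace <- function(profile, config, seed = config$seed,
                                ramp = 0.6) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  fs <- config$sampling_rate
  walk_dur <- config$walk_distance / profile$true_gait_speed
  if (walk_dur < 4 * profile$true_step_time) {
    stop("unusable trial: walk duration (", round(walk_dur, 2),
         " s) shorter than 4 step cycles")
  }
  lead <- config$lead_duration
  tail_dur <- 2
  total <- lead + walk_dur + tail_dur
  time <- seq(0, total, by = 1 / fs)
  tau <- time - lead                     # time since walk start
  env <- walk_envelope(tau, walk_dur, ramp)
  f <- 1 / profile$true_step_time        # step frequency, Hz
  hr <- 0.3                              # second-harmonic amplitude ratio
  # amplitude so that RMS of a*(sin + hr*sin(2.)) equals the target,
  # corrected for the envelope's reduced power over the bout
  env_pow <- mean(env[tau >= 0 & tau <= walk_dur]^2)
  amp <- function(target) target * sqrt(2 / (1 + hr^2)) / sqrt(env_pow)
  a_v <- amp(profile$rms_targets[["v"]])
  a_ap <- amp(profile$rms_targets[["ap"]])
  a_ml <- profile$rms_targets[["ml"]] * sqrt(2) / sqrt(env_pow)
  with_seed(seed, {
    # carriers start at phase pi/2: the first step is an impact (full
    # amplitude), not a zero crossing, which keeps the onset detectable
    v <- 1 + env * a_v * (sin(2 * pi * f * tau + pi / 2) +
                            hr * sin(4 * pi * f * tau + pi / 2)) +
      stats::rnorm(length(time), 0, config$noise_sd)
    ap <- env * a_ap * (sin(2 * pi * f * tau + 3 * pi / 4) +
                          hr * sin(4 * pi * f * tau + 3 * pi / 4)) +
      stats::rnorm(length(time), 0, config$noise_sd)
    ml <- env * a_ml * sin(pi * f * tau + pi / 2) +
      stats::rnorm(length(time), 0, config$noise_sd)
    trace <- acceleration_trace(time, ap, ml, v, sampling_rate = fs)
    n_steps <- floor(walk_dur / profile$true_step_time)
    list(trace = trace,
         ground_truth = list(walk_start_s = lead,
                             walk_stop_s = lead + walk_dur,
                             speed = profile$true_gait_speed,
                             step_times = rep(profile$true_step_time, n_steps)))
  })
}

#' Generate a synthetic quiet-stance recording
#'
#' The horizontal (AP, ML) sway-proxy acceleration is a mixture
#' `sway_regularity * periodic + (1 - sway_regularity) * band-limited noise`,
#' each component standardised to unit SD before mixing and the mixture scaled
#' to the profile's `sway_sd_g`. Higher `sway_regularity` yields lower ApEn of
#' the generated series (in expectation over seeds). Gravity is +1 g on V.
#'
#' @param profile A [subject_profile()].
#' @param config A [cohort_config()]; `stance_duration` must be >= 5 s.
#' @param seed Integer seed.
#' @param sway_freq Frequency of the periodic sway component in Hz
#'   (default 0.4, within the <1 Hz band that dominates quiet stance).
#' @param noise_band Cut-off in Hz of the band-limited noise component
#'   (default 16).
#' @return A list: `trace` (an [acceleration_trace()]) and
#'   `ground_truth_sway` (planar data.frame `ap`, `ml` of the noiseless sway
#'   signal in g).
#' @export
generate_stance_trace <- function(profile, config, seed = config$seed,
                                  sway_freq = 0.4, noise_band = 16) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "cohort_config"))
  if (config$stance_duration < 5) stop("stance_duration must be >= 5 s")
  fs <- config$sampling_rate
  time <- seq(0, config$stance_duration, by = 1 / fs)
  time <- time[-length(time)]            # duration * rate samples
  n <- length(time)
  reg <- profile$sway_regularity
  bf <- signal::butter(2, min(noise_band / (fs / 2), 0.95), type = "low")
  unit_sd <- function(x) if (stats::sd(x) > 0) x / stats::sd(x) else x
  channel <- function(phase) {
    # strictly periodic component (harmonic at exactly twice the base
    # frequency) so that sway_regularity = 1 gives a perfectly repeatable,
    # low-ApEn series
    periodic <- sin(2 * pi * sway_freq * time + phase) +
      0.3 * sin(4 * pi * sway_freq * time + 2 * phase)
    noise <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
    mix <- reg * unit_sd(periodic) + (1 - reg) * unit_sd(noise)
    profile$sway_sd_g * unit_sd(mix)
  }
  # sensor noise floor kept two orders below the sway signal so it does not
  # mask the regularity structure the mixture encodes
  sensor_sd <- config$noise_sd / 100
  with_seed(seed, {
    ap_sway <- channel(0)
    ml_sway <- channel(pi / 2)
    ap <- ap_sway + stats::rnorm(n, 0, sensor_sd)
    ml <- ml_sway + stats::rnorm(n, 0, sensor_sd)
    v <- 1 + stats::rnorm(n, 0, sensor_sd)
    list(trace = acceleration_trace(time, ap, ml, v, sampling_rate = fs),
         ground_truth_sway = data.frame(ap = ap_sway, ml = ml_sway))
  })
}

#' Generate a synthetic cohort feature and outcome table
#'
#' Draws per-subject gait/posture features from group-specific normal
#' distributions matching the frail vs non-frail clinical structure, computes
#' a latent adverse score as the published linear model evaluated at the
#' features plus zero-mean noise (`score_noise_sd`), and maps the latent score
#' to discrete postoperative events through fixed severity-ordered thresholds
#' so that event prevalence is clinically shaped (frail subjects receive
#' stochastically slower speeds and higher latent scores).
#'
#' @param config A [cohort_config()] with `n_subjects >= 2`.
#' @param model An `adverse_score_model` used as the latent-score generator
#'   (default [published_adverse_model()]).
#' @return A list of two data.frames: `features` (subject_id, group,
#'   smartphone_velocity, stopwatch_velocity, rms_ap, rms_v, rms_ml,
#'   apen_ml_cop, apen_r_cop, step_time, latent_score) and `outcomes`
#'   (subject_id, one logical column per event, outcome_score).
#' @export
generate_cohort <- function(config, model = published_adverse_model()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_subjects < 2) stop("n_subjects must be >= 2 to form groups")
  n <- config$n_subjects
  n_frail <- round(config$frail_fraction * n)
  frail <- c(rep(TRUE, n_frail), rep(FALSE, n - n_frail))
  rtrunc <- function(n, mean, sd, lower = 0.05) pmax(stats::rnorm(n, mean, sd), lower)
  with_seed(config$seed, {
    velocity <- rtrunc(n, ifelse(frail, 0.67, 0.98), ifelse(frail, 0.064, 0.222),
                       lower = 0.2)
    stopwatch <- pmax(velocity + stats::rnorm(n, 0, 0.08), 0.2)
    feats <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      group = ifelse(frail, "frail", "non-frail"),
      smartphone_velocity = velocity,
      stopwatch_velocity = stopwatch,
      rms_ap = rtrunc(n, ifelse(frail, 0.12, 0.15), ifelse(frail, 0.03, 0.02)),
      rms_v = rtrunc(n, ifelse(frail, 0.11, 0.17), ifelse(frail, 0.01, 0.02)),
      rms_ml = rtrunc(n, ifelse(frail, 0.11, 0.15), ifelse(frail, 0.02, 0.03)),
      apen_ml_cop = rtrunc(n, ifelse(frail, 1.101, 1.077),
                           ifelse(frail, 0.018, 0.068)),
      apen_r_cop = rtrunc(n, ifelse(frail, 1.113, 1.141),
                          ifelse(frail, 0.021, 0.033)),
      step_time = rtrunc(n, ifelse(frail, 0.654, 0.573),
                         ifelse(frail, 0.150, 0.081), lower = 0.25)
    )
    latent <- predict_adverse_score(feats, model) +
      stats::rnorm(n, 0, config$score_noise_sd)
    feats$latent_score <- latent
    # severity-ordered latent-score thresholds, set so that a frail-heavy
    # cohort reproduces roughly the clinical event mix (SNF and ventilation
    # common, death rare)
    thr <- c(snf_discharge = 3.9, prolonged_ventilation = 4.3, stroke = 4.8,
             renal_failure = 5.2, reoperation = 5.5, prolonged_stay = 5.8,
             death = 6.2, dswi = 7.0)
    outcomes <- data.frame(subject_id = feats$subject_id)
    for (ev in names(outcome_weights())) {
      outcomes[[ev]] <- latent >= thr[[ev]]
    }
    outcomes$outcome_score <- vapply(seq_len(n), function(i)
      outcome_score(outcomes[i, names(outcome_weights())]), numeric(1))
    list(features = feats, outcomes = outcomes)
  })
}

#' Write a synthetic cohort with per-subject traces to disk
#'
#' Simulates a full cohort (walk + stance trace per subject, feature and
#' outcome tables) and writes everything as delimited text together with a
#' YAML manifest recording the configuration and seed.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
simulate_cohort_files <- function(config, dir) {
  stopifnot(inherits(config, "cohort_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  subjects <- list()
  for (i in seq_len(config$n_subjects)) {
    id <- cohort$features$subject_id[i]
    prof <- subject_profile(
      group = cohort$features$group[i],
      true_gait_speed = cohort$features$smartphone_velocity[i],
      true_step_time = cohort$features$step_time[i],
      rms_targets = c(cohort$features$rms_ap[i], cohort$features$rms_v[i],
                      cohort$features$rms_ml[i])
    )
    walk <- generate_walk_trace(prof, config, seed = config$seed + i)
    stance <- generate_stance_trace(prof, config, seed = config$seed + 10000L + i)
    walk_path <- file.path(dir, paste0(id, "_walk.csv"))
    stance_path <- file.path(dir, paste0(id, "_stance.csv"))
    write_trace(walk$trace, walk_path)
    write_trace(stance$trace, stance_path)
    subjects[[id]] <- list(id = id, group = cohort$features$group[i],
                           walk = basename(walk_path),
                           stance = basename(stance_path))
  }
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(package = "gaitfrail",
                   version = as.character(utils::packageVersion("gaitfrail")),
                   config = unclass(config), subjects = unname(subjects))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}
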