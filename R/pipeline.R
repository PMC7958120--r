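#' Pipeline configuration
#'
#' Validated configuration for the end-to-end assessment pipeline. Defaults
#' equal the protocol constants: 50 Hz sampling, 6 Hz 4th-order zero-phase
#' low-pass, 0.5 s detection window with a 3x stand-still threshold, ApEn with
#' m = 2 and tolerance 0.2 x SD, frailty below 0.833 m/s over a 5-m course.
#'
#' @param sampling_rate Hz (default 50).
#' @param cutoff,order Low-pass filter parameters (6 Hz, 4).
#' @param window Detection window in s (0.5).
#' @param multiplier Detection threshold multiplier (3).
#' @param standstill Calibration prefix in s (2).
#' @param apen_m,apen_tolerance ApEn pattern length and tolerance fraction.
#' @param frailty_threshold m/s (0.833).
#' @param walk_distance m (5).
#' @param stance_duration s (30).
#' @param sway_scale mm per g (1000).
#' @param outcome_aggregation `"sum"` or `"max"`.
#' @param seed Integer seed recorded in reports (default 1).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_rate = 50, cutoff = 6, order = 4,
                            window = 0.5, multiplier = 3, standstill = 2,
                            apen_m = 2, apen_tolerance = 0.2,
                            frailty_threshold = 0.833, walk_distance = 5,
                            stance_duration = 30, sway_scale = 1000,
                            outcome_aggregation = c("sum", "max"), seed = 1L) {
  outcome_aggregation <- match.arg(outcome_aggregation)
  if (cutoff >= sampling_rate / 2) stop("cutoff must be below Nyquist")
  if (window <= 0 || multiplier < 1 || standstill < 4 * window) {
    stop("invalid detection parameters")
  }
  if (apen_m < 1 || apen_tolerance <= 0 || apen_tolerance >= 1) {
    stop("invalid ApEn parameters")
  }
  if (frailty_threshold <= 0 || walk_distance <= 0 || stance_duration < 5 ||
      sway_scale <= 0) {
    stop("invalid protocol parameters")
  }
  structure(list(sampling_rate = sampling_rate, cutoff = cutoff,
                 order = order, window = window, multiplier = multiplier,
                 standstill = standstill, apen_m = apen_m,
                 apen_tolerance = apen_tolerance,
                 frailty_threshold = frailty_threshold,
                 walk_distance = walk_distance,
                 stance_duration = stance_duration, sway_scale = sway_scale,
                 outcome_aggregation = outcome_aggregation,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config`: the validated config.
#'   `write_pipeline_config`: `path` invisibly. Serialize-parse-serialize is
#'   the identity.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Stable hash of a configuration (md5 of its canonical YAML serialization).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

log_debug <- function(...) {
  if (isTRUE(getOption("gaitfrail.verbose", FALSE))) {
    message("[gaitfrail] ", sprintf(...))
  }
}

with_stage <- function(stage, subject_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s | subject %s] %s", stage, subject_id,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full preoperative assessment on one subject
#'
#' Executes filter, stand-still calibration, walk detection, gait features,
#' ApEn/sway features, frailty classification and adverse-score prediction,
#' in that order, on a stance recording and a walk recording. Intermediate
#' results are logged to standard error when
#' `options(gaitfrail.verbose = TRUE)`.
#'
#' @param stance_path Path to the quiet-stance trace (delimited text with
#'   header `time_s,acc_ap_g,acc_ml_g,acc_v_g`).
#' @param walk_path Path to the stand-still + walk trace (same format).
#' @param config A [pipeline_config()].
#' @param model An `adverse_score_model` (default the published model).
#' @param subject_id Identifier attached to the report and error messages.
#' @return An object of class `assessment_report`: `gait`
#'   ([extract_gait_features()] result), `posture`
#'   ([extract_posture_features()] result), `frailty`, `adverse_score`,
#'   `cutoff_flags` (published single-variable rules applied to this
#'   subject), and `provenance` (config hash, seed, package version). Reports
#'   are regenerable bit-identically from (inputs, config, seed).
#' @export
run_assessment <- function(stance_path, walk_path,
                           config = pipeline_config(),
                           model = published_adverse_model(),
                           subject_id = "subject") {
  stopifnot(inherits(config, "pipeline_config"))
  stance <- with_stage("parse-stance", subject_id, read_trace(stance_path))
  walk <- with_stage("parse-walk", subject_id, read_trace(walk_path))
  log_debug("subject %s: stance %d samples, walk %d samples", subject_id,
            length(stance), length(walk))
  gait <- with_stage("gait-features", subject_id, extract_gait_features(
    walk, distance = config$walk_distance, cutoff = config$cutoff,
    order = config$order, window = config$window,
    multiplier = config$multiplier, standstill = config$standstill))
  log_debug("subject %s: walk %.2f-%.2f s, velocity %.3f m/s", subject_id,
            gait$walk_start, gait$walk_stop, gait$velocity)
  posture <- with_stage("posture-features", subject_id,
                        extract_posture_features(
    stance, cutoff = config$cutoff, order = config$order,
    scale = config$sway_scale, m = config$apen_m,
    tolerance_fraction = config$apen_tolerance))
  log_debug("subject %s: ApEn ML %.3f, R %.3f", subject_id,
            posture$apen_ml, posture$apen_r)
  frailty <- with_stage("classify", subject_id,
                        classify_frailty(gait$velocity,
                                         config$frailty_threshold))
  feats <- data.frame(rms_ap = gait$rms_ap, rms_v = gait$rms_v,
                      apen_ml_cop = posture$apen_ml,
                      apen_r_cop = posture$apen_r,
                      step_time = gait$mean_step_time)
  score <- with_stage("score", subject_id,
                      predict_adverse_score(feats, model))
  rules <- published_cutoff_rules()
  vals <- c(smartphone_velocity = gait$velocity, rms_v = gait$rms_v,
            step_time = gait$mean_step_time, apen_r_cop = posture$apen_r)
  rules$value <- unname(vals[rules$variable])
  rules$flagged <- ifelse(rules$direction == "<=",
                          rules$value <= rules$threshold,
                          rules$value > rules$threshold)
  structure(list(subject_id = subject_id, gait = gait, posture = posture,
                 frailty = frailty, adverse_score = score,
                 cutoff_flags = rules,
                 provenance = list(
                   config_hash = config_hash(config), seed = config$seed,
                   model = model$provenance,
                   version = as.character(utils::packageVersion("gaitfrail")))),
            class = "assessment_report")
}

#' @export
print.assessment_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Render an assessment report as text
#'
#' Numeric output is printed at 3 decimals; full precision is retained in the
#' report object itself.
#'
#' @param report An `assessment_report`.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "assessment_report"))
  g <- report$gait; p <- report$posture
  fl <- report$cutoff_flags
  c(sprintf("=== preoperative assessment: %s ===", report$subject_id),
    sprintf("frailty: %s (velocity %.3f m/s)", report$frailty, g$velocity),
    sprintf("adverse-outcome score (%s model): %.3f",
            report$provenance$model, report$adverse_score),
    sprintf("gait: step time %.3f s; RMS AP %.3f / V %.3f / ML %.3f g",
            g$mean_step_time, g$rms_ap, g$rms_v, g$rms_ml),
    sprintf("posture: ApEn ML %.3f / R %.3f; sway SD %.3f mm (%s)",
            p$apen_ml, p$apen_r, p$sway_sd, p$derivation),
    sprintf("cut-off flags: %s",
            paste(sprintf("%s %s %.3f -> %s", fl$variable, fl$direction,
                          fl$threshold, ifelse(fl$flagged, "AT-RISK", "ok")),
                  collapse = "; ")),
    sprintf("provenance: config %s, seed %d, gaitfrail %s",
            report$provenance$config_hash, report$provenance$seed,
            report$provenance$version))
}
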