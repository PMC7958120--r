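#' Planar sway proxy from a stance acceleration recording
#'
#' Converts the mean-removed horizontal-plane (AP, ML) accelerations of a
#' quiet-stance recording into a planar sway-excursion proxy in millimetres,
#' plus the per-sample planar resultant. This acceleration-proxy derivation is
#' a stand-in for force-plate center-of-pressure data and is tagged as such in
#' the result.
#'
#' @param stance A filtered [acceleration_trace()] of quiet stance.
#' @param scale Millimetres of sway excursion per g of horizontal acceleration
#'   (default 1000).
#' @return An object of class `sway_trace`: planar series `ap`, `ml`,
#'   resultant `r` (all mm), `time`, `sampling_rate` and `derivation`
#'   (`"acceleration-proxy"`).
#' @export
sway_from_acceleration <- function(stance, scale = 1000) {
  stopifnot(inherits(stance, "acceleration_trace"))
  if (scale <= 0) stop("scale must be positive")
  ap <- (stance$ap - mean(stance$ap)) * scale
  ml <- (stance$ml - mean(stance$ml)) * scale
  structure(list(ap = ap, ml = ml, r = sqrt(ap^2 + ml^2),
                 time = stance$time, sampling_rate = stance$sampling_rate,
                 derivation = "acceleration-proxy"),
            class = "sway_trace")
}

#' @export
print.sway_trace <- function(x, ...) {
  cat(sprintf("<sway_trace> %d samples @ %g Hz (%s), planar SD %.2f mm\n",
              length(x$ap), x$sampling_rate, x$derivation,
              stats::sd(x$r)))
  invisible(x)
}

#' Postural sway dispersion metrics
#'
#' Standard posturography summaries of a planar sway series: total path
#' length, mean sway velocity, mean sway radius about the centroid, 95%
#' confidence-ellipse sway area, and the SD of the resultant (radial)
#' displacement.
#'
#' @param sway A `sway_trace` from [sway_from_acceleration()] (or any list
#'   with planar `ap`, `ml` in mm and `time` in s).
#' @return A list: `sway_path_length` (mm), `mean_sway_velocity` (mm/s),
#'   `mean_sway_radius` (mm), `sway_area` (mm^2, 95% confidence ellipse from
#'   the chi-squared distribution with 2 df), `sway_sd` (mm).
#' @export
sway_metrics <- function(sway) {
  ap <- sway$ap; ml <- sway$ml; time <- sway$time
  n <- length(ap)
  if (n < 2) stop("sway series needs at least 2 samples")
  path <- sum(sqrt(diff(ap)^2 + diff(ml)^2))
  duration <- time[n] - time[1]
  cap <- mean(ap); cml <- mean(ml)
  radial <- sqrt((ap - cap)^2 + (ml - cml)^2)
  covm <- stats::cov(cbind(ap, ml))
  detc <- max(det(covm), 0)
  list(sway_path_length = path,
       mean_sway_velocity = path / duration,
       mean_sway_radius = mean(radial),
       sway_area = pi * stats::qchisq(0.95, df = 2) * sqrt(detc),
       sway_sd = stats::sd(radial))
}

#' Extract posture-complexity features from a stance recording
#'
#' Filters the stance trace, derives the planar sway proxy, and computes
#' approximate entropy per axis and for the planar resultant, plus the sway
#' dispersion metrics.
#'
#' @param stance A raw [acceleration_trace()] of quiet stance (>= 5 s).
#' @param cutoff,order Low-pass filter parameters (defaults 6 Hz, order 4).
#' @param scale Sway-proxy scale in mm per g (default 1000).
#' @param m,tolerance_fraction ApEn parameters (defaults 2 and 0.2).
#' @return An object of class `posture_features`: `apen_ap`, `apen_ml`,
#'   `apen_v`, `apen_r` (unitless), the [sway_metrics()] fields, and the sway
#'   `derivation` tag.
#' @export
extract_posture_features <- function(stance, cutoff = 6, order = 4,
                                     scale = 1000, m = 2,
                                     tolerance_fraction = 0.2) {
  filtered <- lowpass_filter(stance, cutoff = cutoff, order = order)
  sway <- sway_from_acceleration(filtered, scale = scale)
  ae <- function(x) approximate_entropy(x, m = m,
                                        tolerance_fraction = tolerance_fraction)
  metrics <- sway_metrics(sway)
  structure(c(list(apen_ap = ae(filtered$ap - mean(filtered$ap)),
                   apen_ml = ae(filtered$ml - mean(filtered$ml)),
                   apen_v = ae(filtered$v - mean(filtered$v)),
                   apen_r = ae(sway$r)),
              metrics,
              list(derivation = sway$derivation)),
            class = "posture_features")
}

#' @export
print.posture_features <- function(x, ...) {
  cat(sprintf("<posture_features> ApEn: AP %.3f  ML %.3f  V %.3f  R %.3f\n",
              x$apen_ap, x$apen_ml, x$apen_v, x$apen_r))
  cat(sprintf("  path %.1f mm, velocity %.1f mm/s, radius %.2f mm, area %.1f mm^2, SD %.2f mm (%s)\n",
              x$sway_path_length, x$mean_sway_velocity, x$mean_sway_radius,
              x$sway_area, x$sway_sd, x$derivation))
  invisible(x)
}

#' @export
as.data.frame.posture_features <- function(x, ...) {
  data.frame(apen_ml_cop = x$apen_ml, apen_r_cop = x$apen_r,
             apen_ap = x$apen_ap, apen_v = x$apen_v,
             sway_path_length = x$sway_path_length,
             mean_sway_velocity = x$mean_sway_velocity,
             mean_sway_radius = x$mean_sway_radius,
             sway_area = x$sway_area, sway_sd = x$sway_sd)
}
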