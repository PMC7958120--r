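# Peak prominence: height above the higher of the two key saddles, where each
# saddle is the minimum between the peak and the nearest strictly higher
# sample on that side (or the series minimum on that side if none is higher).
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1L)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l) == 0) min(left, h) else
      min(left[seq.int(max(higher_l), p - 1L)])
    right <- x[seq.int(p + 1L, length(x))]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r) == 0) min(right, h) else
      min(right[seq_len(min(higher_r))])
    h - max(base_l, base_r)
  }, numeric(1))
}

#' Detect step events and inter-step times
#'
#' Step events are local maxima of the (filtered) vertical-axis acceleration
#' inside the walking segment, separated by at least `min_separation` seconds
#' and with prominence of at least `prominence_factor` times the segment
#' standard deviation. Inter-step times are differences between successive
#' events.
#'
#' @param trace A filtered [acceleration_trace()].
#' @param segment A [walk_segment()] from the same recording.
#' @param min_separation Refractory period between steps in seconds
#'   (default 0.25).
#' @param prominence_factor Minimum peak prominence as a fraction of the
#'   segment SD (default 0.5).
#' @param min_height Absolute floor in g on the peak height above the segment
#'   mean (default 0.01): pelvis-level step impacts are at least a few
#'   hundredths of g, so smaller maxima are sensor noise, not steps.
#' @return A list with `step_times` (successive differences, s),
#'   `mean_step_time` (s) and `event_times` (s). Fewer than 3 detected events
#'   is an error ("too few steps").
#' @export
detect_steps <- function(trace, segment, min_separation = 0.25,
                         prominence_factor = 0.5, min_height = 0.01) {
  stopifnot(inherits(trace, "acceleration_trace"),
            inherits(segment, "walk_segment"))
  sel <- trace$time >= segment$start_time & trace$time <= segment$stop_time
  if (sum(sel) < 4) stop("too few steps: walking segment nearly empty")
  x <- trace$v[sel]
  tt <- trace$time[sel]
  x <- x - mean(x)
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) == 0) stop("too few steps: no step-scale maxima in segment")
  prom <- peak_prominence(x, cand)
  keep <- prom >= prominence_factor * stats::sd(x)
  cand <- cand[keep]
  if (length(cand) > 0) {
    # enforce refractory period, keeping higher peaks first
    ord <- cand[order(x[cand], decreasing = TRUE)]
    chosen <- integer(0)
    for (p in ord) {
      if (all(abs(tt[p] - tt[chosen]) >= min_separation)) chosen <- c(chosen, p)
    }
    cand <- sort(chosen)
  }
  if (length(cand) < 3) stop("too few steps: fewer than 3 step events detected")
  event_times <- tt[cand]
  step_times <- diff(event_times)
  list(step_times = step_times,
       mean_step_time = mean(step_times),
       event_times = event_times)
}

#' Per-axis RMS of mean-removed walking acceleration
#'
#' Root-mean-square of each axis restricted to the walking segment, after
#' removing the segment mean (so the vertical gravity offset does not inflate
#' RMS_V). Satisfies translation invariance and absolute homogeneity
#' `RMS(k x) = |k| RMS(x)`.
#'
#' @param trace A filtered [acceleration_trace()].
#' @param segment A [walk_segment()].
#' @return Named list `rms_ap`, `rms_v`, `rms_ml` in g.
#' @export
rms_features <- function(trace, segment) {
  stopifnot(inherits(trace, "acceleration_trace"),
            inherits(segment, "walk_segment"))
  sel <- trace$time >= segment$start_time & trace$time <= segment$stop_time
  if (!any(sel)) stop("empty walking segment: no samples between bounds")
  rms <- function(y) sqrt(mean((y - mean(y))^2))
  list(rms_ap = rms(trace$ap[sel]),
       rms_v = rms(trace$v[sel]),
       rms_ml = rms(trace$ml[sel]))
}

#' Extract gait features from a raw walk recording
#'
#' Runs the full gait chain: zero-phase low-pass filter, stand-still
#' calibration, walk-bound detection, gait speed, step detection and per-axis
#' RMS.
#'
#' @param trace A raw [acceleration_trace()] beginning with >= 2 s of
#'   stand-still followed by a 5-m walk.
#' @param distance Course distance in metres (default 5).
#' @param cutoff,order Low-pass filter parameters (defaults 6 Hz, order 4).
#' @param window Moving-window length in seconds (default 0.5).
#' @param multiplier Detection threshold multiplier (default 3).
#' @param standstill Calibration prefix duration in seconds (default 2).
#' @param min_separation,prominence_factor Step-detection parameters.
#' @return An object of class `gait_features`: velocity (m/s), step_times,
#'   mean_step_time (s), rms_ap/rms_v/rms_ml (g), walk_start/walk_stop (s).
#' @export
extract_gait_features <- function(trace, distance = 5, cutoff = 6, order = 4,
                                  window = 0.5, multiplier = 3, standstill = 2,
                                  min_separation = 0.25,
                                  prominence_factor = 0.5) {
  filtered <- lowpass_filter(trace, cutoff = cutoff, order = order)
  calib <- calibrate_standstill(filtered, window = window,
                                multiplier = multiplier,
                                standstill = standstill)
  seg <- detect_walk_bounds(filtered, calib, window = window,
                            distance = distance)
  steps <- detect_steps(filtered, seg, min_separation = min_separation,
                        prominence_factor = prominence_factor)
  rms <- rms_features(filtered, seg)
  structure(list(velocity = gait_speed(seg),
                 step_times = steps$step_times,
                 mean_step_time = steps$mean_step_time,
                 rms_ap = rms$rms_ap, rms_v = rms$rms_v, rms_ml = rms$rms_ml,
                 walk_start = seg$start_time, walk_stop = seg$stop_time,
                 distance = distance),
            class = "gait_features")
}

#' @export
print.gait_features <- function(x, ...) {
  cat(sprintf("<gait_features> velocity %.3f m/s, mean step time %.3f s (%d steps)\n",
              x$velocity, x$mean_step_time, length(x$step_times) + 1L))
  cat(sprintf("  RMS [g]: AP %.3f  V %.3f  ML %.3f; walk %.2f-%.2f s\n",
              x$rms_ap, x$rms_v, x$rms_ml, x$walk_start, x$walk_stop))
  invisible(x)
}

#' @export
as.data.frame.gait_features <- function(x, ...) {
  data.frame(smartphone_velocity = x$velocity,
             step_time = x$mean_step_time,
             rms_ap = x$rms_ap, rms_v = x$rms_v, rms_ml = x$rms_ml,
             walk_start = x$walk_start, walk_stop = x$walk_stop)
}
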