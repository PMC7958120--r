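#' Walk segment
#'
#' Start/stop bounds of a detected walking bout plus the marked course
#' distance (5 m protocol by default).
#'
#' @param start_time,stop_time Bout bounds in seconds; `stop_time > start_time`.
#' @param distance Walked distance in metres (default 5).
#' @return An object of class `walk_segment`.
#' @export
walk_segment <- function(start_time, stop_time, distance = 5) {
  stopifnot(is.numeric(start_time), is.numeric(stop_time), is.numeric(distance))
  if (stop_time <= start_time) stop("stop_time must exceed start_time")
  if (distance <= 0) stop("distance must be positive")
  structure(list(start_time = start_time, stop_time = stop_time,
                 distance = distance),
            class = "walk_segment")
}

#' @export
print.walk_segment <- function(x, ...) {
  cat(sprintf("<walk_segment> %.3f s to %.3f s (%.3f s over %g m)\n",
              x$start_time, x$stop_time, x$stop_time - x$start_time,
              x$distance))
  invisible(x)
}

# Dense moving-window variance (hop = 1 sample, unbiased sample variance).
# Returns window center times and variances; window length in seconds.
moving_window_variance <- function(x, time, fs, window = 0.5) {
  w <- max(2L, round(window * fs))
  if (length(x) < w) stop("series shorter than one window")
  v <- as.numeric(zoo::rollapply(x, width = w, FUN = stats::var))
  idx <- seq_len(length(x) - w + 1L)
  centers <- (time[idx] + time[idx + w - 1L]) / 2
  list(centers = centers, variance = v, window_samples = w)
}

#' Stand-still calibration for walk detection
#'
#' Computes the moving-window-variance baseline of the mean-removed resultant
#' acceleration over the initial stand-still portion of a recording, and a
#' detection threshold as a multiple of that baseline. Windows overlapping the
#' first `edge_margin` seconds are excluded (zero-phase filter edge
#' transients).
#'
#' @param trace A filtered [acceleration_trace()] that begins with at least
#'   2 s of stand-still.
#' @param window Moving-window length in seconds (default 0.5).
#' @param multiplier Threshold multiplier on the baseline variance (default 3).
#' @param standstill Duration in seconds of the initial stand-still prefix
#'   used for calibration (default 2).
#' @param edge_margin Seconds excluded at the start of the recording
#'   (default 0.5).
#' @return An object of class `standstill_calibration` with elements
#'   `baseline_variance`, `threshold`, `window`, `multiplier`.
#' @export
calibrate_standstill <- function(trace, window = 0.5, multiplier = 3,
                                 standstill = 2, edge_margin = 0.5) {
  stopifnot(inherits(trace, "acceleration_trace"))
  if (multiplier < 1) stop("multiplier must be >= 1")
  if (standstill < 4 * window) {
    stop("stand-still prefix (", standstill, " s) shorter than 4 windows of ",
         window, " s: cannot calibrate")
  }
  fs <- trace$sampling_rate
  r <- resultant_acceleration(trace)
  r <- r - mean(r)
  mwv <- moving_window_variance(r, trace$time, fs, window)
  t0 <- trace$time[1]
  half <- window / 2
  keep <- mwv$centers - half >= t0 + edge_margin &
    mwv$centers + half <= t0 + standstill
  if (!any(keep)) stop("no complete calibration window inside the stand-still prefix")
  baseline <- max(mwv$variance[keep])
  if (baseline <= 0) {
    stop("degenerate stand-still prefix: zero variance; record with the ",
         "sensor active (some noise floor) or supply an explicit threshold")
  }
  structure(list(baseline_variance = baseline,
                 threshold = multiplier * baseline,
                 window = window, multiplier = multiplier),
            class = "standstill_calibration")
}

#' @export
print.standstill_calibration <- function(x, ...) {
  cat(sprintf(
    "<standstill_calibration> baseline %.3g g^2, threshold %.3g g^2 (x%g, %g s window)\n",
    x$baseline_variance, x$threshold, x$multiplier, x$window))
  invisible(x)
}

#' Detect walking bounds by moving-window variance
#'
#' Scans the mean-removed resultant acceleration with a dense moving-window
#' variance. The walk start is the first window center whose variance exceeds
#' the calibrated threshold and stays above it for at least `min_duration`
#' seconds; the stop is the last such center.
#'
#' @param trace A filtered [acceleration_trace()] from the same recording
#'   session as `calib`.
#' @param calib A [calibrate_standstill()] result.
#' @param window Moving-window length in seconds (default 0.5).
#' @param min_duration Minimum time the variance must stay above threshold for
#'   a crossing to count as walking (default 0.5 s).
#' @param distance Course distance in metres attached to the segment
#'   (default 5).
#' @return A [walk_segment()]. A detected walk shorter than 1 s triggers an
#'   "implausible walk" warning.
#' @export
detect_walk_bounds <- function(trace, calib, window = 0.5,
                               min_duration = 0.5, distance = 5) {
  stopifnot(inherits(trace, "acceleration_trace"),
            inherits(calib, "standstill_calibration"))
  fs <- trace$sampling_rate
  r <- resultant_acceleration(trace)
  r <- r - mean(r)
  mwv <- moving_window_variance(r, trace$time, fs, window)
  above <- mwv$variance > calib$threshold
  if (!any(above)) stop("no walk detected: no window variance exceeds the threshold")
  # runs of consecutive above-threshold window centers spanning >= min_duration
  rl <- rle(above)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  need <- ceiling(min_duration * fs) + 1L
  ok <- rl$values & rl$lengths >= need
  if (!any(ok)) stop("no walk detected: no sustained above-threshold interval")
  first_run <- which(ok)[1]
  last_run <- which(ok)[sum(ok)]
  start_time <- mwv$centers[starts[first_run]]
  stop_time <- mwv$centers[ends[last_run]]
  if (stop_time - start_time < 1) {
    warning("implausible walk: detected bout shorter than 1 s")
  }
  walk_segment(start_time, stop_time, distance = distance)
}

#' Average gait speed over a walk segment
#'
#' @param segment A [walk_segment()].
#' @return Speed in m/s: `distance / (stop_time - start_time)`.
#' @export
gait_speed <- function(segment) {
  stopifnot(inherits(segment, "walk_segment"))
  segment$distance / (segment$stop_time - segment$start_time)
}
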