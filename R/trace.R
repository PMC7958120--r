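#' Tri-axial acceleration trace
#'
#' Container for a uniformly sampled tri-axial accelerometer recording from a
#' pelvis-worn phone. Axes follow the anatomical convention: anterior-posterior
#' (AP), medial-lateral (ML) and vertical (V), all in units of g. The vertical
#' axis carries the +1 g gravity offset of a phone worn upright at the pelvis.
#'
#' @param time Numeric vector of sample times in seconds, strictly increasing
#'   and uniform (jitter tolerance 1e-6 s).
#' @param ap,ml,v Numeric vectors of acceleration in g, same length as `time`.
#' @param sampling_rate Sampling rate in Hz; inferred from `time` when `NULL`.
#' @return An object of class `acceleration_trace`: a list with elements
#'   `time`, `ap`, `ml`, `v` and `sampling_rate`.
#' @export
acceleration_trace <- function(time, ap, ml, v, sampling_rate = NULL) {
  stopifnot(is.numeric(time), is.numeric(ap), is.numeric(ml), is.numeric(v))
  n <- length(time)
  if (n < 2L) stop("an acceleration trace needs at least 2 samples")
  if (length(ap) != n || length(ml) != n || length(v) != n) {
    stop("time, ap, ml and v must have equal length")
  }
  if (!all(is.finite(c(time, ap, ml, v)))) {
    stop("acceleration trace contains non-finite values")
  }
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6) {
    stop("sampling is not uniform (jitter exceeds 1e-6 s)")
  }
  if (is.null(sampling_rate)) sampling_rate <- 1 / stats::median(dt)
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  structure(
    list(time = as.numeric(time), ap = as.numeric(ap), ml = as.numeric(ml),
         v = as.numeric(v), sampling_rate = sampling_rate),
    class = "acceleration_trace"
  )
}

#' @export
print.acceleration_trace <- function(x, ...) {
  cat(sprintf(
    "<acceleration_trace> %d samples @ %.6g Hz (%.2f s)\n",
    length(x$time), x$sampling_rate, x$time[length(x$time)] - x$time[1]
  ))
  cat(sprintf("  axis RMS about mean [g]: AP %.4f  ML %.4f  V %.4f\n",
              stats::sd(x$ap), stats::sd(x$ml), stats::sd(x$v)))
  invisible(x)
}

#' @export
as.data.frame.acceleration_trace <- function(x, ...) {
  data.frame(time_s = x$time, acc_ap_g = x$ap, acc_ml_g = x$ml, acc_v_g = x$v)
}

#' @export
length.acceleration_trace <- function(x) length(x$time)

trace_duration <- function(trace) trace$time[length(trace$time)] - trace$time[1]

#' Read an acceleration trace from delimited text
#'
#' Expects a header row with columns `time_s, acc_ap_g, acc_ml_g, acc_v_g`
#' (comma-separated). Accelerations recorded in m/s^2 can be converted at
#' ingest with `units = "ms2"`.
#'
#' @param path Path to the delimited text file.
#' @param units Either `"g"` (default, no conversion) or `"ms2"` (divided by
#'   the standard gravity 9.80665 m/s^2 on read).
#' @return An [acceleration_trace()].
#' @export
read_trace <- function(path, units = c("g", "ms2")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("time_s", "acc_ap_g", "acc_ml_g", "acc_v_g")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("trace file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  k <- if (units == "ms2") 1 / 9.80665 else 1
  acceleration_trace(df$time_s, df$acc_ap_g * k, df$acc_ml_g * k, df$acc_v_g * k)
}

#' Write an acceleration trace as delimited text
#'
#' @param trace An [acceleration_trace()].
#' @param path Output file path; columns `time_s, acc_ap_g, acc_ml_g, acc_v_g`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "acceleration_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
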