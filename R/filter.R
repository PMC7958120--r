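#' Zero-phase low-pass Butterworth filter
#'
#' Applies a forward-backward (zero net phase shift) low-pass Butterworth
#' filter to each axis of a trace. The forward-backward pass squares the
#' magnitude response, so the effective attenuation at twice the cut-off of a
#' 4th-order design is 1/(1 + 2^8), about -48 dB.
#'
#' @param trace An [acceleration_trace()].
#' @param cutoff Cut-off frequency in Hz (default 6).
#' @param order Filter order of the one-way design (default 4).
#' @return The filtered [acceleration_trace()]. The first and last ~0.5 s carry
#'   edge transients; calibration routines exclude them.
#' @export
lowpass_filter <- function(trace, cutoff = 6, order = 4) {
  stopifnot(inherits(trace, "acceleration_trace"))
  fs <- trace$sampling_rate
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 ||
      cutoff >= fs / 2) {
    stop("cutoff must lie in (0, sampling_rate/2); got ", cutoff,
         " Hz at fs = ", fs, " Hz")
  }
  if (order < 1) stop("order must be >= 1")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  acceleration_trace(
    time = trace$time,
    ap = as.numeric(signal::filtfilt(bf, trace$ap)),
    ml = as.numeric(signal::filtfilt(bf, trace$ml)),
    v  = as.numeric(signal::filtfilt(bf, trace$v)),
    sampling_rate = fs
  )
}

#' Resultant (vector-magnitude) acceleration
#'
#' Per-sample Euclidean norm over the three axes, in g.
#'
#' @param trace An [acceleration_trace()].
#' @return Numeric vector, one value per sample.
#' @export
resultant_acceleration <- function(trace) {
  stopifnot(inherits(trace, "acceleration_trace"))
  sqrt(trace$ap^2 + trace$ml^2 + trace$v^2)
}
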