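#' Approximate entropy (ApEn)
#'
#' Regularity statistic of a scalar time series: the logarithmic likelihood
#' that runs of patterns of length `m` that are close (within tolerance `d`)
#' remain close at length `m + 1`. Low values indicate regular, repeatable
#' series (a noiseless periodic signal approaches 0); uncorrelated noise
#' yields high values.
#'
#' The implementation follows the original Pincus formulation with
#' self-matches included:
#' `ApEn(N, m, d) = Phi_m(d) - Phi_{m+1}(d)` where
#' `Phi_k(d) = (N - k + 1)^{-1} sum_i ln C_i^k(d)` and `C_i^k(d)` is the
#' fraction of embedded vectors of length `k` within Chebyshev distance less
#' than `d` of vector `i`. The tolerance is `d = tolerance_fraction * sd(x)`,
#' so ApEn is invariant under affine rescaling of the series.
#'
#' @param x Numeric series (length must exceed `m + 1`; at least ~100 samples
#'   recommended for stable estimates).
#' @param m Pattern length (default 2).
#' @param tolerance_fraction Tolerance as a fraction of the series standard
#'   deviation, in (0, 1) (default 0.2).
#' @return Non-negative scalar. A constant series (zero SD) returns 0 with a
#'   warning: every pattern is trivially similar. Although a range of 0-2 is
#'   often quoted for physiological series at these settings, the statistic is
#'   not bounded by 2 for arbitrary tolerances, so no upper bound is enforced.
#' @export
approximate_entropy <- function(x, m = 2, tolerance_fraction = 0.2) {
  stopifnot(is.numeric(x))
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("m must be a positive integer")
  }
  if (!is.numeric(tolerance_fraction) || length(tolerance_fraction) != 1 ||
      tolerance_fraction <= 0 || tolerance_fraction >= 1) {
    stop("tolerance_fraction must lie in (0, 1)")
  }
  N <- length(x)
  if (N <= m + 1) stop("series too short for pattern length m = ", m)
  if (!all(is.finite(x))) stop("series contains non-finite values")
  s <- stats::sd(x)
  if (s == 0) {
    warning("constant series: ApEn defined as 0 for degenerate input")
    return(0)
  }
  d <- tolerance_fraction * s
  phi <- function(k) {
    nk <- N - k + 1L
    # embedded vectors as columns of lagged copies; pairwise Chebyshev counts
    within <- matrix(TRUE, nk, nk)
    for (l in 0:(k - 1L)) {
      seg <- x[(1L + l):(nk + l)]
      within <- within & (abs(outer(seg, seg, "-")) < d)
    }
    counts <- rowSums(within)  # self-match included, so counts >= 1
    mean(log(counts / nk))
  }
  phi(m) - phi(m + 1L)
}
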