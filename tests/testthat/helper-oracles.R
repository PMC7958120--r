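# Independent brute-force oracles kept deliberately naive: they define the
# expected semantics against which the vectorized implementations are checked.

# ApEn by explicit double loop over embedded vectors (Chebyshev distance,
# self-matches included, tolerance = tf * sd(x)).
apen_oracle <- function(x, m = 2, tf = 0.2) {
  N <- length(x)
  d <- tf * stats::sd(x)
  phi <- function(k) {
    nk <- N - k + 1L
    tot <- 0
    for (i in seq_len(nk)) {
      cnt <- 0L
      xi <- x[i:(i + k - 1L)]
      for (j in seq_len(nk)) {
        if (max(abs(x[j:(j + k - 1L)] - xi)) < d) cnt <- cnt + 1L
      }
      tot <- tot + log(cnt / nk)
    }
    tot / nk
  }
  phi(m) - phi(m + 1L)
}

# Dense sliding-window variance scan by explicit loop.
rollvar_oracle <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
         function(i) stats::var(x[i:(i + w - 1L)]), numeric(1))
}

# Exhaustive cut-point scan over midpoints (max sens + spec, ties -> higher
# sensitivity, then lowest threshold).
cutpoint_oracle <- function(values, labels, direction = "<=") {
  u <- sort(unique(values))
  cands <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (thr in cands) {
    pred <- if (direction == "<=") values <= thr else values > thr
    sens <- sum(pred & labels) / sum(labels)
    spec <- sum(!pred & !labels) / sum(!labels)
    if (is.null(best) || sens + spec > best$sens + best$spec + 1e-12 ||
        (abs(sens + spec - best$sens - best$spec) <= 1e-12 &&
         sens > best$sens + 1e-12)) {
      best <- list(thr = thr, sens = sens, spec = spec)
    }
  }
  best
}

# Sinusoidal tri-axial trace for filter tests.
sine_trace <- function(freq, fs = 50, dur = 10, amp = 1) {
  t <- seq(0, dur, by = 1 / fs)
  s <- amp * sin(2 * pi * freq * t)
  acceleration_trace(t, s, s, 1 + s, sampling_rate = fs)
}

# Least-squares amplitude of a sinusoid at a known frequency (robust to the
# filter's edge transients when fitted over an interior window).
fitted_amplitude <- function(x, t, freq) {
  fit <- stats::lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
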