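---
title: "Smartphone gait and posture features for preoperative frailty assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smartphone gait and posture features for preoperative frailty assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitfrail)
```

## The clinical problem

Older adults awaiting cardiac surgery differ widely in physiologic reserve.
Frail patients — conventionally operationalised as those walking a marked
5-m course slower than 0.833 m/s — face elevated risk of postoperative
morbidity and mortality, yet frailty is rarely quantified in routine
preoperative visits. A pelvis-worn smartphone sampling its tri-axial
accelerometer at 50 Hz during a short protocol (quiet stance for 30 s, then
a 5-m walk) yields enough signal to estimate gait speed, inter-step timing,
movement variability, and postural-sway complexity — and those features feed
a simple linear score of adverse postoperative outcome.

`gaitfrail` implements that pipeline end to end: a synthetic-recording
generator with frail/non-frail group structure, the signal-feature chain,
approximate entropy and sway dispersion metrics, frailty classification,
outcome severity scoring, the published five-predictor adverse-outcome
model, model refitting with diagnostics, and single-variable cut-point
analysis.

## Signal chain and its conventions

**Axes and units.** Traces carry anterior-posterior (AP), medial-lateral
(ML) and vertical (V) acceleration in g end to end; a constant +1 g gravity
offset rides on V for an upright pelvis-worn phone. Conversion from m/s² is
offered at ingest only.

**Filtering.** Every analysis stage begins with a zero-lag (forward-
backward) 4th-order low-pass Butterworth filter at 6 Hz. The double pass
squares the magnitude response, so a 12 Hz component is attenuated by about
48 dB while gait-band components (≤ 4 Hz) pass essentially unchanged, with
zero net phase shift. The first and last half second of a filtered recording
carry edge transients and are excluded from calibration statistics.

**Walk detection.** The resultant (vector-magnitude) acceleration is scanned
with a dense half-second moving-window variance (unbiased estimator, hop of
one sample). The detection threshold is calibrated per recording: 3 times
the maximum window variance observed during the initial 2 s stand-still
(the multiplier is exposed; 3 is the default). The walk starts at the first
window center whose variance exceeds the threshold and stays above it for at
least 0.5 s, and stops at the last such center. Average gait speed is the
course distance (5 m) divided by the detected duration. Because the window
looks 0.25 s ahead of and behind its center, detected bounds sit slightly
outside the true bout; with the generator's gait initiation/termination
ramps the net bias on speed is under a few percent (measured in the test
suite over 50 subjects per group).

**Step detection.** No extraction rule for inter-step time is standard for
pelvis-worn phones, so the package uses peak picking on the filtered
vertical axis within the detected walk: local maxima separated by at least a
0.25 s refractory period, with prominence at least half the segment SD and
an absolute height floor of 0.01 g above the segment mean (pelvis-level step
impacts are at least a few hundredths of g; smaller maxima are sensor
noise). Inter-step times are the successive differences of the surviving
peaks; fewer than three peaks is an error, not a silent zero.

**RMS.** Per-axis root-mean-square is computed on mean-removed signal
restricted to the walk segment, because the ~0.1 g clinical RMS scale is
incompatible with retaining the 1 g gravity component on V. RMS is therefore
translation invariant and absolutely homogeneous.

## Approximate entropy

Approximate entropy (ApEn) quantifies the regularity of a series: the
logarithmic likelihood that patterns of length `m` that match within
tolerance `d` still match at length `m + 1`. The package implements the
original Pincus formulation, Φ^m − Φ^(m+1), with self-matches included
(guaranteeing nonzero counts inside the logarithm) and the Chebyshev
(max-norm) distance between embedded vectors. Defaults are `m = 2` and
`d = 0.2 × SD` of the series.

Two documented readings in this area deserve a note. First, the tolerance is
sometimes written as "0.2% of the standard deviation"; taken literally
(0.002 × SD) that drives ApEn toward its maximum on every physiological
signal, so the package uses the standard convention 0.2 × SD and exposes the
fraction as a parameter. Second, a 0–2 range is often quoted for ApEn at
these settings; the statistic is not in fact bounded by 2 for arbitrary
tolerances, so the range is documented but never asserted.

A naive O(N²) double-loop oracle lives in the test suite and the production
implementation must agree with it to 1e-12 across random series
(N ≤ 200, m ∈ {1, 2, 3}).

**Sway proxy.** Force-plate center-of-pressure series are not available from
a phone; the package derives a planar sway proxy as mean-removed (AP, ML)
acceleration scaled by a nominal 1000 mm per g, tagged
`"acceleration-proxy"` in every output. ApEn of the ML channel and of the
planar resultant feed the adverse-outcome model; path length, mean sway
velocity, mean sway radius, 95% confidence-ellipse area (χ², 2 df — "sway
area" has no single standard definition, this is the one adopted) and the SD
of the radial displacement summarise dispersion.

## The adverse-outcome model and outcome scoring

The published score is linear in five predictors:

```
Score = 44.13 − 26.96·RMS_AP − 28.29·RMS_V + 13.33·ApEn_ML_COP
        − 46.85·ApEn_R_COP + 5.35·StepTime
```

with coefficients stored at their printed two-decimal precision
(`published_adverse_model()`); worked-example checks therefore use a ±0.06
band to absorb rounding. Postoperative events carry severity weights (death
7, prolonged ventilation 6, prolonged stay 5, skilled-nursing-facility
discharge 4, stroke or renal failure 3, reoperation 2, deep sternal wound
infection 1). How multiple events combine is not standardised; the package
defaults to the **sum** of weights (a multi-event patient can plausibly
exceed the single-event ceiling of 7) with `max` available.

Of the five printed held-out test rows, only ID02 and D25 are internally
consistent with the published coefficients; the ApEn entries of the other
three are implausible against the ~1.1 clinical scale and their scores are
not reproducible from the printed inputs. `example_test_patients()` ships
all five rows with this caveat documented rather than silently correcting
them.

`fit_adverse_model()` refits by OLS and reports R² (computed directly from
residual and total sums of squares), Mallows' Cp referenced to the full
five-predictor model (for the full model the identity Cp = p holds and is
tested), and per-predictor VIFs from the inverse predictor correlation
matrix, flagged at VIF ≥ 5. Perfect collinearity is a hard error naming the
cause. The original 16-patient outcome scores were never published, so
refitting the clinical model is impossible by construction; the package
claims (and tests) parameter recovery on synthetic data only.

**Frailty boundary.** Strictly less than 0.833 m/s is frail; 0.833 m/s
exactly is non-frail (the strict reading matches the operational definition
used for group assignment; an alternative severe threshold of 0.65 m/s is
available as a parameter).

**Cut-point analysis.** `cutpoint_analysis()` scans every midpoint between
sorted unique values and maximises sensitivity + specificity, breaking ties
toward higher sensitivity (screening use favours catching morbid patients).
Morbidity for this purpose is any nonzero outcome score.

## The synthetic-data generator

No recordings were released with the source study, so the generator is a
first-class, tested module that defines the study conditions.

**Walk traces.** A quiet stand-still lead-in (3 s, Gaussian noise floor
0.02 g), then a walking bout of exactly `distance / speed` seconds, then a
2 s tail. The walking signal is a sum of harmonics at the step frequency
(vertical and AP each carry a second harmonic at 0.3 relative amplitude; ML
oscillates at the stride frequency, half the step rate), with amplitudes
solved so that filtered, mean-removed per-axis RMS over the bout matches the
profile's targets. Gait initiation and termination are 0.6 s half-sine
ramps *inside* the bout, and the carriers start at phase π/2 — the first
step is an impact, not a zero crossing — which keeps onset energy growth
sharp enough for the variance scan to localise it. Group defaults follow the
clinical structure: frail 0.67 m/s, 0.654 s steps, RMS (AP, V, ML) =
(0.12, 0.11, 0.11) g; non-frail 0.98 m/s, 0.573 s, (0.15, 0.17, 0.15) g.

**Stance traces.** Horizontal sway acceleration is the mixture
`reg · periodic + (1 − reg) · band-limited noise` (components standardised
to unit SD before mixing), scaled to 0.0065 g (frail) or 0.004 g
(non-frail) — about 6.5 and 4 mm of proxy sway at the nominal scale,
bracketing the reported 6.45 mm clinical SD cut-off. The periodic component
is a 0.4 Hz sine plus an exact second harmonic (strictly periodic, so
`reg = 1` gives ApEn < 0.3); the noise component is white Gaussian low-passed
at 16 Hz (broadband enough that `reg = 0` gives ApEn > 1 at N = 1500).
ApEn is insensitive to the mixing fraction until the periodic part dominates:
the mean curve is flat within Monte Carlo error for `reg` ≤ 0.4 and falls
steeply from ~1.67 to ~0.23 thereafter, which is why the monotonicity
property is tested on the grid {0, 0.5, 0.75, 0.9, 1} with paired seeds.

**Cohorts.** Feature tables are drawn from group-specific normals at the
clinical group moments above (normality is the generator's assumption — the
source tables constrain only means and SDs). The latent adverse score is the
published model evaluated at the drawn features plus zero-mean Gaussian
noise (default SD 0.75 on the score scale; 0 gives exact linear structure
for parameter-recovery tests). Events derive from severity-ordered latent
thresholds (SNF 3.9, ventilation 4.3, stroke 4.8, renal failure 5.2,
reoperation 5.5, prolonged stay 5.8, death 6.2, DSWI 7.0) chosen once so a
frail-heavy cohort shows the clinically expected mix — skilled-nursing
discharge and ventilation common, death rare. All randomness in a call flows
from a single seed; identical (config, seed) reproduces outputs bit for bit.

**What passing tests do and do not show.** The generator produces clean
quasi-periodic gait with stationary noise, a single walking bout, perfect
protocol compliance and no postural transitions, tremor, or device
misalignment. Tests against it validate the *algorithms* (detection logic,
feature definitions, model algebra), not field robustness on real patient
recordings.

## Numerical choices and degenerate inputs

* Sampling must be uniform within 1e-6 s jitter; traces are validated on
  construction.
* A constant stand-still prefix (zero variance) is a calibration error with
  a remediation hint, not a zero threshold.
* A constant series has ApEn defined as 0 with a warning.
* Detected walks shorter than 1 s warn ("implausible walk"); no sustained
  above-threshold window is a hard "no walk detected" error.
* Walks shorter than 4 step cycles are rejected at generation time as
  unusable trials.
* Cut-point ties break toward higher sensitivity, then the lowest threshold.
* Reports print at 3 decimals; full precision is retained in the objects
  and machine-readable outputs.

## Problem sizes in the shipped tests

The suite exercises 50 synthetic subjects per group for gait recovery,
20 seeds per condition for ApEn-level and monotonicity checks, 100 random
series for oracle equivalence, and cohorts of 12–40 subjects for model
fitting — sizes at which every statistical margin tested (5% speed/step
recovery, ApEn thresholds, coefficient recovery to 1e-6) holds with
comfortable room under the seeds used.

## Known limitations

* The acceleration sway proxy is a stand-in for center-of-pressure data;
  its ApEn values are not numerically comparable to force-plate COP ApEn.
* Gait speed relies on variance-based bout detection; movement artifacts
  immediately before or after the walk shift the detected bounds.
* The published model's fitted diagnostics (Cp 2.77, R² 0.52) are carried
  as metadata only — the training outcomes were never released, so they are
  not recomputable.
* No orientation estimation or sensor fusion: the phone is assumed upright
  at the pelvis, and no gyroscope or magnetometer channels are used.
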