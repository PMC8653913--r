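---
title: "Methods: smoothing and peak features for ambulatory EDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoothing and peak features for ambulatory EDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edapeaks)
```

## The problem

Wrist-worn dry-electrode sensors record skin conductance (SC, in
microsiemens) at low rates (typically 4 Hz) while participants go about
structured tasks. The signal is the sum of a slowly drifting tonic level
(the skin conductance level, SCL) and phasic skin conductance responses
(SCRs) — transient rises with a fast onset and a slower recovery — plus
measurement noise, motion artifacts and, with dry electrodes, stretches of
near-zero readings when the band loses skin contact. The analysis goal is
not the raw trace but a small set of per-task features of the *peaks* of a
smoothed profile: how many SCRs occurred, how soon, how large, and how
fast the signal recovered.

## Preprocessing

**Segmentation.** Each task window is cut out of the recording and
re-expressed in seconds elapsed since the task start, so profiles are
comparable across participants and assessments. Transmission gaps remain
gaps: both smoothers tolerate unequally spaced samples, so nothing is
interpolated.

**Filtering (optional).** A linear-phase windowed-sinc FIR low-pass,
designed with `signal::fir1` and normalized to unit DC gain. Defaults: 16
taps (four per hertz of sampling) and a 0.5 Hz cutoff — SCR energy at 4 Hz
sampling lies well below this, while transmission noise sits near Nyquist.
The cutoff is a free choice (the tap-count convention does not fix it) and
is exposed as a parameter. An even tap count has a half-integral group
delay of (16 − 1)/2 = 7.5 samples; it is removed exactly by averaging the
two straddling convolution outputs, which is itself linear-phase (a
half-sample interpolator), so peak times are not shifted. Samples whose
filtered value depends on edge padding are flagged `transient` rather than
dropped.

**Validity.** Samples with SC below 0.05 µS are flagged `near_zero`, the
established exclusion rule for loose electrode contact. The mask is always
computed from the *raw* conductance, so raw and filtered pipelines flag
identical indices. Flagged runs are excised with the time axis preserved
(yielding unequally spaced data) rather than split into separate profiles
or zero-filled; an all-invalid segment is a reported failure, mirroring
how unusable participants are discarded in practice.

**Normalization.** Within one task segment,
$x' = 1 - \frac{\max - x}{\max - \min}$, computed over valid samples only.
The minimum maps to 0 and the maximum to 1, making profiles with very
different conductance ranges comparable; the min and max used are stored
with the profile. A constant segment has no scale and is a reported
failure, not a silent zero.

## Penalized B-spline smoothing

The profile is treated as a single smooth function estimated as a linear
combination of cubic B-splines on equally spaced interior knots, with a
curvature penalty:
$$\min_c \; \sum_i \big(y_i - B(t_i)c\big)^2 + \lambda \int f''(t)^2\,dt.$$

Numerical choices:

* The penalty matrix $\int B_j'' B_k''$ is assembled exactly by
  Gauss–Legendre quadrature per inter-knot interval (the integrand is
  piecewise polynomial).
* The penalty is rescaled by `tr(BᵀB)/tr(Ω)` so that λ is dimensionless:
  the same λ grid behaves comparably across time spans and sampling
  rates, and the affine null space is reachable within the default grid.
* λ is selected by generalized cross-validation,
  `GCV = n·SSE/(n − df)²` with `df` the trace of the smoother map, over a
  log-spaced grid `1e-6 … 1e4` (21 points).
* The interior-knot count is selected by GCV over the ladder
  {5, 9, 13, 17, 21, 29, 37, 53, 75, 107, 149}, capped at a quarter of the
  sample size, ties toward fewer knots. The ladder extends beyond the
  thirties deliberately: for 4 Hz, 300 s profiles with realistic SCR rise
  times, a 37-knot basis (about 8 s between knots) is resolution-limited —
  apex positions are biased by one to three seconds even at λ → 0, and GCV
  still improves by 25–40% per additional ladder step. Once the basis is
  rich enough, λ (not the knot count) controls smoothness, which is the
  premise of selecting a generous basis and penalizing it. A fixed basis
  size (`n_basis = 13`) bypasses selection entirely.
* Derivatives are exact derivatives of the fitted spline via derivative
  design matrices — never finite differences — and evaluation outside the
  basis span is an error rather than an extrapolation.

Assumptions: the profile is a smooth function observed with roughly
homoscedastic noise. Serial correlation in the errors is *not* modelled
here; GCV then tends to undersmooth, which the drop threshold downstream
tolerates (micro-wiggles have drops far below 0.1).

## Local polynomial regression with AR errors

The second smoother models the serial correlation directly:
$$y_t = m(t) + \varepsilon_t, \qquad
\varepsilon_t = \beta_1\varepsilon_{t-1} + \dots +
\beta_d\varepsilon_{t-d} + \eta_t.$$

The estimation is two-stage profile least squares:

1. *Initial fit* $\hat m_I$: local linear regression under working
   independence. Kernel: Epanechnikov (the standard choice; the result is
   insensitive to the kernel). Bandwidth: direct plug-in
   (`KernSmooth::dpill`), converted from its Gaussian kernel to
   Epanechnikov by the canonical-bandwidth ratio (≈ 2.214) and clipped to
   `[3 × median spacing, span/4]`; if the plug-in pilot fails,
   leave-one-out cross-validation over a log grid is the fallback.
2. *Error model*: residuals $\hat\varepsilon_t = y_t - \hat m_I(t_t)$
   feed a difference-based estimator — least squares of
   $\hat\varepsilon_t$ on its $d$ lags, with the trend differenced out
   once through the initial fit rather than refit. The order $d$ is
   selected by BIC, `n·log(σ̂²) + d·log(n)`, over `d = 0…8` (two seconds
   of history at 4 Hz). All candidate orders are scored on a common
   effective sample (the series minus its `d_max` leading points) so the
   criteria are comparable; the winning order is then refit on the full
   series. Non-stationary estimates are flagged, not silently accepted.
3. *Correction and final fit*:
   $y^*_t = y_t - \sum_k \hat\beta_k\hat\varepsilon_{t-k}$ has
   (approximately) white errors; a fresh plug-in bandwidth is selected on
   $y^*$ (the autocorrelation that inflates bandwidth selectors has been
   removed, so reusing the initial bandwidth would oversmooth) and the
   final local fit is evaluated on the dense grid. The first $d$ points
   have no complete lag history and are excluded; peak detection treats
   that boundary as the data limit. When BIC selects $d = 0$ the result
   *is* the working-independence fit, bit for bit.

Degree 1 (local linear) is the default; degrees 2 and 3 are available and
dampen peaks less at curvature maxima, at the cost of variance. For
degree 1 the second derivative is obtained by finite-differencing the
slope estimates; for degree ≥ 2 it is `2 × ` the quadratic coefficient.
Kernel windows holding fewer than `degree + 1` distinct points are widened
with a warning — never a silent `NaN`.

## Peak identification and features

Local maxima are zero crossings of the first derivative from positive to
negative with negative second derivative, on a grid ten times denser than
the sampling rate. Each crossing is refined by root-finding on the cubic
Hermite interpolant of the derivative over the bracketing grid interval
(we know both the derivative and its slope at the grid points), giving
apex times accurate well below the grid step. Minima are the opposite
crossings with *no* curvature condition, so kink minima — a new SCR
starting on a decaying tail — are found.

For each candidate maximum the nearest minimum on each side sets
`drop_left` and `drop_right`; both must exceed the threshold (default 0.1
normalized units) for the candidate to count as a peak. A maximum whose
right side reaches the end of the profile without an interior minimum is
an incomplete peak and is discarded regardless of its drops. At the left
edge the segment start value may serve as the left minimum (flagged
`left_is_edge`; symmetric exclusion is available as an option).

Features per profile: `n_peaks`; time to and amplitude at the first and
the highest peak (ties on amplitude resolve to the earliest apex, a
deterministic rule); reactivity as the time (s) from the highest apex to
its right minimum, with the drop magnitude also exported so a rate can be
formed; and the trapezoidal AUC of the whole curve together with the
segment duration, because unequal observed spans make raw AUC
incomparable across individuals. With no peaks, every peak-derived field
is explicitly missing (empty in CSV, `null` in JSON).

## The simulator and what passing tests mean

`simulate_eda()` builds
`sc(t) = tonic(t) + Σ A·(e^{−(t−onset)/τ_d} − e^{−(t−onset)/τ_r}) + AR noise
+ artifacts`, then overwrites dropout intervals with values uniform on
[0, 0.04] µS. The bi-exponential difference is the minimal shape with a
rapid rise and a slower decay; its apex is at
`onset + log(τ_d/τ_r)/(1/τ_r − 1/τ_d)` in closed form, which the truth
object records together with the noiseless signal value there. Artifacts
are additive half-cosine spikes 0.25–1 s wide. Simulation is bitwise
deterministic given a seed.

The packaged scenarios freeze the study conditions used for validation:
the **clean** scenario has five SCRs at onsets 25–225 s (50 s apart, full
recovery in between), rise constant 4 s and decay constant 8 s — apex
about 5.5 s after onset and recovery over 15–20 s, the sluggish shapes
actually seen at the wrist rather than palmar laboratory SCRs — with
realized apex heights 0.6–1.0 µS over a 2 µS tonic level that climbs
gently (0.1 µS quarter-wave over the task) and i.i.d. noise of 0.01 µS.
The drift is deliberately gentle: a steeper tonic slope provably moves the
apex of the *total* signal away from the closed-form kernel apex by more
than a second, which would corrupt any apex-recovery comparison
independent of the smoother. **ar-noise** replaces the noise with AR(1),
β = 0.6; **artifacted** adds three spikes; **dropout** places contiguous
loose-connection runs over 22.5% of the samples (a reported free-play loss
rate for this kind of study); **dense** spaces events 15 s apart with slow
(20 s) decays so small follower events ride on a tail and their
inter-event dip drops below 0.1 — they merge, demonstrating the threshold
behaviour, and its terminal event decays into the right limit, exercising
the incomplete-peak rule.

What the simulator does *not* emulate: temperature and accelerometry
channels (only SC is simulated), physiologically mechanistic sudomotor
dynamics, superposed SCR trains with sub-second onsets asynchrony, or the
heavy-tailed artifact distributions of real wrist data. Passing the
recovery tests therefore shows the chain is correct under its stated
model, not that every real profile is smoothed well — the two smoothers
genuinely fit different individuals differently, which is why both run
side by side by default.

## Problem sizes and runtime choices

The validation suite runs 300 s, 4 Hz profiles (1200 samples) end to end;
AR recovery uses 100 replicates of length 2000; whitening 50 replicates of
length 600; the detector-vs-oracle comparison 200 random smooth profiles;
the normalization contract 1000 random segments. These sizes put every
stochastic rate comfortably past its asserted bound while keeping the full
suite around a minute of compute.

## Known limitations

* The nearest-minimum drop rule is sensitive to micro-wiggles on peak
  shoulders when a fit undersmooths: a tiny shoulder dip becomes the
  "nearest minimum" and vetoes a real peak. The drop threshold and GCV
  usually prevent this; very noisy profiles may still lose peaks.
* GCV assumes independent errors; under strong serial correlation the
  spline smoother undersmooths. The AR-corrected local fit is the
  appropriate alternative there.
* Reactivity requires the highest peak to have an interior right minimum;
  a highest peak near the segment end is excluded by the right-limit rule
  and reactivity then refers to the next-highest retained peak.
* The normalization is per segment: amplitudes are comparable within a
  profile, not across profiles in microsiemens terms (the stored
  `min_eda`/`max_eda` allow back-conversion).
* Tonic/phasic decomposition is out of scope; features are computed on
  the normalized total signal.
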