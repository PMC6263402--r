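---
title: "Template-based step detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based step detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepscan)
```

## The detection model

A step, for this package, is a half-open interval `[start, end)` of
samples during which the foot moves between two foot-flat rests. The
detector assumes nothing about amplitude or sensor orientation; it
assumes only that a step *looks like* one of the exemplars in a template
library. Matching is done per component with the Pearson correlation,

$$\rho(y, z) = \frac{\mathrm{cov}(y, z)}{\sigma_y\,\sigma_z},$$

computed with population moments (the ratio is identical with sample
moments; fixing the convention makes the oracle tests bit-reproducible).
Pearson correlation is invariant under $y \mapsto a y + b$ for $a > 0$,
which is precisely the invariance a foot-worn sensor needs: gain absorbs
inter-subject amplitude differences, offset absorbs orientation bias.

Sliding each template component along the matching signal component
yields a correlation value $r(k, p, t)$ for every component $k$,
template $p$ and lag $t$. Strict local maxima of $r$ in $t$ — strictly
greater than both neighbours, boundaries excluded — form the candidate
set. Greedy selection then visits candidates in decreasing score order
and accepts any candidate whose interval overlaps no previously accepted
step; accepted intervals forbid their samples; iteration stops when the
best remaining score drops below $\lambda$. A final amplitude gate
discards a detected step when the signal's standard deviation over the
detected interval, on the matched component, is below $\mu$ times the
template's standard deviation on that component — without it, the scale
invariance would happily match templates against near-zero rest noise.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `lam` ($\lambda$) | 0.6 | none (correlation) | greedy stop threshold; every detection scores at least $\lambda$ |
| `mu` ($\mu$) | 0.1 | none (ratio of standard deviations) | rejects low-amplitude matches |
| `fs` | 100 | Hz | metadata for the template detector (all of whose thresholds are in samples); required by the baseline's bandpass filter |

Both thresholds sit on wide plateaus: on the synthetic benchmark the
precision and recall move by well under two percentage points across
$\lambda \in [0.5, 0.8]$ and $\mu \in [0.05, 0.15]$ (the
`run_sweep()` function recomputes this surface). The defaults were not
tuned to the simulator; they are the method's standard operating point.

Two internal conventions matter for reproducibility and are therefore
fixed rather than configurable:

* **Degenerate windows.** A constant signal window has no defined
  correlation. It is scored 0 ("no evidence of a step") and flagged,
  never `NaN` and never an error, because foot-flat rest produces
  constant windows as a matter of course and the greedy ordering must
  stay total. A window counts as constant when its variance is below
  $10^{-12}$ times its mean square, which catches exact-constant windows
  computed through running sums (cancellation residue) without touching
  genuinely small noise variance.
* **Ties.** Equal-scoring candidates are ordered by earliest lag, then
  lowest template index, then component. Real-valued ties are
  practically nonexistent, but a total deterministic order makes the
  optimized implementation provably equal to the naive reference.

Two further choices the method's definition leaves open:

* $\lambda$ is implemented as a pre-filter of the candidate set rather
  than a stop condition inside the loop; the two are provably
  equivalent (candidates below $\lambda$ can never be visited before the
  stop would fire) and the pre-filter is faster.
* The $\mu$ gate runs once, after the greedy loop. Samples freed by a
  discarded step are *not* returned to the pool: re-detection would
  require a feedback loop the greedy procedure does not have. The
  consequence is a marginal recall loss on genuinely low-amplitude
  steps, which is accepted and documented rather than patched.
* Timing errors (ΔStart, ΔEnd, ΔDuration) are computed from the
  precision-pass pairing; either pass could serve, and the precision
  pass is the one whose pairs are guaranteed one-per-detection.

## The synthetic generator

No clinical recordings ship with the package, so every stage is
exercised against a parametric simulator (`make_library()`,
`simulate_recording()`). A synthetic step has three components:

* **Angular velocity** (`gyr_y`): a positive swing lobe flanked by two
  negative dips — a three-Gaussian mixture whose centres and widths are
  fractions of the step duration.
* **Z-axis acceleration** (`acc_z`): band-limited oscillatory bursts at
  heel-off and heel-strike, at both ends of the step.
* **Vertical acceleration** (`acc_v`): a weak foot-lift hump followed by
  a dominant swing hump, each with a sharp rise and a slow decay. The
  rise and decay time constants are in *samples*, not fractions of the
  duration: impact timescales are set by mechanics, not by how long the
  step takes.

All components are tapered to zero at the template edges with a short
raised-cosine window so a planted step joins the surrounding rest
without a discontinuity, and normalized to unit population standard
deviation, which makes gains and noise levels interpretable as fractions
of template amplitude. Shape parameters are jittered per template to
diversify a library; durations are drawn uniformly from the configured
range (65–96 samples by default).

A recording is a leading rest (100 samples), the requested number of
steps separated by foot-flat rests of 30–60 samples, and a trailing
rest; each step is a randomly chosen library template scaled by a
per-step gain (0.8–1.2 by default), with white Gaussian noise at
`noise_sigma` times the template amplitude added everywhere and a
per-component DC offset applied last. The leading rest stands in for the
quiet-standing phase of a typical clinical protocol, scaled to one
second to keep simulated recordings compact. Low-amplitude
turning-like steps are available through `lowamp_fraction` (gain drawn
below the $\mu$ gate, labelled `uturn`); they are modelled *only* as
low-gain steps — distinct turning morphology is out of scope. Noise is
white because no sensor noise spectrum is assumed; the hooks for
colored noise would go in `sim_config()`.

What passing the synthetic benchmark shows — and what it does not: the
simulator produces steps that *are* library templates up to gain, noise
and offset, so near-perfect recovery demonstrates the correctness of the
correlation/greedy/gate machinery and its invariances, not clinical
performance. Real steps differ from every template in the library, real
noise is not white, and real annotations carry their own uncertainty;
absolute scores on real data will be lower and must be established on
real recordings.

### Why the vertical-acceleration morphology looks the way it does

The baseline's integration stage is a centred *box* average. The box
average of a compact squared-derivative pulse has a flat or
near-flat top, and on a flat top sensor noise freely creates several
strict local maxima, which the activity gate cannot remove because the
raw signal there is genuinely active. Oscillatory or wavelet-like impact
shapes (tried first) make this worse: their squared derivative ripples
at twice the carrier frequency and splits into multiple deterministic
lobes after integration. The hump-with-sharp-rise morphology
concentrates the squared derivative in a single narrow in-band lobe
(one strict maximum at any window near its width), while the slow decay
and the quiet remainder of the step keep every other candidate peak in a
low-raw-activity zone that the gate removes. With it, the grid-searched
baseline reaches a pooled F-measure above 0.95 on the benchmark across
library seeds — which is what makes an honest baseline comparison
possible at all. The multi-peak fixture used for the legacy-rule
comparison reverses the trick: a strong 12 Hz oscillation is carried on
the hump's decay, which a 20 Hz low-pass preset keeps (over-detection)
but a grid-tuned 6 Hz cut-off removes.

## The baseline

The Pan-Tompkins chain is implemented exactly as the classic sequence —
bandpass, derivative, squaring, moving-window integration — with three
packaging choices:

* the filter is a zero-phase (forward–backward) Butterworth of order 4,
  so peak positions are not lag-shifted and the peak-inside-annotation
  scoring stays unbiased; `fmin = 0` degrades to a pure low-pass;
* the integrator's edge windows shrink instead of padding, avoiding
  spurious edge peaks;
* the peak search takes strict local maxima of the transformed signal,
  and the activity gate keeps a peak only when the raw component's
  standard deviation over a symmetric neighbourhood reaches
  `noise_level` (a symmetric neighbourhood, the simpler of the two
  unstated possibilities). The gate defaults to off (`noise_level = 0`).

The baseline consumes the vertical-acceleration component by default
(the component the historical step-counting adaptations used); the
choice is a function argument. Its five parameters (`fmin`, `fmax`,
`ninte`, `neigh`, `noise_level`) are tuned by exhaustive grid search
maximizing pooled F-measure, ties broken by grid order. The legacy
preset (`fmin` 0 Hz, `fmax` 20 Hz, `ninte` 0.1 s, every-other-peak
selection) ships for the qualitative comparison; the activity gate, a
later addition, is applied in both modes.

## Degenerate inputs and numerical notes

* Correlations are clipped to $[-1, 1]$ after computation to absorb
  floating-point rounding.
* The fast sliding correlation (FFT cross-correlation plus running
  sums) matches direct per-lag evaluation to better than $10^{-9}$;
  this equivalence is asserted over randomized inputs in the test
  suite.
* Templates longer than the signal are skipped with a warning; if no
  template fits, detection errors out ("no usable template").
* Equal-valued correlation plateaus produce no candidates (the strict
  inequality is applied literally); plateaus have measure zero on real
  signals.
* Recordings with zero detections score precision `NA`, not 0 or 1;
  aggregation ignores `NA` scores.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on a
benchmark of 10 generated templates and 20 recordings of 30 steps each
(600 steps, roughly 4,000 samples per recording), with 81-point grids
for baseline tuning — sizes chosen so the whole suite completes in well
under a minute on a single core while every code path, including the
FFT correlation and the grid search, runs at realistic shape.

## Known limitations

* Matching is at native template length only — no time warping; steps
  much shorter or longer than every template are found with biased
  boundaries or missed.
* The detector is offline and single-foot; streaming detection and
  left/right fusion are out of scope.
* Low-amplitude steps below the $\mu$ gate are rejected by design;
  lowering $\mu$ trades this against false detections during rest.
* The simulator is a shape model, not a biomechanical one; it validates
  the algorithmic machinery, not clinical accuracy.
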