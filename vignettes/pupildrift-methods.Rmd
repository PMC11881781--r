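---
title: "Methods: event-locked pupillometry of illusory motion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked pupillometry of illusory motion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupildrift)
```

## The analysis model

Each trial is a 500 Hz recording of pupil diameter (mm) and gaze position
(degrees of visual angle, dva) that begins at a triggering event — the
appearance of an illusion pattern, or the cue for a controlled blink or
saccade — and ends shortly after the observer presses a key to report that
apparent motion in the pattern has ceased. The working hypothesis is that
the reflexive pupil response to the event (fast constriction, slow
re-dilation) modulates retinal illuminance, `E = L · π(d/2)²` Trolands for
display luminance `L` and pupil diameter `d`, and that the dilation phase
of this response drives the illusory motion. The pipeline therefore
reduces each trial to a constriction–dilation profile and asks whether its
trial-to-trial variation predicts the reported illusion duration.

The per-trial chain is:

1. **Event location.** Blink trials: the raw diameter sequence is scanned
   for runs of exactly zero (the tracker's "pupil lost" sentinel). A run of
   at least 60 ms (30 samples) denotes a blink; exactly one is required,
   and analysis starts 200 ms after its last zero, when the lid has cleared
   the pupil. Saccade trials: the smoothed horizontal gaze is scanned with
   a 40 ms (20-sample) lag; the saccade starts at the first lagged
   difference of at least 0.5 dva and ends at the first later difference
   below it, and analysis starts at the saccade end, which must fall in the
   first half of the recording. Onset trials are analysed from the first
   sample. Violations (no event, multiple blinks, late saccades, stray
   zeros in onset trials) mark the trial invalid with a recorded reason;
   invalid trials are quarantined, never silently dropped.
2. **Preprocessing.** On the analysed span, samples more than 3 scaled
   median absolute deviations (scale constant 1.4826, the Gaussian
   consistency factor) from the median of a moving 400 ms (200-sample)
   window are flagged and replaced by linear interpolation between their
   nearest unflagged neighbours (nearest-value extension at the edges);
   the result is smoothed with a centred 100 ms (50-sample) moving mean.
   Windows are centred with the convention of the corresponding Matlab
   functions (`isoutlier`, `movmean`): an even window of length *k* covers
   *k*/2 samples before and *k*/2 − 1 after, truncating at the sequence
   edges. The threshold comparison is strict, so constant stretches
   (zero MAD, zero deviation) are never flagged while an isolated spike
   within one always is. Gaze receives the same outlier-then-mean chain
   before saccade detection.
3. **Profile features.** From the smoothed span: the global minimum, the
   maximum before it (`max1`) and the maximum after it (`max2`), ties
   resolved to the earliest sample, searched to the end of the recording.
   The four derived measures are the constriction duration/amplitude
   (`max1 → min`) and dilation duration/amplitude (`min → max2`).
   A minimum at the first or last analysed sample means the corresponding
   phase is absent; such degenerate trials keep `NaN` measures and are
   excluded from the correlation layer — a zero-duration phase would
   distort correlations rather than inform them. Luminance changes are
   computed from pupil area, `100·(area(d₂) − area(d₁))/area(d₁)`, and the
   blur change over dilation as `100·(max2 − min)/min` (blur scales with
   diameter, not area).
4. **Inference.** Within each (participant, stimulus, experiment) cell
   with at least 3 valid trials, each measure is correlated (Pearson) with
   the reported illusion duration. Evidence per cell is a two-sided Bayes
   factor for ρ ≠ 0: the exact sampling density of r under bivariate
   normality, integrated over a uniform prior on (−1, 1) — the
   stretched-beta prior with κ = 1 that is the common default for this
   test; the source experiments did not state a prior, so the default is
   used. r-values are averaged across stimuli within participant, then
   across participants, with the standard error taken across participants;
   the median BF is taken over all cells of a measure.

## Numerical choices

- *Outlier replacement.* The published procedure says outliers were
  "removed"; interpolation (rather than deletion) is used so the uniform
  time grid the feature stage relies on is preserved.
- *MAD implementation.* The windowed median/MAD pass is a sliding sorted
  window in C++ (binary insertion/removal plus a two-pointer walk for the
  deviation median). It is exactly equal — boolean for boolean — to a
  literal per-window evaluation of the rule; the test suite asserts this
  against an independent plain-R reimplementation on random sequences.
- *Bayes factor.* The likelihood uses the Gauss-series form of the
  density of r (a ₂F₁(1/2, 1/2; n − 1/2; (1+ρr)/2) factor) and
  `stats::integrate` after peak-shifting in log space; |r| = 1 returns an
  infinite-evidence signal. The test oracle evaluates the same density
  through its cosh-integral representation on dense trapezoid grids; the
  two routes agree to well under 1%.
- *Report rounding.* Summary tables round half-away-from-zero to 3
  decimals, the convention of the published table they mirror.
- *Provenance.* Output tables carry the package version and an FNV-1a
  hash of the configuration; all thresholds live in a single
  `pipeline_config()` object and default to the published values.

## What the synthetic generator emulates

`generate_trial()` builds each trace from a deterministic waveform plus
noise. The waveform is piecewise smooth: a gentle linear pre-constriction
drift (0.05 mm/s), a smoothstep descent, a symmetric parabolic valley of
±150 ms around the minimum, a smoothstep rise, a symmetric parabolic cap
of ±150 ms around the post-minimum maximum, and an exponential relaxation
back toward baseline. The shape was chosen over, e.g., a difference of
gamma kernels for two properties that matter to validation: the extrema
have exact closed-form locations and values (ground truth is not itself a
numerical estimate), and the local symmetry at both extrema means the
centred moving-average smoother shifts neither extremum in time, so
recovery tolerances reflect noise rather than systematic bias. Default
timing and amplitude ranges follow the reported physiology: constriction
of 0.1–0.7 mm reaching the minimum 0.5–1 s after the event, dilation
lasting 1.5–5 s, baseline ≈ 3.1 mm. The dilation duration is a direct
generator parameter (not a time constant) so the quantity the correlation
layer targets has exact ground truth.

Blink trials prepend baseline samples, a 60–120 ms zero-run and a partial
re-opening ramp sized so the response begins exactly 200 ms after the
last zero; saccade trials add a ±10 → ∓10 dva sigmoidal gaze step
(~40 ms). Measurement noise is Gaussian (default sd 0.01 mm) with sparse
spike outliers (rate 0.002, magnitude 0.5–2 mm). Illusion durations are
drawn as a linear function of the nominal dilation duration plus Gaussian
noise, solved to hit a target correlation (default 0.7) with mean 4 s and
sd 1.2 s, spanning roughly the observed 1–7 s; they are quantised to 1 ms,
the resolution of a response timestamp. Stimulus effects scale the
constriction amplitude and mean illusion duration
(snakes > disks > Fraser–Wilcox).

Two deliberate divergences from the recording protocol: traces extend to
the later of button press + 250 ms and the post-minimum maximum (real
recordings stop at the former), so the full profile is always observable
and the nominal dilation duration is recoverable; and for saccade trials
the detected saccade end on the smoothed gaze step differs from the
injected transition time by up to ~100 ms of smoothing ramp, so
`max1`-time ground truth is only exact for onset and blink trials —
recovery tests use those, while interior extrema (the minimum, `max2`,
and the dilation duration) are exact in all conditions.

What passing tests on this generator do **not** show: robustness to
correlated physiological noise (hippus), foreshortening from gaze
eccentricity, partial blinks without zero samples, or real illusion
response behaviour — the generator encodes the monotone linear coupling
the analysis assumes, so correlation-layer tests validate the machinery,
not the scientific claim itself.

## Problem sizes used in validation

The shipped checks use 500 low-noise (sd 0.005 mm) trials for
ground-truth recovery (median errors: < 0.01 mm per point, < 20 ms per
duration), 100 replicate datasets of 4 participants × 3 stimuli × 20
trials for the correlation-ranking property, 200 threshold-straddling
events for detector sensitivity/specificity, and 100 random sequences of
up to 2000 samples for the preprocessing oracle. These sizes give the
stochastic checks comfortable margins (e.g. the dilation-duration rank
test separates means by roughly ten standard errors) while keeping a full
run in a few minutes.

## Known limitations

- The blink detector requires the tracker's zero-diameter encoding;
  dropouts recorded as non-zero garbage will surface as outliers instead,
  which the MAD stage handles only if they are brief.
- "Exactly one blink" and "saccade in the first half" are hard abort
  rules taken from the published procedure; long recordings with late
  re-fixations are discarded rather than re-windowed.
- The Bayes factor assumes bivariate normality through the sampling
  density of r; with n per cell around 10–20 this is an approximation of
  convenience, as it was in the source analysis.
- Correlations treat illusion duration as error-free; attenuation from
  response-time noise is not modelled.
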