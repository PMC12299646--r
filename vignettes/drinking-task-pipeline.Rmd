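---
title: "Methods: segmentation, metrics and statistics of the drinking-task pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, metrics and statistics of the drinking-task pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scapkin)
```

## The measurement problem

People with chronic shoulder pain and scapular dyskinesis show altered
scapular kinematics and muscle activity during everyday arm use. A standard
way to quantify this is a functional drinking task: the hand reaches for a
bottle, transports it to the mouth, the person drinks, the bottle is
returned, and the hand comes back to rest. The task decomposes into five
phases — reaching, forward transport, drink, backward transport, returning —
bounded by six events. This package implements the complete measurement
chain for that task: signal conditioning, event detection and phase
segmentation, per-phase kinematic and EMG outcomes, whole-task
movement-quality outcomes, test–retest reliability, and paired pre–post
inference, together with a synthetic-data generator that provides ground
truth for every stage.

## Signals and conditioning

Three signal families enter the pipeline:

* eleven joint-angle channels at 100 Hz (elbow flexion/extension, shoulder
  elevation, four scapular degrees of freedom — abduction/adduction,
  elevation/depression, upward/downward rotation, winging — and three trunk
  angles), in degrees;
* signed hand-path acceleration at 2000 Hz (m/s²);
* surface EMG of six scapular muscles (UT, MT, LT, SAup/mid, SAlow, LS) at
  2000 Hz.

Conditioning follows standard practice: EMG is band-pass filtered with a
2nd-order Butterworth at 20–450 Hz and rectified into a sliding-window RMS
envelope of 100 samples (50 ms at 2000 Hz); hand acceleration is low-pass
filtered with a 4th-order Butterworth at 4 Hz. All filters are applied
zero-phase (forward–backward), which preserves the timing of events used by
segmentation at the price of doubling the effective attenuation order. The
RMS envelope is returned same-length and centre-aligned with reflective edge
padding so EMG remains alignable with the kinematic clock; envelopes are
block-mean downsampled to 100 Hz before per-phase averaging, so phase
windows are defined on a single time base.

EMG amplitude is normalized to a submaximal isometric contraction (SVIC):
three 5-s repetitions per muscle; the reference is the mean over repetitions
of the mean RMS envelope of each repetition's central 3 s. The central
window discards ramp-up and ramp-down of the contraction; its width is a
package convention (the protocol specifies only "three 5-s repetitions")
and is configurable. Joint rest position is the mean of the first 5 s of
static recording.

## Event detection and segmentation

The six events are: task onset (hand acceleration leaves a ±0.3 m/s² band
around its resting mean), b1 = maximum elbow extension before the drink,
b2 = initiation of shoulder elevation, b3 = maximum shoulder elevation,
b4 = the next elbow-extension maximum, and task end (acceleration returns
into the band). Three operational choices close gaps the event definitions
leave open:

* **Sustain windows.** A threshold crossing counts only if sustained: 50 ms
  for onset, 200 ms for end, 100 ms for elevation initiation. These suppress
  single-sample noise crossings and are configurable
  (`segmentation_params()`).
* **Initiation of shoulder elevation.** Operationalized as the elevation
  velocity exceeding 5°/s (sustained). Threshold crossings of a smooth
  velocity rise are intrinsically late, so the reported time is refined by
  walking back from the velocity peak to the last sample at the rest
  velocity floor.
* **Adaptive refinement.** Zero-phase filtering and smoothing smear signal
  energy symmetrically around events, so refinement (walk-backs to the rest
  floor, extremum localization) always runs on the least-processed signal
  whose rest-segment noise estimate permits it: the raw channel when the
  rest segment is effectively noise-free, the smoothed channel otherwise.
  On noise-free recordings every boundary is therefore recovered exactly at
  sample resolution; on noisy recordings the smoothed path bounds the error
  (see below).

For noisy angle channels, event detection smooths with a 4th-order
zero-phase Butterworth at 3 Hz; extrema (b1, b3, b4) are then localized by a
least-squares quadratic fitted over ±0.15 s around the argmax, whose vertex
averages the noise rather than chasing it along the flat top of a smooth
peak. The elevation-initiation walk-back uses a milder 8 Hz smoothing: the
3 Hz kernel would smear the velocity onset backwards by tens of
milliseconds, while raw differentiation of a 1° -noise angle channel at
100 Hz yields ~70°/s velocity noise and no usable floor. With 1° angle
noise (a pessimistic level for modern IMU angle outputs), all six boundaries
are recovered within ±50 ms in ≥95% of trials; the test suite verifies this
on 200 seeded trials.

Extrema are global within their search windows (onset→b3 for b1, after b3
for b4), with ties broken to the earliest sample; whether extrema should be
global or local is not fixed by the event definitions, and the choice is
recorded here as the package convention.

## Outcomes

* **Range of motion**: max − min of a joint angle within a phase window.
  Windows are half-open `[start, end)` except the final phase, which
  includes the end sample; generator ground truth uses the identical
  convention.
* **Scapulohumeral rhythm (SHR)**: shoulder-elevation ROM divided by
  scapular upward-rotation ROM over the drink phase (the elevation portion
  of this task). The evaluation window is configurable; a scapular ROM
  below 0.5° raises a degenerate-denominator error rather than returning an
  unstable ratio.
* **Trunk compensation**: the signed deviation from the rest posture with
  maximal absolute value during the task. Referencing to rest posture
  (rather than the trial's first sample) is the package's choice; rest is
  re-estimated per trial.
* **Time-to-peak acceleration**: time of the largest absolute hand
  acceleration within reaching, as a percentage of task duration, earliest
  sample on ties.
* **Global movement smoothness**: the log dimensionless jerk of the hand
  velocity over onset→end,
  ln(D³/v²ₚₑₐₖ · ∫j²dt), with jerk estimated by second differences
  (second-order one-sided stencils at the window edges, where reaching
  movements concentrate real jerk). Larger values mean less smooth
  movement. The speed-normalized form is the default because it is
  invariant to both uniform time rescaling and amplitude scaling; an
  amplitude-normalized variant (D⁵/L², L the path length) is available via
  `run_config(jerk_variant = "amplitude")`. A single minimum-jerk segment
  gives exactly DJ = 720/(15/8)² = 204.8, i.e. ln DJ ≈ 5.322: the quintic's
  squared-jerk integral is 720 A²/D⁵ and its peak speed 15A/(8D). Published
  smoothness scores for this task (≈2–3) evidently use a different,
  platform-specific normalization that is not recoverable from the
  literature; smoothness is therefore validated by its invariances, its
  closed form, and its strict increase under velocity sub-peaks, not by
  matching printed values. Hand velocity comes from trapezoidal integration
  of the filtered acceleration with endpoint-pinned linear detrending
  (drift control), since the sensor provides acceleration only.
* **Trial aggregation**: five trials per session; the analysed value is the
  element-wise mean of trials 2–4 in execution order ("three central
  trials").

## Reliability and pre–post statistics

Test–retest reliability uses the average-measures absolute-agreement
intraclass correlation from the two-way ANOVA decomposition,
ICC = (MS_R − MS_E)/(MS_R + (MS_C − MS_E)/n), with the standard F-based 95%
interval (single-measures bounds with a Satterthwaite df, stepped up by
Spearman–Brown). The "two-way mixed, absolute agreement, average measures"
and "ICC(2,k)" formulations coincide numerically in this formula. Negative
estimates are legitimate outputs (no error is raised); the raw estimator is
returned untruncated. SEM = SD·√(1−ICC) and MDC95 = SEM·√2·1.96. Which SD
enters the SEM is not universally fixed; the default is the between-subject
SD of the first measurement, with a pooled-SD option
(`run_config(sem_sd = "pooled")`). Interpretation bands close the published
cut-point gaps as
little < 0.16 ≤ low < 0.50 ≤ moderate < 0.70 ≤ high < 0.90 ≤ very high; all
published ICC values of this protocol band identically under this
convention.

Pre–post inference gates on a Shapiro–Wilk test of the paired differences at
α = 0.05: parametric → paired t with Cohen's d = t/√n and mean ± SD
descriptives; otherwise Wilcoxon signed-rank with median ± IQR (type-7
quantiles). Zero differences use Pratt handling (zeros ranked, then
discarded from both sums, normal approximation with tie and continuity
correction); without zeros the exact small-sample distribution is used. The
prescribed visual histogram inspection cannot be automated and is flagged in
the output instead. No multiplicity adjustment is applied by default,
mirroring how such exploratory pre–post batteries are usually reported; a
Holm option exists. Design-stage power uses the noncentral t directly:
required n is the smallest integer whose paired-t power reaches the target.
For d = 13.2/20.71 = 0.63737, α = 0.05, power 0.80, the one-tailed
computation yields n = 17 (the two-tailed would require 22); the one-tailed
default was fixed by verifying which variant reproduces the published
requirement, and the tails are configurable.

## The synthetic-data generator

No recordings of this protocol are publicly deposited, so the generator is a
first-class module: it fabricates trials whose every downstream quantity is
known by construction, and all pipeline stages are validated against that
ground truth.

Design (the underlying study models no trajectories, so all shapes are
package choices, chosen once for identifiability and physiological
plausibility):

* **Hand path**: minimum-jerk position segments for the four transport
  movements (closed-form velocity/acceleration/jerk make smoothness
  analytically checkable); reach/transport path lengths default to 0.30 m
  and 0.25 m, a table-to-mouth bottle geometry.
* **Elbow**: half-cosine extension excursions (40° reach, 30° transport)
  whose maxima at b1/b4 have non-zero curvature, hence are localizable
  under noise (abutting minimum-jerk segments would meet with zero velocity
  *and* zero acceleration — a cubically flat, nearly unobservable peak).
* **Shoulder elevation**: flat until the drink phase, quarter-sine rise
  (60° by default, below the 120° analysis ceiling of the protocol) peaking
  at b3, quarter-cosine descent. The non-zero initial slope makes
  "initiation of elevation" a well-defined instant.
* **Scapular upward rotation** = shoulder elevation ÷ `shr_ratio`
  (default 1.5) plus noise, so SHR is exact by construction. The other
  scapular DOFs carry per-phase half-sine excursions with configurable
  amplitudes; trunk channels carry one signed half-sine over the task.
* **EMG**: per-phase plateau levels (%SVIC) smoothed by a 100-ms Hann ramp,
  scaled into acquisition units by the per-muscle SVIC amplitude, with
  multiplicative noise. Ground truth stores the per-phase *mean* of the
  noise-free envelope — the ramps make the mean differ slightly from the
  plateau, and the truth must be what the definitional computation yields.
  An optional raw-carrier mode (band-limited noise amplitude-modulated by
  the envelope) exercises the full band-pass + RMS chain.
* **Variability and effects**: amplitudes and EMG levels carry a
  subject-level multiplicative random effect (10% SD, shared by both
  sessions — this is what makes ICC > 0) and a trial-level effect (5% SD).
  Session M1 applies `effect_delta` additively on generator parameters, not
  post hoc on metrics, so recovery tests exercise the entire pipeline.
  Smoothness perturbations superimpose C²-continuous velocity sub-peaks
  (`a·sin²(πτ)sin(2πkτ)`) on the transport segments.
* **Determinism**: every random draw derives from the master seed plus
  subject/trial/session offsets; identical configurations are bit-identical.

Default conditions mirror the underlying protocol: 18 subjects, 5 trials
per session, two sessions, 100/2000 Hz, ≥5 s rest (6 s default), 1°
kinematic noise, 0.05 m/s² accelerometer noise at rest (well inside the
0.3 m/s² band), 5% envelope noise.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: soft-tissue artifact and sensor-fusion drift,
EMG crosstalk between muscles, inter-phase movement overlap (real reaching
blends into transport), within-phase plateaus of real muscle activity, and
trunk strategies correlated with arm kinematics. The generator's events are
cleanly identifiable by design; real recordings may violate the event
definitions outright (e.g. no discernible elbow re-extension), which the
segmenter reports as named errors rather than guessing.

## Numerical choices and degenerate inputs

* Phase durations snap to the kinematic grid so true boundaries sit on
  samples; the EMG rate must be an integer multiple of the kinematic rate.
* Window convention `[start, end)` (final phase closed) shared between
  ground truth and metrics; a window containing no samples is an error.
* Ties in extremum searches resolve to the earliest sample, with a 1e-12
  relative tolerance so exactly symmetric profiles don't tie-break on
  floating-point rounding.
* Degenerate guards raise errors with named causes: SVIC reference ≈ 0,
  scapular ROM < 0.5° in SHR, zero peak speed in smoothness, missing
  segmentation events (named boundary), fewer than 3 subjects for paired
  inference, fewer than 2 subjects or measurements for ICC.
* Constant paired differences route to the nonparametric branch with a
  zero-variance flag and p = 1.

## Problem sizes used in validation

The shipped validation runs use compact problem sizes chosen to exercise
every code path at full fidelity: one noise-free trial for exact-recovery
checks; 200 seeded noisy trials for boundary-recovery coverage; 1000 random
small matrices for the ICC oracle; 2000 simulated null cohorts (n = 18) for
type-I calibration; and a 12-subject cohort (120 full trials) for
end-to-end recovery of an injected −8 %SVIC EMG effect. A complete
18-subject, 5-trial, two-session study runs through `run_study()` in a few
minutes on one core.

## Known limitations

* The smoothness score's absolute scale is normalization-dependent; only
  comparisons computed with the same variant are meaningful.
* The ICC confidence interval relies on the usual normal-theory F
  approximation; with n ≈ 10–20 subjects it is wide and can extend far
  below zero.
* The segmentation operationalizations (sustain windows, 5°/s initiation
  threshold, smoothing cutoffs) are conventions; all are surfaced in
  `segmentation_params()` and logged by `run_study()`.
* One- vs two-tailed design power changes the required sample size
  materially (17 vs 22 at d ≈ 0.64); the tails are an explicit argument,
  never inferred.
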