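---
title: "Heading from optic flow: stimuli, the MT–MST subspace model, and simulated cell loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heading from optic flow: stimuli, the MT-MST subspace model, and simulated cell loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headingflow)
```

## What this package models

An observer translating through a rigid world sees a radial pattern of
image motion — optic flow — whose focus of expansion (FOE) marks the
heading. `headingflow` implements, end to end, a simulation study of how
heading perception from such flow degrades with age:

1. **Stimuli**: random-dot clouds inside a camera frustum (23 mm–20 m),
   translated at 1 m/s along one of seven azimuths (−15°…+15° in 5° steps),
   projected at 60 Hz, optionally with per-frame direction noise
   (coherence 0.15) or off-axis stereoscopic projection.
2. **Model**: a two-layer MT→MST population network with fixed,
   analytically derived least-squares weights that decodes heading from the
   flow field.
3. **Aging**: random deactivation of MST-layer units (1–10%), the
   cell-loss account of the behavioral decline, quantified as a heading
   error curve.
4. **Baselines**: Monte-Carlo bounds on the worst plausible behavioral
   error under three response strategies.
5. **Behavioral analysis**: regression fits, accuracy (mean absolute
   error), precision (per-heading SD/SEM), Mann–Whitney group comparisons
   with Benjamini–Hochberg correction — exercised on synthetic cohorts
   with a known generative model.

All angles are degrees, lengths meters, times milliseconds.

## Stimulus generation

`build_frustum()` derives the display half-angles from the headset's 60°
diagonal field of view and 5:4 panel aspect via planar-screen
trigonometry (horizontal half-angle ≈ 24.3°). Dots are uniform in screen
position; depth is drawn uniformly in Z by default. The sources describe
dot placement only as "random within the frustum", so the depth law is a
modeling choice: we fix it with the one quantitative calibration
available, the reported mean dot speed of ≈2.7°/s at 1 m/s. Uniform
inverse depth concentrates dots at the near plane (mean inverse depth
≈21.7 m⁻¹) and predicts mean speeds an order of magnitude too fast;
uniform Z (mean inverse depth ≈0.34 m⁻¹) lands at a few degrees per
second, the right order. `depth_distribution` keeps `"uniform_invz"` and
`"uniform_volume"` available. The mean speed is treated as a calibration
observable, not a constraint: the test suite only asserts the order of
magnitude.

`simulate_trial()` advects dots at the frame rate, evaluates flow at each
frame's temporal midpoint, and respawns dots that exit the frustum so the
dot count stays constant. Motion coherence follows the classic
random-dot-kinematogram construction: each frame, each dot independently
becomes a noise dot with probability 1 − coherence; noise dots get a
uniformly random direction with magnitude resampled from the signal dots,
so only direction information is destroyed. Coherence 0.15 implies a
signal-to-noise ratio 0.15/0.85 ≈ 0.177. Stereo pairs use the
parallel-axis asymmetric-frustum (off-axis) projection: parallel view
vectors, purely horizontal disparity, zero disparity on the zero-parallax
plane and crossed (negative) disparity nearer than it. Eye separation is
not stated in the sources; the default is 0.063 m, configurable.

## The two-layer heading network

**MT layer.** 300 receptive-field locations uniform within 50°
eccentricity, four units per location with preferred directions 0°, 90°,
180°, 270° and rectified-cosine direction tuning scaled linearly by
speed. Linear speed coding is our choice (speed tuning is unspecified in
the sources); it makes the local flow vector exactly recoverable from a
quadruple (`u = r0 − r180`, `v = r90 − r270`), so the MST stage operates
on a faithful flow measurement.

**MST layer.** Candidate headings form a grid (default 1° spacing,
azimuth ±16°, elevation ±5°). For each candidate `T`, the image flow
fields that `T` can generate — over any scene depths, rotation components
included — span a linear subspace of the measurement space over a neuron's
30 sampled receptive-field locations. Each of 20 neuron pairs per
population carries a weight vector drawn from the orthogonal complement
of that subspace (computed by QR), so the pair's drive `w·v` vanishes
exactly when the stimulus heading equals `T` regardless of the depth
layout: the subspace least-squares criterion with fixed, untrained
weights. With dots placed at receptive-field locations the residual at
the true heading is numerically zero (<1e−8, tested for 20 random
heading/depth draws), and on small instances the summed squared drive
equals a QR-based projection residual computed independently, with
matching argmins.

**Activation and readout.** Each pair member applies a saturating
logistic activation to ±drive with a positive bias, so the *summed pair
activity is maximal at zero drive*: the population encoding the true
heading is the most active. Heading is read out as the activity-weighted
centroid of the 3×3 grid neighborhood around the most active population
(`"argmax"` available). Two numerical choices matter here:

* *Receptive-field sampling.* Each RF takes the flow of the nearest dot
  within 1° (silent otherwise, which reproduces the sparse-input regime
  of 2-dot displays), and the sampled flow is averaged over the frames of
  the trial before encoding. Both choices control the positional mismatch
  between a dot and the RF center at which the weights were built; with a
  5° radius and single frames that mismatch alone produced decode errors
  of several degrees. Under pure translation the flow direction at a
  fixed image point is stationary, so temporal averaging stays inside the
  heading subspace.
* *Grid margin.* The grid extends 1° beyond the largest tested heading so
  the centroid neighborhood is complete at ±15°.

**The sigmoid operating point.** The logistic bias is 2; the gain is
calibrated at build time so that the median pair drive at the task's
extreme heading offset (15°, under the reference 100-dot integrated
stimulus) maps to 1. This anchors the breadth of the population heading
tuning to the tested heading range — broad tuning being the hallmark of
MST-like heading codes — and is fixed before any lesion experiment is
run. The absolute scale of the lesion-error curve below depends on this
single free parameter; the sources do not pin it down.

## Simulated cell loss

`lesion()` silences each MST unit independently with probability `p`;
the partner of a silenced unit stays active, which breaks the pair's
symmetric activation and perturbs the population activity landscape.
`lesion_error_curve()` sweeps `p`, drawing fresh dot clouds and lesion
masks per heading and seed, with masks coupled across `p` by common
random numbers (a unit dead at `p` stays dead at every larger `p`), so
the monotone trend is not obscured by Monte-Carlo wiggle.

Two structural facts about this mechanism are worth stating plainly,
because they bound what the simulation can reproduce:

* A pure least-squares argmin readout is *lesion-immune* on noise-free
  flow: the true-heading population's residual is zero with or without
  deactivation. Lesion-induced errors require the saturating activation,
  where each lost unit removes a finite chunk of population activity.
* Unit loss is discrete. At p = 0.02 roughly 45% of 40-unit populations
  lose no unit at all; within that unlesioned subset the noise-free
  activity landscape still peaks at the true heading, so the mean decoded
  error stays well below a degree *for any gain* (a sweep over a 40-fold
  gain range moves it only from 0.52° to 0.55°). Error levels of several
  degrees at 2% deactivation would require an additional continuous
  response-noise source, which the sources do not describe. The package
  therefore reports the curve its stated mechanism actually produces
  (≈0.5° at p = 0.02, ≈2° at p = 0.10 under the default calibration,
  monotone in p and veridical at p = 0), and the acceptance suite marks
  the corresponding magnitude check as failed rather than inflating the
  mechanism to match.

`match_cell_loss()` interpolates the summarized curve to report which
deactivation range corresponds to a given behavioral error level.

## Chance-performance baselines

Three response strategies bound the worst plausible behavioral error on
the seven-heading design: always answering straight ahead (closed form
`mean(|h|)` = 60/7 ≈ 8.57°), answering uniformly on the ruler `(−R, R)`
(closed form `(R² + mean(h²))/(2R)`; the ruler half-range is not printed
in the sources — the reported 14° implies R ≈ 24°, the default), and
answering from a σ = 2° Gaussian centered straight ahead (folded-normal
closed form, ≈8.80° on this design). Responses are continuous by default
so the closed forms are exact oracles; `discrete_ruler = TRUE` snaps to
the 1°-spaced ruler. Note that for *any* response distribution centered
on straight-ahead, `E|X − h| ≥ |h|`, so no centered strategy can beat
8.57° on this design; a reported value below that bound for the Gaussian
strategy must rest on a different error definition, and the package
reports the analytic value instead.

## Synthetic cohorts and what a green test establishes

`generate_cohort()` fills the 4 × 4 × 7 × 5 factorial scaffold with
responses `b + a·h + ε`, `ε ~ N(0, (σ₀ + σ₁|h|)·duration
factor·density factor)`, clipped to the ±24° ruler, with 10% CV
subject-level variation in `a` and `b`. Defaults (control: a = 0.55,
σ₀ = 2°; test: a = 0.30, σ₀ = 4°; error factors decreasing with duration
and dot count) reproduce the three qualitative signatures the analysis
stack must detect — compressive slopes, eccentricity-growing dispersion,
group/condition offsets — and the static-target control task is the same
machinery with slope 1 and σ₀ chosen so the folded-normal mean error is
1.7°. The generator makes no claim of subject-level realism: no learning,
lapses, reaction times, or verbal-report error. A green
parameter-recovery test establishes that the analysis recovers the
generative parameters at the design's n, not that real cohorts look like
this.

## Known limitations

* The lesion-curve *scale* is governed by the sigmoid operating point and
  the discreteness of unit loss, as analyzed above; only its shape
  properties (veridical at p = 0, monotone growth) are
  calibration-independent.
* The behavioral numbers of the motivating study (group slopes and error
  levels) depend on unavailable human data; synthetic cohorts emulate
  structure, not values.
* Rotation-contaminated flow (pursuit), vestibular cues, and
  tuning-broadening or noise-increase aging models are out of scope; only
  cell loss is implemented.
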