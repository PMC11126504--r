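---
title: "Methods: trajectory metrics, circular tests and panorama matching for ant learning walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory metrics, circular tests and panorama matching for ant learning walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antwalks)
```

`antwalks` analyses the first outdoor walks of desert ants: the single
looping *learning walk* a naive worker performs around its nest, the short
out-and-back *excavation trips* that follow, and the *displacement tests* in
which an ant is released a few metres from home and its final heading
recorded. This vignette documents the models and procedures behind each
module, the parameters that matter and why their defaults were chosen, what
the synthetic-data generators do and do not emulate, and the numerical
choices a careful user should know about.

## Coordinate and angle conventions

Trajectories live in nest-centred map coordinates: the nest entrance is the
origin, +x is East, +y is North, units are centimetres, and time advances at
a constant frame rate (25 frames/s by default, the usual tracking-video
rate). On ingest from pixel tables (`read_tracking_table()`) the image
y-axis, which grows downward, is flipped; the calibration (cm per pixel,
nest pixel) comes from the caller because recording geometries vary and the
mapping cannot be inferred from the table alone.

Body orientation — the direction of the thorax-to-head vector — is measured
in degrees counterclockwise from North and *unwrapped* over time, so a full
on-the-spot rotation spans 360 continuously. Final headings on displacement
tests use the complementary convention of the displacement literature:
`final_heading()` reports the angle from the release-point-to-nest bearing
to the exit orientation such that, for an ant released North of the nest, a
head pointing due South reads 0 (facing home) and a head pointing due East
reads 270. These two conventions coexist deliberately: orientation series
feed angular-velocity and scanning analyses in map coordinates, while
heading sets are nest-relative by construction and all circular tests
operate on them.

Frame gaps are rejected, not interpolated: every metric below assumes a
constant time step. Raw coordinates are not smoothed by default
(`smooth_trajectory()` exists for users who want a boxcar).

## Path metrics

All metrics are computed from thorax positions, with steps taken between
consecutive video frames (no rediscretization — the step is the natural
sampling unit of the data):

* **Convex-hull area** (cm²): shoelace area of the hull of all visited
  points; the spatial extent of exploration.
* **Maximum displacement** (cm): the farthest thorax distance from the nest.
* **Duration** (s): last minus first frame time.
* **Mean speed** (cm/s): per-frame speed averaged after excluding *stops* —
  runs of frames slower than `stop_speed_thresh` (default 0.5 cm/s)
  sustained for at least `stop_min_dur` (default 0.2 s). The source data
  define stops only qualitatively; both thresholds are explicit, reported
  parameters.
* **Orientation angular velocity** (deg/s): the mean of |Δ orientation| ×
  frame rate. The magnitude is used because ants oscillate their gaze left
  and right while walking; a signed mean would cancel to ~0.
* **Straightness**: net displacement over path length, in [0, 1].
* **Sinuosity**: \(S = 2\,[p\,((1+c)/(1-c) + b^2)]^{-1/2}\) with \(p\) the
  mean step length (cm), \(c\) the mean cosine of turning angles and \(b\)
  the coefficient of variation of step length. Note that although sinuosity
  is often described as ranging from 0 (straight) to 1 (extremely curved),
  the formula itself is not bounded by 1 — small mean step lengths push it
  above 1. The formula is implemented verbatim and the discrepancy
  documented rather than hidden by rescaling.
* **Maximum expected displacement** \(E^a_{max} = \beta/(1-\beta)\), with
  \(\beta\) the mean cosine of turning angles; flagged infinite when
  \(\beta \ge 1 - 10^{-12}\) (perfectly straight paths).

A perfectly straight path is a limit point for sinuosity (\(c \to 1\)); the
limit value 0 is returned with a `limit` flag instead of dividing by zero.

## Scanning-bout detection

A scanning bout is an on-the-spot rotation with successive stationary
head-direction fixations pointing in different directions. The detector
(`detect_scanning_bouts()`) formalizes this as intervals that
simultaneously satisfy:

1. *on the spot*: every thorax position stays within `on_spot_radius`
   (0.5 cm) of the interval's centroid, **and** the median translation
   speed — measured on positions boxcar-smoothed over `pos_smooth_window`
   (9 frames), which suppresses digitization jitter — stays below
   `max_bout_speed` (0.5 cm/s). The speed criterion matters: a slow walker
   rounding a tight loop apex can curl inside a half-centimetre ball for a
   second while turning substantially, which is locomotion, not scanning.
2. *long enough*: at least `min_bout_dur` (0.5 s).
3. *scanning*: at least two fixations — maximal runs of duration
   ≥ `fixation_min_dur` (0.08 s, two frames) whose smoothed rotation rate
   stays below `fixation_max_rot_rate` (50 deg/s) — whose mean orientations
   differ by ≥ `min_fixation_separation` (20°), with the bout's extreme
   fixation orientations spanning ≥ `min_bout_span` (60°). The span
   criterion separates deliberate wide scanning from the narrow (±15°
   or so) gaze oscillation ants show continuously while walking.

Rotation rates are estimated on an orientation series boxcar-smoothed over
`smooth_window` (5 frames): at 25 fps, independent per-frame orientation
noise of only 3° sd would otherwise masquerade as ~100 deg/s rotation and
destroy every fixation. Bouts closer than `merge_gap` (0.3 s) are merged.
Detection is deterministic, and every threshold is recorded in the output's
`params` attribute — the behaviour is defined qualitatively in the field
literature, so the quantitative defaults here were calibrated against the
package's own synthetic walks (where ground truth is known) and are
reported rather than hidden.

## Circular statistics

Heading sets hold angles in degrees in [0, 360), nest direction 0. The test
battery implemented:

* **Rayleigh test** of uniformity: \(Z = n\bar R^2\) with the standard
  series approximation for the p-value (accurate for the n ≈ 20 samples it
  is used on; its type-I error is verified by simulation in the test
  suite).
* **V test** toward a known target: \(V = \bar R\cos(\bar\mu -
  \theta_0)\), \(u = V\sqrt{2n}\), one-sided normal approximation.
* **Mean-direction 95% CI** by the circular-dispersion method
  (\(\hat\delta = (1-\hat\rho_2)/(2\bar R^2)\), half-width
  \(\arcsin(q\sqrt{\hat\delta/n})\)). The quantile \(q\) is Student-t on
  n−1 df rather than normal — a small-sample correction for estimating the
  dispersion from the data; with the normal quantile the interval
  undercovers by about 2 percentage points at n = 20. For weakly
  concentrated samples (\(\bar R <\) 0.45, where the arcsine saturates) a
  seeded percentile bootstrap (2000 resamples) takes over; the method used
  is recorded in the result. The "does the interval contain the nest
  direction" check is wrap-aware, so an interval like (335.7°, 5.0°)
  contains 0°.
* **Watson–Williams test** for equal mean directions of two samples, with
  the usual \(1 + 3/(8\hat\kappa)\) correction; flagged when the pooled
  mean resultant length is below 0.45 (the test's assumptions strain).
* **Single-sample von Mises likelihood-ratio test**: the mean is estimated
  freely and re-fit constrained to the target direction (concentration
  re-estimated under the constraint, truncated at 0 when the constrained
  resultant component is negative); \(\chi^2 = 2(\ell_{free} -
  \ell_{constrained})\) on 1 df. The description of this test in the field
  is ambiguous between a uniformity test and a mean-direction test; given
  that it is reported alongside a concentration estimate, the
  mean-direction reading is implemented. Concentration estimates solve
  \(A_1(\kappa) = \bar R\) exactly (the classical piecewise approximation
  seeds a `uniroot` refinement), so likelihoods match numeric
  profile-likelihood evaluation to high precision.

Where tests require minimum sample sizes (n ≥ 2 for Rayleigh/V, n ≥ 5 for
CI, Watson–Williams, LRT) smaller inputs raise errors or are flagged and
skipped by the pipeline rather than silently computed.

## Panoramas and the rotational image difference function

Panoramas are equirectangular grayscale grids (rows = elevation, columns =
azimuth, intensities in [0, 1]; RGB input is converted with luminance
weights 0.299/0.587/0.114 and, by default, rescaled per image to span
[0, 1] — an explicit choice, since camera scales are otherwise arbitrary).
`rotidf()` rotates the test panorama through every whole-degree shift and
records the root-mean-square pixel difference to the reference (RMS is the
convention of the view-matching literature; mean absolute difference is
available). Summaries: minimum, its argument, median, mean, and **depth** =
mean − minimum, the usability of the minimum as a homing signal. Ties on
the minimum return the smallest shift and set a flag; panoramas of
different shapes are rejected rather than resampled implicitly
(`downsample()` exists for explicit block-mean reduction).

In `run_rotidf_analysis()` the reference (nest) panorama is first rolled so
its first column faces the same world bearing as each test panorama's (the
nest-ward direction, for panoramas from the synthetic experiment); the
best-matching rotation then reads directly as a deviation from the homing
direction, mirroring how nest-aligned comparisons are presented in the
displacement literature. Because the original field images are not
shipped, the absolute discrepancy scales reported in print elsewhere are
not reproducible here; the identities (self-match at zero, shift
consistency, depth = mean − min, symmetry of the minimum) and the
qualitative structure (best direction pointing home, depth not growing
with distance) are what the tests pin down.

## Group statistics

The condition comparisons exploit the complete repeated-measures design —
every ant performs the learning walk and all three excavation trips, and
visits all four displacement sites:

* **A-priori contrasts**: LW vs the mean of E1–E3; E1 vs the mean of
  E2–E3; E2 vs E3 (orthogonal, zero-sum rows). Rather than a generalized
  linear mixed model with a random ant intercept, each contrast is applied
  *within* each ant and the resulting per-ant contrast values are tested
  against zero with a one-sample t test (F = t² is reported alongside).
  For a complete design this is an exact repeated-measures test with
  transparent degrees of freedom (ants − 1) — a deliberate methodological
  substitution for REML machinery, which means reported df differ from
  mixed-model output.
* **Bounded metrics**: straightness (and sinuosity when treated as
  bounded) lie in (0, 1); a binomial likelihood is ill-defined for such
  non-count data, so bounded metrics are logit-transformed (clamped to
  [1e-6, 1−1e-6]) before contrasting, and the transform is flagged in the
  output.
* **Welch's ANOVA** (`stats::oneway.test`) for heterogeneous variances,
  **Welch t tests** (`stats::t.test`), and **Tukey-adjusted pairwise
  comparisons** — paired within ants, with the studentized-range
  adjustment \(q = |t|\sqrt{2}\) on (ants − 1) df, as standard
  post-hoc machinery does for a family of six pairs.
* **Bootstrap mean differences**: seeded percentile intervals (≥ 1000
  resamples) for display-style effect summaries.

Alpha levels follow the study design: 0.01 for the multi-metric walk
comparisons (many dependent variables from the same trajectories), 0.05
for circular tests; both sit in `run_config()`.

## The synthetic experiment

`gen_experiment()` builds the complete input tree with known ground truth,
so the entire pipeline can be exercised and validated without field data.
What it emulates, and the defaults chosen once as the study conditions:

* **Learning walks**: a single smooth loop leaving and re-entering the
  nest (start and end within 1 cm), bearing advancing monotonically around
  the nest with low-frequency shape jitter, peak excursion `loop_radius`
  = 6.5 cm over an angular span of 120°, giving hull areas around 20 cm²
  and durations near 20 s — the reported scale of naive excavator walks
  (areas ~20 cm², excursions well under 30 cm, durations under a minute).
  Travel speed 1.2 cm/s with smooth fluctuation (cv 0.2); 1–3 scanning
  bouts (stationary thorax; three fixations 45° apart, 0.4 s each,
  rotations at 150 deg/s) spliced at spread positions; the head oscillates
  ±15° about the travel direction at 0.8 Hz.
* **Excavation trips**: straight out-and-back runs at 2.5 cm/s (faster
  than learning walks, as observed), deposit distance uniform in 5–10 cm,
  no stops and no scanning; gaze oscillation is faster and wider (1.5 Hz,
  ±25°), reflecting the faster pace.
* **Displacement headings**: von Mises draws (Best–Fisher sampler) with
  κ = 3 about the nest direction for the 2 m conditions and κ = 0
  (uniform) for the 4 m conditions — the oriented-at-2-m,
  lost-at-4-m pattern.
* **Panoramas**: a parametric semi-arid scene — immediate surroundings
  cleared (as in the field protocol), bushes at 8–25 m, distant trees at
  40–90 m, and a world-fixed azimuthal sky brightness gradient — rendered
  as blocks of angular width \(2\arctan(w/2d)\) and height
  \(\arctan(h/d)\) with occlusion. Landmark placement is irregular on
  purpose: periodic placements create aliased rotIDF minima that no real
  scene has.

Per-ant lognormal multipliers (sd 0.15) on size and speed induce the
between-ant variability that the repeated-measures tests absorb;
digitization noise defaults to 0.02 cm positional and 1° orientational
jitter in the bundled experiment.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: gait dynamics and body-axis wobble
beyond a sinusoid; pauses other than commanded scanning bouts; sky
polarization or 3-D vegetation; pixel-level camera noise in panoramas; and
any calibration of maximum displacement differences between walk types
(learning-walk excursions ~6.5 cm and deposit distances 5–10 cm are
similar by design, but their near-equality is not a calibrated null).
Detector thresholds validated on these walks are a reasonable, reported
starting point for real recordings, not a guarantee.

## Numerical choices and degenerate inputs

* Turning angles are wrapped to (−π, π]; orientation unwrapping accumulates
  shortest arcs.
* Zero-length paths make straightness undefined (error); zero body axes
  (head = thorax) are rejected at construction.
* Contrast tests guard the zero-variance case against floating-point
  residue of the coefficient arithmetic (1 − 3·(1/3) ≠ 0 in binary) with a
  scale-relative epsilon.
* `a1inv` refines the piecewise κ approximation by root-finding to 1e-12;
  Bessel functions are evaluated exponentially scaled to avoid overflow at
  large κ.
* Rayleigh p-values are clamped to [0, 1] (the series approximation can
  stray marginally outside).
* All stochastic procedures (generators, bootstrap) take explicit integer
  seeds; identical seeds give byte-identical outputs, which the tests
  assert.

## Problem sizes used in validation

The shipped test-suite and acceptance script validate at sizes chosen to
estimate each property tightly: 100 random fixtures for formula oracles;
5000 uniform samples (n = 20) for test calibration; 2000 simulations for
CI coverage; 200 jittered walks for scanning-bout recovery; 100–200
replicate synthetic studies (20 ants × 4 walks each) for the end-to-end
contrast pattern; 500 replicates (n = 100) for κ recovery.

## Known limitations

* Sinuosity's printed range (0–1) and its formula disagree; the formula
  wins here.
* The scanning-bout definition is operational; different thresholds yield
  different counts on real data, which is why every threshold is surfaced
  and recorded.
* The mean-direction CI is approximate at small n even with the t
  correction (coverage ~95 ± 1% at n = 20, κ = 4, by simulation).
* Absolute rotIDF scales depend on image normalization; only relative
  structure is comparable across sources.
* Reported degrees of freedom follow the exact within-ant scheme and will
  not match mixed-model printouts.
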