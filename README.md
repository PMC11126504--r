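# antwalks

Analysis of the first outdoor walks of desert ants: the looping **learning
walk** a naive worker performs around its nest, the straight out-and-back
**excavation trips** that follow, and **displacement tests** probing what
the ant learned from that single walk. The package is written for
researchers in insect navigation and movement ecology who digitize
head/thorax positions from overhead video and want the full analysis chain
— path metrics, scanning-bout detection, circular statistics, panoramic
image matching and repeated-measures group comparisons — as tested,
scriptable functions, together with synthetic-data generators that make the
whole pipeline runnable and verifiable without any field data.

## What it computes

**Per-walk path metrics** (thorax-based, steps between consecutive frames):
convex-hull area, maximum displacement from the nest, duration,
stop-excluded mean speed, mean orientation angular velocity of the
thorax→head axis, straightness (net displacement / path length),
sinuosity

S = 2 [ p ( (1+c)/(1−c) + b² ) ]^−1/2

with p the mean step length, c the mean cosine of turning angles, b the
coefficient of variation of step length; and the maximum expected
displacement E^a_max = β/(1−β), β the mean cosine of turning angles.

**Scanning bouts**: on-the-spot rotations with ≥ 2 stationary
head-direction fixations pointing ≥ 20° apart and spanning ≥ 60°, detected
deterministically with every threshold reported.

**Circular statistics** on final headings (nest direction = 0°): mean
vector (μ, R̄), 24-wedge histograms, Rayleigh test (Z = nR̄²), V test
(u = R̄ cos(μ−θ₀)·√(2n)), dispersion-based 95% CI of μ with wrap-aware
nest-inclusion, Watson–Williams two-sample test, and a single-sample von
Mises likelihood-ratio test of the nest direction (χ² on 1 df, with the
ML concentration κ̂ solving A₁(κ) = R̄ exactly).

**Panorama matching**: rotational image difference functions (rotIDF)
between equirectangular panoramas — RMS pixel difference at each 1°
rotation — with minimum, best-matching bearing and depth (mean − minimum).

**Group statistics** for the complete repeated-measures design: a-priori
contrasts (learning walk vs all excavation trips; trip 1 vs 2–3; trip 2
vs 3) as exact within-ant tests, Welch's ANOVA and t tests, Tukey-adjusted
pairwise comparisons, and seeded bootstrap mean-difference intervals.

**Synthetic data**: seeded generators for learning walks, excavation
trips, von Mises heading sets and parametric panoramic scenes, all with
ground truth, plus `gen_experiment()` which writes a complete study bundle
(20 ants × 4 walks, 4 heading conditions, 5 panoramas).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data:

```sh
Rscript analysis/01_simulate.R --seed 1     # writes results/synthetic_study/
Rscript analysis/02_walk_analysis.R         # metrics + contrasts
Rscript analysis/03_displacement.R          # circular test battery
Rscript analysis/04_rotidf.R                # panorama matching
```

which prints, for seed 1:

```
metrics separating the learning walk from the excavation trips (contrast 1, alpha = 0.01):
   convex_hull_area, max_displacement, duration, mean_speed, mean_orient_angular_velocity, straightness, sinuosity, emax
contrast 2-3 rejections: 0 of 16
learning walks: area 22.8 cm^2, duration 21.1 s, 1-3 scan bouts

2mE: n=20 mu=   5.6 deg rbar=0.78 Rayleigh p=7.175e-07 -> oriented (V p=4.32e-07, CI contains 0)
2mN: n=20 mu= 358.9 deg rbar=0.84 Rayleigh p=2.452e-07 -> oriented (V p=5.3e-08, CI contains 0)
4mE: n=20 mu=  78.8 deg rbar=0.09 Rayleigh p=0.8559 -> uniform not rejected (V p=0.456, CI contains 0)
4mN: n=20 mu= 150.4 deg rbar=0.28 Rayleigh p=0.2165 -> uniform not rejected (V p=0.936, CI excludes 0)

2mN: min 0.108 at   1 deg, mean 0.194, depth 0.087, best bearing 181.0 (nest at 180.0)
2mE: min 0.107 at 358 deg, mean 0.192, depth 0.085, best bearing 268.0 (nest at 270.0)
4mN: min 0.129 at   2 deg, mean 0.196, depth 0.066, best bearing 182.0 (nest at 180.0)
4mE: min 0.132 at 357 deg, mean 0.190, depth 0.058, best bearing 267.0 (nest at 270.0)
```

Reading this: the learning walk differs from the three excavation trips on
every metric (first contrast significant at α = 0.01) while the excavation
trips are mutually indistinguishable (contrasts 2–3 never reject); ants
displaced 2 m are oriented toward the nest (Rayleigh and V tests reject,
the 95% CI of the mean heading contains 0°) while at 4 m uniformity cannot
be rejected; and every test-site panorama matches the nest panorama best
within a few degrees of the true homeward bearing, with the depth of the
match shrinking with distance.

In R, the same pieces compose directly:

```r
library(antwalks)
lw <- gen_learning_walk(walk_gen_params("learning", n_scan_bouts = 2, seed = 7))
path_metrics(lw$traj)          # one row: area, duration, speed, S, Emax, bouts...
detect_scanning_bouts(lw$traj) # 2 bouts, with locations and angular spans
h <- gen_headings(20, mu = 0, kappa = 3, seed = 2, condition = "2mN")
rayleigh_test(h); v_test(h, 0)
```

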