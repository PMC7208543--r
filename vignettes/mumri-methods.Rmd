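---
title: "Motor-unit territory mapping from dynamic diffusion-weighted MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-unit territory mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mumri)
```

## The measurement

A motor unit is one motor neuron and all muscle fibres it innervates; its
territory is the cross-sectional region those fibres occupy. When a unit
contracts during a diffusion-weighted acquisition, the motion of its fibres
dephases the signal and the territory appears as a localized signal void.
Driving the nerve with a programmable stimulator while imaging at one frame
per second turns this into a recruitment experiment:

* a **coarse-grain scan** ramps the current up (0.1–0.5 mA per step, one
  dynamic per level) until the stimulated muscle shows clear contrast. The
  ROI intensity–current profile is flat until the first units recruit, then
  declines; the knee of that profile (the *inflection point*) marks the
  current at which activity first appears.
* a **fine-grain scan** starts five coarse steps above the inflection
  (`I_MAX`) and descends in 0.01 mA steps, five dynamics per level. Near its
  activation threshold a unit fires probabilistically in an all-or-none
  fashion, so frames at the same current alternate between void and no-void
  over a spatially consistent region — *motor unit alternation*. Alternation
  is the handle by which single units are isolated.

Per unit, frames are grouped into fired and not-fired, averaged and
subtracted; the difference map is normalised to its maximum and thresholded
at 0.5 of the peak to give a binary territory, which is then quantified
(CSA, Feret diameters, shape class, split-component gap) together with its
recruitment behaviour (activation threshold, alternation current range).

## The phantom model

Scanner data cannot carry ground truth, so the package ships a simulator in
which every stage has a recoverable answer. Its components:

* **Territories.** Five canonical outline classes are generated
  analytically and pixelated by voxel-centre membership: ellipse, circular,
  crescent (annular sector), spider (core with radiating arms) and split
  (two disjoint discs at a stated border-to-border gap).
* **Firing.** Each unit draws fire/no-fire per dynamic from a logistic
  probability `plogis((I - threshold) / width)` — exactly 0.5 at the
  threshold, monotone in the current. The published description of
  probabilistic all-or-none firing names no functional form; the logistic is
  the standard psychometric choice and its `width` maps monotonically onto
  the observed alternation range. The default width of 0.05 mA yields
  alternation ranges around 0.3–0.4 mA, the order reported in vivo; widths
  are varied in the recovery studies.
* **Voids.** A fired unit multiplies the signal over its whole territory by
  `void_fraction` (default 0.4). The published work does not report the
  void depth numerically; 0.4 is a free simulator parameter chosen to give
  the strong contrast visible in published difference maps. Mechanical
  coupling of adjacent fibres — the reason a void can over-estimate the
  territory — is modelled as a binary dilation of the void by
  `coupling_dilation_vox` voxels (default 0 for recovery tests, 1 to
  emulate the over-estimation caveat).
* **Noise.** Magnitude-MRI Rician noise,
  `sqrt((S + sigma N1)^2 + (sigma N2)^2)`, with `sigma` a fraction
  (default 0.03) of the mean muscle baseline.
* **Schedules.** `plan_coarse_schedule()` and `plan_fine_schedule()`
  reproduce the acquisition grammar: an ascending ramp with one dynamic per
  level, and a descending staircase with 0.01 mA steps repeated 5 times per
  level (216 levels × 5 = 1080 dynamics in the full-scale protocol).

What the phantom does *not* emulate: diffusion/IVIM signal physics, EPI
distortion, subject motion, partial-volume fading at territory borders, and
interdigitation of many weakly-contributing units. Passing recovery tests
therefore shows that the analysis chain is correct and well-calibrated for
all-or-none, spatially uniform voids under Rician noise — not that it is
robust to every artefact of in-vivo data.

## Analysis pipeline and its parameters

**Inflection detection.** The ROI profile is fit with a continuous
two-segment model: a constant baseline followed by a descending line,
searched exhaustively over measured breakpoint levels (each candidate has a
closed-form least-squares solution). The first segment is constrained flat
because below the first recruitment the ROI intensity has no current
dependence; an unconstrained first segment systematically anticipates the
knee of an accelerating decline by a level or two. A breakpoint is accepted
only if the fitted second-segment decline exceeds `margin` (default 3)
times the first-segment residual SD, which makes the decision invariant to
affine intensity rescaling; otherwise "no inflection" is reported. The
published work names the inflection concept but not its algorithm; this fit
is this package's choice.

**Candidate voxels.** Within the analysis window a voxel is a candidate
when an exact 1-D two-means split of its trace separates two clusters by at
least `separation_min` (default 5) pooled within-cluster SDs, with a
relative drop of at least `min_drop` (default 0.15, comfortably above the
~8% apparent drop that pure Rician noise produces at sigma 0.03), and both
states recur on at least `min_events` (default 3) dynamics.

**Grouping frames.** The published analysis grouped frames manually; here
the mean seed-region trace is two-means partitioned and the lower cluster is
"fired" — the automation of that manual step. Degenerate splits (below the
same separation/drop criteria) signal "no alternation".

**Co-firing clustering.** Candidate voxels are joined when the squared
Pearson correlation of their binary firing vectors reaches `cofire_r2`
(default 0.6 — between the reported same-unit ~0.87 and different-unit
~0.45 observations); connected groups of that relation are putative units;
groups below `min_unit_voxels` (default 3) are dropped.

**Difference maps over the alternation zone.** Each unit's difference map
is averaged only over the dynamics of its own alternation zone (its
mixed-outcome levels). Within that zone fired and not-fired frames sample
the same currents, so any other unit is in an essentially constant state
and cancels in the subtraction; averaged over the whole staircase, every
other unit's firing co-varies with the current and bleeds into the map
(in three-unit simulations this merged territories, Dice ~0.5–0.65; the
zone-restricted maps recover Dice 1.0). When the zone holds fewer than two
frames of either kind the whole window is used.

**Thresholding.** Negative map values are clipped, the map normalised to
its maximum, voxels at or above `threshold_fraction` (default 0.5, the
published operating point) retained, and components smaller than
`min_unit_voxels` removed. `threshold_sweep()` reports CSA/Feret across
fractions for threshold-choice QC.

**Alternation statistics.** The activation threshold is the lowest current
level with at least one fired repeat. The alternation range is the current
span of the levels with mixed outcomes (zero when no level is mixed); a
unit firing at every measured level is flagged right-censored.

## Morphometry

Geometry is computed on the union-of-squares polygon of the territory —
voxel corners, not centres — so a single voxel measures its physical size
(minimum Feret 1.5 mm, not 0). The maximum Feret is the convex-hull
diameter and the minimum Feret the smallest width across any hull edge
(rotating calipers); for split units the calipers enclose all components
jointly, reading the bracketed definition "the distance between two
parallel planes restricting the object" as applying to the whole object.
Components are labelled with 8-connectivity. The split-component gap is the
minimum distance between component boundary polygons, computed
segment-to-segment.

Shape classification is a rule cascade: split when ≥ 2 components of at
least `min_component_voxels`; otherwise solidity (area / hull area) below
0.5 is spider, 0.5–0.75 is crescent; compact shapes are circular below
aspect ratio 1.3 and elliptical above. The published classification was
visual; these cutoffs are package-defined and configurable. Two values
deserve comment. The spider/crescent boundary sits at 0.5 because a half
annulus — the canonical crescent — has solidity `1 - (r/R)^2 ≈ 0.5–0.7`
(its hull is the half disc), while core-and-arms geometries fall below
~0.45. The crescent/compact boundary sits at 0.75 rather than a more
intuitive 0.85 because pixelated discs at 1.5 mm resolution lose hull area
to corner-cutting: a radius-3-voxel disc has corner-polygon solidity
≈ 0.78. Both boundaries were set from these geometric facts, verified on
the canonical fixtures.

## Observer-agreement statistics

`agreement()` implements the intraclass correlation for absolute agreement
under the two-way model from the ANOVA mean squares,

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},$$

with single measures as the default (the published family, "two-way mixed
with absolute agreement", does not say single vs average; single is the
conservative choice and `average_measures = TRUE` switches). Bland–Altman
bias is the mean paired difference and the coefficient of repeatability is
1.96 times the SD of the paired differences (no formula is published; this
is the standard definition). Normality uses Shapiro–Wilk, muscle
comparisons a one-way ANOVA, age-group comparisons an unpaired equal-
variance t-test with the age dichotomy at 40 years (configurable), and
correlations are Pearson — all via the base R implementations.

## Numerical choices and degenerate inputs

* Two-means splits are exact (sorted scan minimising within-class sum of
  squares), not iterative k-means; a perfectly two-valued trace yields an
  infinite separation statistic, handled explicitly.
* Width 0 in the firing model degenerates to a step function with
  probability 0.5 at the threshold by convention.
* Empty candidate sets, all-zero difference maps, single-component "gaps"
  and constant statistical inputs all signal typed conditions
  (`mumri_no_activity`, `mumri_no_alternation`, `mumri_undefined_warning`)
  rather than returning silent zeros.
* Seeded runs are bit-reproducible: all randomness in a simulation derives
  from the single `seed` argument, and pipeline outputs embed the seed and
  a configuration hash.

## Problem sizes in the shipped studies

The validation studies run at desk scale: 32–48 voxel grids, 30–120
staircase levels, 50-phantom recovery batches, 100-simulation width sweeps,
and a three-unit end-to-end demo — large enough for the binomial error of
the rate-style checks (≥ 90%, ≥ 95%) to be meaningful, small enough that
the whole battery completes in a few minutes. Full-scale protocols
(64 × 64 × 1080 dynamics) run through the same code paths.

## Known limitations

* Overlapping-unit resolution beyond co-firing correlation is out of scope,
  mirroring the published exclusion of overlapping regions; units whose
  alternation zones overlap heavily in both space and current may merge.
* The activation-threshold estimator ("lowest level with a fired repeat")
  estimates the lowest observed active current, which sits below the
  logistic midpoint by about `1.9 × width`; recovery is therefore assessed
  against the planted firing draws, not the latent threshold.
* The inflection estimator carries a ~1-level early bias on near-step
  profiles (a continuous piecewise-linear knee cannot sit inside a jump);
  on gradually declining recruitment curves it is unbiased.
* Morphometrics are 2-D per slice; whether split regions coalesce along the
  muscle is unanswerable from one slice by design.

## A worked demonstration

```{r demo, eval = FALSE}
report <- mumri_demo(seed = 1)
report$recovery
```

plants an ellipse, a crescent and a split unit at staggered thresholds
(10.6, 10.3, 10.0 mA), simulates a 110-level descending staircase at
Rician sigma 0.03, and recovers all three with correct shape classes,
threshold ordering, and the planted 4.3 mm split gap to within half a
voxel. The README shows the printed output.
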