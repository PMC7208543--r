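# mumri

Motor-unit territory mapping from dynamic diffusion-weighted MRI (motor
unit MRI, "MUMRI").

## What this package does

A contracting motor unit dephases the diffusion-weighted MR signal over its
territory, producing a localized signal void. Imaging a muscle slice once
per second while electrically stimulating its nerve with very fine current
steps (0.01 mA, five repeats per level, descending from just above the
recruitment current) exposes *motor unit alternation*: near its activation
threshold a unit fires probabilistically, all-or-none, so a spatially
consistent region flickers between frames at the same current. Grouping
frames into fired and not-fired, averaging and subtracting, normalising and
thresholding at half the peak turns that flicker into a binary territory
map whose size and shape can be measured.

`mumri` implements the full analysis chain plus a ground-truth phantom
simulator, for researchers developing or validating motor-unit imaging
pipelines:

* **Phantom simulator** — territories of the five canonical outline
  classes (ellipse, circular, crescent, spider, split), logistic
  probabilistic firing `p(I) = plogis((I - threshold) / width)`,
  multiplicative signal voids, mechanical-coupling halos, Rician noise,
  and the coarse-ramp / fine-staircase stimulation schedules.
* **Coarse-scan analysis** — ROI current–intensity profiles, inflection
  detection by a constant-then-descending continuous changepoint fit, and
  the fine-scan starting current `I_MAX = inflection + 5 steps`.
* **Unit extraction** — bimodality screening of voxel traces (exact 1-D
  two-means), co-firing clustering (r² ≥ 0.6 joins voxels), automated
  frame grouping, difference maps restricted to each unit's alternation
  zone, and 0.5-of-peak thresholding.
* **Morphometry** — CSA; maximum/minimum Feret diameters by rotating
  calipers on the voxel-corner polygon (`max` = hull diameter, `min` =
  smallest width across a hull edge); split-component border-to-border
  gap; five-class shape taxonomy from component count, solidity and
  aspect ratio.
* **Agreement statistics** — two-way absolute-agreement ICC
  `(MS_R - MS_E) / (MS_R + (k-1)MS_E + k/n (MS_C - MS_E))`, Bland–Altman
  bias and coefficient of repeatability (1.96 × SD of paired differences),
  Shapiro–Wilk, ANOVA / t-test comparisons and Pearson correlation over
  unit metric tables.

I/O uses NIfTI-1 for image series and masks (RNifti), CSV for stimulation
schedules, JSON for per-unit results and PNG for QC difference maps.
Tabular results are tibbles; result objects have `tidy()`/`glance()` and
`autoplot()`/`plot_*()` methods.

## Worked example

```r
library(mumri)
report <- mumri_demo(seed = 1)
report$metrics
#>   unit_id shape_class csa_mm2 feret_max_mm feret_min_mm activation_threshold_mA alternation_range_mA component_gap_mm
#> 1       1     ellipse   42.75        11.42         5.69                   10.52                 0.13               NA
#> 2       2    crescent   81.00        16.77         9.00                   10.17                 0.24               NA
#> 3       3       split   72.00        17.10         7.50                    9.86                 0.20              4.5
report$recovery[, c("planted_shape", "detected", "shape_match", "dice")]
#>   planted_shape detected shape_match dice
#> 1       ellipse     TRUE        TRUE    1
#> 2      crescent     TRUE        TRUE    1
#> 3         split     TRUE        TRUE    1
```

The demo plants three units of known shape at staggered activation
thresholds (10.6, 10.3, 10.0 mA) in a 64 × 64 phantom, simulates a
110-level descending staircase (0.01 mA steps, 5 repeats per level, Rician
noise 3% of baseline), and runs the full extraction pipeline. Here all
three territories are recovered voxel-exactly (Dice 1.0): CSA in mm², the
caliper diameters in mm, the recruitment threshold and alternation range in
mA, and the split unit's 4.5 mm recovered gap against the planted 4.3 mm —
within half a voxel at 1.5 mm resolution.

Working from files instead:

```r
report <- run_pipeline(list(
  seed = 1,
  paths = list(series = "fine_scan.nii.gz",
               mask = "muscles.nii.gz",
               schedule = "staircase.csv"),
  mask_names = list("1" = "TA", "2" = "EDL", "3" = "PL")),
  out_dir = "out")
```

writes per-unit JSON (firing vector + metrics), a metrics CSV and QC PNGs.
A thin CLI with `simulate`, `coarse`, `extract`, `metrics`, `stats` and
`demo` subcommands is installed at `inst/cli/mumri`.

## Package layout

| Area | Files |
| --- | --- |
| Domain objects & I/O | `R/dynamic-series.R`, `R/schedule.R`, `R/mask.R` |
| Phantom simulator | `R/phantom.R`, `R/geometry.R` |
| Coarse-scan analysis | `R/coarse.R` |
| Unit extraction | `R/extract.R` |
| Morphometry | `R/morphometry.R` |
| Cohort statistics | `R/stats.R` |
| Pipeline, demo, CLI | `R/pipeline.R`, `inst/cli/mumri` |
| Plots | `R/plot.R` |

The methods vignette (`vignettes/mumri-methods.Rmd`) documents the models,
parameter defaults and their rationale, numerical choices, and known
limitations.
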