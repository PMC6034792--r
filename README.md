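# octadensity

Reproducible vessel-density quantification for en-face OCT angiography
(OCT-A).

## The problem

OCT-A visualises retinal blood flow without contrast agents, and the vessel
density around the optic-nerve head is a promising marker for glaucoma
progression. Getting a *reproducible* number out of an en-face angiogram is
harder than it looks: the avascular region (optic-nerve head, foveal
avascular zone, ischemic area) has no canonical shape, so fixed disc or
ellipse templates bias the region of interest; and the instruments
themselves fluctuate by 1–3 % between repeat acquisitions of the same eye,
a floor against which any clinical contrast must be read.

`octadensity` is for image-analysis and ophthalmology researchers who need
that measurement chain end to end:

* **Shape-prior-free segmentation** of the avascular region: a per-pixel
  multi-scale feature bank (Gaussian scale space — smoothed intensity,
  gradient magnitude, Laplacian, Hessian eigenvalues, local variance, at
  physical scales spanning the expected vessel diameters 10–160 μm) feeding
  a random-forest pixel classifier trained on sparse scribble annotations.
  The forest is implemented in compiled code inside the package and is
  byte-for-byte reproducible under a seed.
* **Peripapillary annulus ROIs at physical widths** (default 640 / 920 /
  1960 μm) built from an exact Euclidean distance transform of the
  segmented core.
* **Gray-level densitometry**: mean gray value and integrated gray-level
  sum over each ROI, on the 8-bit scale.
* **Repeatability statistics**: the relative fluctuation (coefficient of
  variation) 100·sd/mean of a repeat series, with the
  truncation-at-printed-precision reporting convention, plus an
  annotation-repeatability experiment that reruns the whole pipeline per
  annotation set.
* **Cohort statistics**: the KS-normality / variance-homogeneity routed
  decision tree (Student's t vs Kruskal–Wallis; one-way F test for ≥ 3
  groups) and Hoddap–Parrish–Anderson glaucoma staging from visual-field
  mean deviation.
* **A ground-truthed synthetic phantom** (vessel trees over a configurable
  avascular region, speckle, device brightness jitter) so every stage is
  testable without clinical data.

The core statistic is the relative fluctuation

    CV% = 100 · sd(x_1 … x_n) / mean(x_1 … x_n)

of repeated density measurements `x_i` (mean gray value over an ROI), and
the stage-to-stage density decrease
`100 · (m_earlier − m_later) / m_earlier`.

## Worked example

Segment a synthetic optic-nerve phantom, measure annulus densities, and
check against ground truth:

```r
library(octadensity)
ph  <- generate_phantom(phantom_spec(seed = 7))     # 304x304 px, 3x3 mm
ann <- phantom_scribbles(ph$truth, seed = 2)        # sparse scribbles
run <- run_density_pipeline(ph$image, ann, pipeline_config(seed = 11))
run$table[, c("roi_role", "band_width_um", "n_pixels", "mean_gray")]
#>                    roi_role band_width_um n_pixels mean_gray
#> whole           whole_image            NA    92416 100.42423
#> core         avascular_core            NA    11467  25.09761
#> annulus_640         annulus           640    37746 114.71970
#> annulus_920         annulus           920    60908 113.16411
#> annulus_1960        annulus          1960    80949 111.09478

dice_coefficient(run$core$mask, ph$truth$avascular_mask)
#> [1] 0.9933
```

The whole-image mean sits near 100 gray levels; the segmented core mean
(25.1) matches the phantom's avascular intensity model, and the 640 μm
annulus is the densest band because it hugs the peripapillary vessels.
The segmentation overlaps the true avascular region with Dice 0.993.

Repeatability of a simulated 10-acquisition series with 3 % injected
device brightness jitter:

```r
series <- simulate_repeat_series(phantom_spec(seed = 7), n = 10,
                                 brightness_jitter_pct = 3, seeds = 101:110)
fluctuation_stats(sapply(series, function(i) whole_image_mean(i)$mean_gray))
#> fluctuation_stats: n = 10, mean 99.9900, sd 2.5673 (population),
#>   fluctuation 2.5676% (reported 2.56%)
```

The recovered fluctuation (~2.6 %) tracks the injected 3 % jitter up to the
small-sample bias of the CV estimator at n = 10 (see the methods vignette).
Reporting uses truncation (floor) at the stated precision — the convention
under which published repeatability rows reproduce from their own sd/mean
pairs:

```r
truncate_at_precision(100 * 2.92 / 99.82, 2)   # sd 2.92, mean 99.82
#> [1] 2.92
classify_glaucoma_stage(-13)
#> glaucoma stage 3 (advanced defect), MD = -13.00 dB
```

A command-line front end (`inst/cli/octadensity`) exposes `train`,
`segment`, `density`, `repeatability`, `cohort` and `phantom` subcommands;
see `?octa_cli`.

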