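---
title: "Methods: reproducible vessel-density quantification for en-face OCT-A"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reproducible vessel-density quantification for en-face OCT-A}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octadensity)
```

## The measurement problem

Optical coherence tomography angiography (OCT-A) images retinal blood flow
without contrast agents. A clinically useful quantity is the vessel density
around an avascular landmark — above all the optic-nerve head, whose
peripapillary capillary bed thins in glaucoma. Two obstacles stand between
the raw en-face angiogram and a reproducible number:

1. **The avascular region has no canonical shape.** The optic-nerve head can
   be circular, elliptical or completely irregular, so fitting a fixed disc
   or ellipse template biases the region of interest. This package instead
   segments the avascular region with a trainable pixel classifier and no
   shape prior.
2. **The devices themselves fluctuate.** Repeat acquisitions of the same eye
   on the same instrument differ by a few percent in overall gray level, and
   different instruments differ far more. Any clinical contrast must be read
   against this instrumental floor, so the package makes the repeatability
   statistics first-class citizens.

The pipeline is: multi-scale feature bank → random-forest pixel classifier
trained on sparse scribbles → largest avascular component, holes filled →
peripapillary annulus at physical band widths → gray-level density →
fluctuation / cohort statistics.

## Feature bank

Every pixel is described by the raw intensity plus six isotropic responses
per physical scale: Gaussian-smoothed intensity, gradient magnitude,
Laplacian, the two eigenvalues of the Hessian, and local variance in a
Gaussian window. Physical scales (μm) convert to Gaussian widths as

σ (px) = scale_um / (2 · pixel_size_um),

i.e. a scale is read as a structure *diameter*. Derivatives are finite
differences of the smoothed image and are scale-normalised (first order by
σ, second order by σ²), so a vessel of diameter *d* produces its strongest
tubular response (most negative smaller Hessian eigenvalue) at the ladder
rung nearest *d*; the test suite verifies this on an ideal ridge against a
dense-convolution finite-difference oracle.

The default scale ladder is geometric with factor 2 over an expected vessel
diameter range of 10–160 μm (capillaries to large peripapillary vessels),
with sub-pixel rungs dropped. Covering the *smallest* vessels is not a
luxury: without fine scales, the tiny interspaces between capillaries are
smoothed away and get misclassified as avascular. All convolutions use
reflective padding so ROI-edge pixels carry no zero-padding halo.

## Pixel classifier

The classifier is a random forest (bagged CART trees, Gini criterion,
per-node feature subsampling) over the feature vectors of annotated pixels
only. The forest is implemented in compiled code inside this package and
draws all of its randomness from R's RNG, so a single config seed makes
training byte-for-byte reproducible — a deliberate design point, since the
whole purpose of the tool is reproducibility auditing.

Defaults (all exposed in `pipeline_config()`): 100 trees, ⌊√F⌋ features per
split, unlimited depth, balanced per-class subsampling capped at 10,000
pixels, out-of-bag accuracy reported. Two classes only — avascular and
"everything else" (vessels *and* the inter-vessel background). The
avascular-class probability is the fraction of tree votes; the binary mask
thresholds at 0.5 with ties assigned to avascular (deterministic and
documented; a threshold of 0 means "any avascular vote", 1 means
"unanimous"). No post-hoc smoothing of the probability map is applied;
regularisation happens geometrically in the next stage.

## ROI geometry

The avascular core is the largest 8-connected component of the avascular
mask (smaller components and specks are ignored below `min_area_px`,
default 50), with interior holes filled (4-connected background components
not touching the border) so vessels crossing the disc do not perforate it.
When two components tie exactly on area, the one whose top-left-most pixel
comes first in row-major order wins — an arbitrary but documented and
deterministic tie-break.

The peripapillary annulus at band width *w* μm is the set of pixels outside
the core whose Euclidean distance to the core is ≤ *w*/pixel_size — exactly
the dilation of the core by a Euclidean disc, minus the core, clipped at the
image border. It is computed from an exact squared Euclidean distance
transform (Felzenszwalb–Huttenlocher), so the radius is used as a real
number and no structuring-element rounding occurs; unit tests check exact
agreement with an exhaustive per-pixel distance oracle. Annuli are nested
and monotone in band width by construction.

The printed sources for this design are ambiguous about whether 640 μm is a
"diameter" or a "radius" of the peripapillary band. We read it as the band
width beyond the disc margin (a fixed-distance dilation); the width is fully
configurable (`band_widths_um`, default {640, 920, 1960}) so either reading
can be produced.

## Densitometry and repeatability

Vessel density over an ROI is the arithmetic mean gray value; the integrated
gray-level sum is carried alongside since both conventions appear in
practice and their relative fluctuation is identical at fixed pixel count.
All gray values live on the 8-bit [0, 255] scale; higher-bit-depth exports
are linearly rescaled on load. This scale convention is what makes
whole-image means near 100 and density tables comparable across devices.

`fluctuation_stats()` reports the coefficient of variation,
100·sd/mean, of a repeat series. Two reporting conventions deserve note:

* **Truncation, not rounding.** Reported percentages are floored at the
  stated decimal precision (`truncate_at_precision()`). This choice is not
  cosmetic: recomputing the published device-repeatability row from its own
  printed sd/mean pairs, and the published stage-difference table from its
  printed stage means, reproduces *all eleven* printed cells under
  truncation, while rounding fails four of them. Full-precision values are
  always retained alongside.
* **Population sd by default** (divide by *n*), with a `sd_type = "sample"`
  flag. The source tables do not state which was used; only printed sd/mean
  pairs are acceptance-tested, so the default is free. A consequence worth
  knowing: the CV of an *n* = 10 series has a small-sample downward bias
  (E[s]/σ ≈ 0.92 under the population formula), visible in the phantom
  jitter-recovery experiment as recovered fluctuations a few percent below
  the injected value — a property of the estimator, not of the pipeline.

`annotation_repeatability()` runs the entire pipeline once per annotation
set and returns the fluctuation of the resulting densities; it quantifies
how much the final number depends on where the annotator scribbled.

## Cohort statistics and staging

`compare_two_groups()` encodes the decision tree used for clinical
contrasts: both groups must pass a one-sample Kolmogorov–Smirnov test
against a normal with their own moments, *and* an F-ratio test must find the
variances homogeneous, for Student's t (equal variances) to run; otherwise
the comparison falls back to Kruskal–Wallis. `compare_multi_groups()` uses
the one-way F test of equal means when all groups pass normality, else
Kruskal–Wallis. The "Fisher test" of the source material is read as this
F test of means — its stated null ("samples from the same population",
alternative "at least one mean deviates") is ANOVA's, not Fisher's exact
test on counts. Every result records its `decision_path`. The two-group
non-parametric fallback is Kruskal–Wallis on two groups (equivalent to
Mann–Whitney up to the statistic's distribution), for consistency with the
multi-group branch. KS on a zero-variance sample is an error by design: the
fitted normal is degenerate.

Glaucoma staging follows the Hoddap–Parrish–Anderson scale on visual-field
mean deviation (MD, dB): stage 0 normal field; 1: MD ≥ −6; 2: −12 ≤ MD < −6;
3: −20 < MD < −12; 4: MD ≤ −20; 5: unable to perform the test. The printed
scale leaves a gap between −12.00 and −12.01 and prints stage 4 with an
inverted inequality; we close the gap on the stage-2 side, read stage 4 as
MD ≤ −20, and test that the staging is total and monotone in MD.

## The phantom: what it emulates, and what a green test proves

Clinical OCT-A cohorts are not redistributable, so validation runs on a
synthetic phantom whose ground truth is known exactly. Its stated world
(defaults of `phantom_spec()`, chosen once):

| parameter | default | why |
|---|---|---|
| grid / FOV | 304 px / 3 mm | the common 3 × 3 mm optic-nerve scan grid |
| avascular radius | 600 μm | optic-nerve-head scale within a 3 mm field |
| vessel intensity | 180 ± 20 | bright flow signal on the 8-bit scale |
| background | 90 ± 15 | unresolved capillary bed; puts whole-image means near 100 |
| avascular | 25 ± 8 | flow void, clearly above the noise floor of 0 |
| vessels | 14 seeds, 12–80 μm diameters | branching trees spanning the resolvable range |
| speckle | multiplicative, sd 0.10 | simplest model producing realistic gray-level fluctuation |

Vessels grow as biased random walks with branching, rasterised at their
local diameter; each vessel has its own derived seed, so phantoms with
increasing vessel counts have *nested* vessel sets and the density-
monotonicity property is well-posed. Avascular shapes are a disc, a rotated
ellipse, or a disc with low-frequency radial harmonics ("irregular").
`simulate_repeat_series()` freezes the geometry (the same eye) and redraws
noise plus a multiplicative brightness factor Normal(1, jitter) per repeat —
emulating the acquisition-to-acquisition fluctuation of a device, at the
1–3 % level the repeatability literature reports.

The phantom deliberately does **not** model: physical speckle statistics,
flow projection artifacts, eye motion, vessel hemodynamics, device-specific
decorrelation algorithms, or 3D depth structure. A green phantom suite
therefore establishes that the *algorithmics* are correct (segmentation
recovers known truth, geometry matches oracles, statistics recover injected
effects, everything is deterministic under a seed) — not that any particular
clinical contrast will replicate. The published cohort tables (clinical
p-values and stage means) are inputs to the reporting functions, not
reproducible outputs; that boundary is stated in the acceptance tests
themselves.

## Numerical choices and degenerate inputs

* Scale → σ conversion requires σ ≥ 0.5 px; unresolvable scales are errors.
* The annulus band width must be at least one pixel.
* An empty ROI is an error before any division is attempted.
* `fluctuation_stats()` requires n ≥ 2 and a positive mean.
* Forest leaf ties vote avascular; mask ties at the threshold go avascular.
* `truncate_at_precision()` guards the floor with a 1e−12 relative epsilon
  so values exactly representable at the target precision (5.0 at 3
  decimals) do not land one ulp low.
* All stochastic stages derive their streams from a single config seed and
  restore the caller's RNG state afterwards.

## Known limitations

* The classifier is per-device in spirit: contrast differs enough between
  instruments that a forest trained on one device's images should be
  retrained for another (the package exposes retraining rather than
  shipping a model zoo).
* Gray-level density is a flow-signal proxy; skeleton- or area-fraction
  vessel metrics are out of scope.
* The TIFF reader covers the uncompressed grayscale baseline profile only;
  PNG is the first-class format.
* Depth-layer selection (superficial vs deep network) is metadata here; the
  package works on already-projected en-face images.
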