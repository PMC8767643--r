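---
title: "Methods: image-based phenotyping of rosette crops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based phenotyping of rosette crops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phenotyper` implements a semi-automated analysis chain for indoor
high-throughput phenotyping of rosette crops such as *Brassica napus*: it
turns per-plant, per-day top- and side-view RGB images plus top-view
near-infrared (NIR) images into growth traits, phenology calls, boundary
shape descriptors and cross-validated trait predictions. This vignette
documents the models and procedures, the parameters that matter, the
synthetic-data generator used for validation, and the numerical choices
behind each stage.

## Segmentation model

Plants are separated from background by colour-space thresholding rather
than learned segmentation: each RGB image is converted to HSV and CIELAB
(D65/2° reference white, via `grDevices::convertColor()`), named channels
are thresholded into sub-masks, and a configurable boolean rule combines
them. The default rule,

```
(hsv_s | lab_b) & hsv_v
```

catches chromatic tissue through saturation (S ≥ 0.30) or through the
CIELAB blue–yellow channel (b ≥ 15, which also captures yellow petals),
then applies a brightness floor (V ≥ 0.08) to exclude dark soil. Cleanup
removes 8-connected foreground objects under `min_object_px` (default
25 px) and fills enclosed background holes under `fill_hole_px`
(default 64 px).

Thresholds are deliberately configuration, not constants: on real
facilities they are tuned iteratively by visual inspection of segmented
images and of trait curves across the experiment, and they differ per
camera and crop. The shipped defaults were tuned once against the
synthetic generator's colour distributions (leaf tissue b ≈ 22–36,
S ≈ 0.5–0.7; background b < 4, S < 0.15) and are not claimed to transfer
to any particular real camera.

All component analysis in the package uses 8-connectivity, chosen once
and used everywhere: diagonal leaf tips and petal edges remain attached
to their plant. A small compiled flood-fill labeller provides this; the
hole-filling step labels the background with the same connectivity and
fills only components that do not touch the image border.

Pixel coordinates are 1-based with x = column and y = row, matching R's
matrix indexing; extents are inclusive (`max − min + 1`), so a single
pixel has height = width = 1.

## Holistic traits

Per plant and day the package extracts: projected leaf area (foreground
pixel count, top and side), convex hull area of the pixel centres
(shoelace formula on `chull()`), height and width of the bounding extent,
side-view plant area below the pot rim (the rim row is a per-facility
config value), and the mean Excess Green Index over plant pixels.

Two ExG variants are supported. The default follows the formula as used
by this workflow's source pipeline, ExG = 2G − R + B; the canonical
Woebbecke index 2G − R − B is available as `variant = "canonical"`
because the two differ in how blue tissue and petals are scored. The
variant is recorded on the returned value.

Derived traits: estimated biovolume `sqrt(side_area² × top_area)` (a
biomass proxy), and day-to-day deltas Δ for each trait. Deltas bridge
missing imaging days to the previous *available* day — under an
every-other-day schedule a skip-only rule would produce an empty series,
so bridging is the only useful interpretation.

Outlier filtering follows a per-trait, per-day rule: values outside
median ± 3 standard deviations are flagged. The SD is the sample (n − 1)
standard deviation; with fewer than two finite values the rule passes
everything through.

## NIR transfer and summaries

The RGB and NIR cameras share neither resolution nor field of view. The
mapping is modelled as an axis-aligned affine transform
`nir = rgb × scale + offset` (no rotation: both cameras are fixed
overhead). `transfer_mask()` resamples the RGB plant mask into the NIR
frame by nearest-neighbour lookup, treating positions outside the RGB
frame as background; an all-background result is flagged and downstream
summaries become missing. Masked NIR intensities are summarized by their
mean and 75th percentile (linear interpolation between order statistics,
`quantile()` type 7 — the percentile convention is a numerics default,
chosen once). `calibrate_registration()` grid-searches scale and offset
to maximize Jaccard overlap against a reference region when the true
registration is unknown.

## Boundary curvature (HOCS)

Leaf rolling and ruffling under water stress change boundary curvature
before they change area. The histogram-of-curvature-over-scale descriptor
summarizes the plant outline at multiple scales using the normalized area
integral invariant: at a boundary point, the fraction of a radius-r disc
(pixels with squared distance ≤ r²; off-frame pixels count as background)
lying inside the plant. The invariant is ≈ 0.5 on straight edges, < 0.5
at convex points, > 0.5 at concave points.

The descriptor evaluates the invariant at every boundary pixel (boundary
= foreground pixel with an 8-neighbour in the background, so interior
hole boundaries contribute; pixels are weighted equally rather than by
arc length) for 25 radii from 5 to 125 px in steps of 5, and bins the
values into 5 uniform bins on [0, 1] per radius. Bins are left-closed
with the last bin closed on the right, and each radius's histogram is
normalized to sum to one so scales are comparable. Disc counts are
computed for all pixels at once by FFT convolution with the disc
indicator and rounded back to exact integers, which makes the
implementation equal to a brute-force double loop exactly — a property
the test suite asserts. The descriptor is exactly invariant to
translation and to grid-exact (90°/180°/270°) rotations.

## Flower detection and phenology

Flowers are detected in the CIELAB blue–yellow (b) channel of the
top-view image, masked by the plant segmentation, so flower pixels are a
subset of plant pixels by construction. The b threshold is policy-driven
(rules keyed by plant age and treatment, first match wins) because canopy
colour drifts with age and watering; the default single rule at b ≥ 55
is calibrated to the generator (leaves < 40, open flowers > 65).

Components of the flower mask smaller than 100 px are discarded — this
also drops most protruding bud petals, and a 100-px component is kept
("less than 100" is excluded). Anthesis is called as the first imaging
day with a surviving component; no additional bud filter is applied, so
the known failure mode of this rule (yellow petals protruding from buds)
is preserved rather than masked. Flower counts divide each large
component's pixel count by the area of one fully opened flower
(`flower_ref_px`, a per-image-scale calibration constant; 150 px at the
generator's scale): components up to 1.5 reference flowers count as one,
larger ones as `round_half_up(pixels / flower_ref_px)`. Rounding half up
and the 1.5× split threshold are package definitions; only the division
rule itself is inherent to the method.

Canopy metrics: canopy width is the horizontal span of all component
bounding boxes; the canopy angle is defined here as the apex angle
`2·atan(width / (2·height))` of the isoceles triangle formed with the
side-view height — a package definition for a trait that is usually
named without a formula. Raceme branches are approximated by
agglomerative hierarchical clustering (complete linkage — the cited
clustering routine's conventional default — on Euclidean distances) of
each component's six positional features (min/max x, min/max y, centroid
x/y), cutting the tree at the known or predicted branch count k.

## Machine-learning harness

Two supervised tasks are built in.

*Raceme branch regression.* Features: plant age (DAS), flower pixels,
estimated flower count; label: manually counted branches. Because branch
counts are unevenly distributed integers this is treated as regression
(ordinary least squares, or Huber robust regression via `MASS::rlm`)
rather than classification. The published accuracy metric for this task
is not formally defined anywhere we could find; the package defines
accuracy as the fraction of predictions matching the true count after
rounding half up, with `1 − MAPE` available behind `metric = "mape"`.

*Drought-stress classification.* The 21-feature table at the target day
(default 49 DAS, deltas from the previous imaging day): mean/p75 NIR,
top-view pixels and hull with deltas, side-view pixels and hull with
deltas, pot weight before and after watering, area below the pot rim,
height and width with deltas, ExG, flowering group, and branch count.
The flowering group is encoded ordinally (early = 0, intermediate = 1,
late = 2) from terciles of observed anthesis days; plants that never
flowered fall in the late group. Rows with missing features (e.g.
unpaired NIR days, absent pot weights) are dropped and counted. The
majority class is down-sampled without replacement to the minority size
before cross-validation.

Both tasks use unstratified random k-fold cross-validation (default
k = 5; fold sizes differ by at most one, the shuffle seed is recorded in
every report). Classifiers — random forest, LDA, logistic regression,
KNN (K = 1 by default), decision tree, SVM — run with their libraries'
default hyperparameters; per fold, held-out observations are scored and
ROC AUC is computed by the Mann–Whitney rank statistic with ties
counting one half, which makes it invariant under monotone score
transformations. Folds whose training data collapse to a single class
are skipped and flagged.

## The synthetic generator

Real facility images are large, proprietary to their experiments, and
lack pixel-level ground truth. The generator renders rosettes with known
truth so that every stage is testable end to end:

- **Geometry.** Elliptical leaves around a centre with per-leaf angle,
  size and colour jitter; top view 160×160 px, side view 160×160 px
  (stem, canopy leaves, drooping tissue below a rim row at 118), NIR
  rendered independently at 80×80 px under a known registration
  (scale 0.5, offset 2,2) — so mask transfer is a real resampling task
  and the NIR truth region is not produced by the code under test.
- **Phenology.** Each genotype has a flowering onset; from that day,
  flowers are uniform yellow discs (radius ≈ 7 px, ≈ 150 px area — discs
  because the pipeline consumes only pixel counts and positions, and the
  disc area directly calibrates `flower_ref_px`) placed in `branches_k`
  spatial clusters with overlap-free rejection sampling whose scatter
  widens under crowding. Flowers per branch per day are 4 with mild
  integer jitter, keeping total flower count approximately linear in
  branch count — the condition under which branch regression is
  learnable.
- **Stress.** Drought symptoms from 35 DAS: leaf area shrinkage
  (1.2 %/day), sinusoidal boundary ruffling (amplitude 0.18, 9 lobes),
  hue shift toward yellow-green (−12°, lowering ExG), NIR intensity drop
  (−30), reduced side-view height and increased drooping below the rim,
  and lower simulated pot weights. Stressed plants are guaranteed
  smaller with strictly larger small-scale curvature variance than their
  control twins at equal seeds.
- **Determinism.** All randomness descends from one master seed through
  per-plant-day subseeds, so cohorts are bit-reproducible and any
  plant-day can be re-rendered alone.

The default validation cohort is 10 genotypes × 3 replicates per
watering regime × 10 imaging days (37–55 DAS, every other day), i.e.
600 plant-days and 1800 images — small enough to render and process in
about two minutes on one CPU while still giving ≈ 300 flowering
plant-days for the regression task and 60 day-49 observations for the
stress task.

What the generator does *not* emulate: photorealistic texture, occlusion
between neighbouring plants, mechanical damage from plant transport,
uneven watering within treatment groups, and the genotype-specific
colour/shape diversity of a real breeding panel. Passing tests therefore
demonstrate that the algorithms are implemented correctly and recover
known signal under controlled conditions — not that the shipped
thresholds segment any particular real facility's images, where
within-group variation is far larger and classification performance
substantially lower.

## Numerical choices and degenerate inputs

- Empty masks yield all-zero traits with an `empty` flag, not errors;
  empty NIR transfers are flagged and summaries become missing.
- `round_half_up(x) = floor(x + 0.5)` is used for count splitting and
  integer-match accuracy; base R's round-half-to-even would bias flower
  splitting at exact half counts.
- Hull areas of fewer than three distinct pixels are 0.
- Fold shuffling, down-sampling and stochastic learners draw from
  private RNG streams that save and restore the caller's `.Random.seed`.
- FFT convolution sizes are padded to 2-3-5-smooth lengths; results are
  rounded to integers, which is exact for counts below 2^52.
- Duplicate (plant, day, view, modality) metadata rows and inverted
  threshold bounds are rejected with named errors.

## Command-line interface

The exported functions are the primary interface; a thin `Rscript`
front end at `inst/cli/phenotyper` wraps them for shell use
(`synth`, `index`, `run`, `hocs` subcommands) without adding logic of
its own, and `scripts/acceptance.R` reproduces the headline numbers from
a fresh cohort (see the README).

## Known limitations

- Segmentation thresholds do not transfer across cameras or crops
  without re-tuning; that is inherent to threshold-based segmentation.
- The anthesis rule inherits the bud-protrusion false-positive mode.
- Raceme clustering approximates branches by top-view spatial clusters;
  overlapping branches in dense canopies will merge.
- The regression accuracy metric (rounded exact match) is a package
  definition; alternative conventions change the number.
- NIR registration is scale+offset only; a rotated or sheared camera
  pair needs external rectification first.
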