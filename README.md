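# phenotyper

Semi-automated image-based phenotyping of rosette crops (e.g. *Brassica
napus*) in indoor high-throughput imaging facilities.

Breeding experiments in plant-to-sensor facilities produce thousands of
per-plant, per-day images — top- and side-view RGB plus top-view
near-infrared (NIR) — and turning them into agronomic traits is the
bottleneck. `phenotyper` implements the full analysis chain for people
running such experiments:

- **Segmentation** by HSV/CIELAB channel thresholding with a configurable
  combine rule, small-object removal and hole filling (8-connected
  components throughout).
- **Holistic growth traits**: projected leaf area, convex hull area,
  height/width, side-view area below the pot rim, Excess Green Index
  (ExG = 2G − R + B, with the canonical 2G − R − B behind a flag),
  estimated biovolume `sqrt(side² × top)`, day-to-day Δ-traits, and
  per-trait per-day outlier filtering (median ± 3 SD).
- **NIR analysis**: transfer of the RGB plant mask onto the NIR camera
  geometry (scale + offset registration, nearest neighbour) and masked
  intensity summaries (mean, 75th percentile).
- **Boundary shape**: the histogram-of-curvature-over-scale (HOCS)
  descriptor built from the normalized area integral invariant — at each
  boundary pixel, the fraction of a radius-r disc inside the plant
  (≈ 0.5 on straight edges, < 0.5 convex, > 0.5 concave) — over 25 radii
  (5–125 px) × 5 histogram bins.
- **Flower phenology**: thresholding the CIELAB blue–yellow channel inside
  the plant mask, ≥ 100 px connected components, anthesis calling, flower
  counting with overlap splitting, canopy width/angle, and hierarchical
  clustering of components into raceme branches.
- **ML harness**: 5-fold cross-validated branch-count regression (linear,
  Huber) and drought-stress classification (random forest, LDA, logistic,
  KNN, decision tree, SVM) with majority-class down-sampling and
  rank-statistic ROC AUC.
- **Synthetic cohorts**: a generator that renders rosette plants with known
  ground truth (masks, flowering onset, flower and branch counts, stress
  morphology, NIR frame with known registration) so the whole pipeline is
  testable without an imaging facility.

## Worked example

Generate a small synthetic cohort and run the pipeline end to end:

```r
library(phenotyper)

coh <- generate_cohort(n_genotypes = 10, reps_per_treatment = 3,
                       schedule = seq(37, 55, by = 2), seed = 42)
cfg <- run_config(coh$dir,
                  registration = file.path(coh$dir, "registration.yaml"),
                  flower_ref_px = 150, seed = 42)
res <- run_pipeline(cfg)
#> indexed 1800 observations (0 rows failed)
#> segmented 1200 images; 600 NIR pairs; 60 HOCS descriptors
#> branch regression on 309 flowering plant-days
#> stress classification on 60 balanced day-49 observations (0 rows dropped)

res$ml$branches_linear
#> <cv_report> linear  rounded_match = 0.955 (SD 0.029)  n = 309/247/62
res$ml$stress_random_forest
#> <cv_report> random_forest  roc_auc = 1.000 (SD 0.000)  n = 60/48/12
```

The cohort is 10 genotypes × 6 replicates (3 control, 3 drought) × 10
imaging days. `run_pipeline()` writes `traits.csv`, `flowers.csv`,
`nir.csv`, `hocs.csv`, `plantday_features.csv`, `anthesis.csv`,
`ml_report.json` and a `run_manifest.json` (config hash, seed, stage
tallies) under `cfg$out_dir`. The branch-regression report reads: rounded
predictions matched the true branch count on 95.5% of held-out
plant-days (SD 2.9 points across the 5 folds; 309 observations, largest
split 247 train / 62 test). On this clean synthetic cohort the stress
classifier separates the groups essentially perfectly; real facilities
show far more within-group variation.

Individual stages are exported too — `segment_plant()`,
`extract_holistic()`, `transfer_mask()`/`summarize_nir()`,
`hocs_descriptor()`, `flower_mask()`/`extract_components()`/
`detect_anthesis()`, `cv_regression()`/`cv_classification()` — see the
help pages and the methods vignette (`vignettes/phenotyping-methods.Rmd`).
A thin CLI wrapper ships at `inst/cli/phenotyper`
(`synth`, `index`, `run`, `hocs` subcommands).

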