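# Solid-colour RGB raster (values 0-255), rows x cols x 3.
solid_rgb <- function(rgb, rows = 4, cols = 4) {
  array(rep(rgb, each = rows * cols), dim = c(rows, cols, 3))
}

# Brute-force area-integral-invariant oracle: naive double loop over disc
# offsets, independent of the package's FFT path.
aii_oracle <- function(mask, pts, radius) {
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2, ]
  apply(pts, 1, function(p) {
    cc <- p[1] + off$dx
    rr <- p[2] + off$dy
    ok <- cc >= 1 & cc <= ncol(mask) & rr >= 1 & rr <= nrow(mask)
    sum(mask[cbind(rr[ok], cc[ok])]) / nrow(off)
  })
}

# Write a tiny on-disk image dataset for dataset_io tests; returns the
# metadata data frame with a `dir` attribute.
write_tiny_dataset <- function(n_plants = 2, das = c(40, 42)) {
  dir <- tempfile("tinyds")
  dir.create(dir)
  rows <- list()
  for (p in seq_len(n_plants)) for (d in das) {
    id <- sprintf("P%d", p)
    f <- sprintf("%s_%d_top_rgb.png", id, d)
    png::writePNG(array(runif(4 * 4 * 3), dim = c(4, 4, 3)),
                  file.path(dir, f))
    rows[[length(rows) + 1]] <- data.frame(
      plant_id = id, genotype = "G1", das = d, treatment = "control",
      view = "top", modality = "RGB", path = f,
      weight_before = 900, weight_after = 1100)
  }
  md <- do.call(rbind, rows)
  attr(md, "dir") <- dir
  md
}

# One synthetic cohort (the study conditions: 10 genotypes x 3 reps per
# watering regime x 10 imaging days) processed once per test session and
# shared across tests; generating and segmenting it dominates the suite's
# runtime, so it is memoized.
.cohort_cache <- new.env(parent = emptyenv())
test_cohort <- function() {
  if (!is.null(.cohort_cache$res)) return(.cohort_cache$res)
  coh <- generate_cohort(n_genotypes = 10, reps_per_treatment = 3,
                         schedule = seq(37, 55, by = 2), seed = 42)
  cfg <- run_config(coh$dir,
                    registration = file.path(coh$dir, "registration.yaml"),
                    flower_ref_px = 150, seed = 42)
  res <- run_pipeline(cfg, quiet = TRUE)
  .cohort_cache$res <- list(cohort = coh, pipeline = res)
  .cohort_cache$res
}
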