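test_that("rendering is bit-identical for identical seeds", {
  g <- genotype_params(flowering_onset_das = 43)
  a <- render_plant(g, 49, seed = 12)
  b <- render_plant(g, 49, seed = 12)
  expect_identical(a, b)
  c <- render_plant(g, 49, seed = 13)
  expect_false(identical(a$rgb_top, c$rgb_top))
})

test_that("truth records match the rendered rasters", {
  g <- genotype_params(flowering_onset_das = 43, branches_k = 3)
  out <- render_plant(g, 49, seed = 2)
  # flower pixels are plant pixels
  expect_true(all(out$truth$mask_top[out$truth$flower_mask]))
  # flower truth: every flower disc is a separate component of the truth mask
  comps <- component_table(out$truth$flower_mask)
  expect_equal(nrow(comps), out$truth$flower_count)
  expect_equal(nrow(out$truth$flower_centers), out$truth$flower_count)
  expect_equal(out$truth$branch_count, 3)
})

test_that("pre-flowering plants carry no flower signal", {
  g <- genotype_params(flowering_onset_das = 51)
  out <- render_plant(g, 45, seed = 6)
  expect_equal(out$truth$flower_count, 0)
  expect_false(out$truth$flowering)
  b <- convert_colorspace(out$rgb_top, "CIELAB")[, , 3]
  expect_equal(sum(b[out$truth$mask_top] >= 55), 0)
})

test_that("stress shrinks the plant and ruffles its boundary", {
  g <- genotype_params(flowering_onset_das = Inf)
  ctrl <- render_plant(g, 49, seed = 8)
  strs <- render_plant(g, 49, stress = stress_params(), seed = 8)
  expect_lt(sum(strs$truth$mask_top), sum(ctrl$truth$mask_top))
  # curvature variance at a small scale is strictly larger when ruffled
  v_c <- var(area_integral_invariant(ctrl$truth$mask_top,
                                     trace_boundary(ctrl$truth$mask_top), 5))
  v_s <- var(area_integral_invariant(strs$truth$mask_top,
                                     trace_boundary(strs$truth$mask_top), 5))
  expect_gt(v_s, v_c)
})

test_that("impossible geometry is rejected", {
  g <- genotype_params(flower_radius_px = 200)
  expect_error(render_plant(g, 49, seed = 1), "flower radius")
})

test_that("cohort layout has the expected image count and is reproducible", {
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(n_genotypes = 2, reps_per_treatment = 1,
                        schedule = c(41, 43, 45), seed = 99, out_dir = d1)
  # 2 genotypes x 2 plants (1 rep x 2 treatments) x 3 days x 3 images
  expect_equal(nrow(c1$metadata), 36)
  expect_true(all(file.exists(file.path(d1, c1$metadata$path))))
  expect_true(file.exists(file.path(d1, "truth.csv")))
  expect_true(file.exists(file.path(d1, "registration.yaml")))

  c2 <- generate_cohort(n_genotypes = 2, reps_per_treatment = 1,
                        schedule = c(41, 43, 45), seed = 99, out_dir = d2)
  expect_identical(c1$metadata[, names(c1$metadata) != "path"],
                   c2$metadata[, names(c2$metadata) != "path"])
  expect_identical(c1$truth, c2$truth)
  f <- c1$metadata$path[1]
  expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                   readBin(file.path(d2, f), "raw", 1e6))
})

test_that("drought replicates are flagged stressed during the treatment window", {
  coh <- generate_cohort(n_genotypes = 1, reps_per_treatment = 1,
                         schedule = c(47, 49), seed = 31)
  tr <- coh$truth
  expect_true(all(tr$stressed[tr$treatment == "drought"] == 1))
  expect_true(all(tr$stressed[tr$treatment == "control"] == 0))
  ctrl49 <- tr[tr$treatment == "control" & tr$das == 49, ]
  strs49 <- tr[tr$treatment == "drought" & tr$das == 49, ]
  expect_lt(strs49$pixels_top, ctrl49$pixels_top)
})
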