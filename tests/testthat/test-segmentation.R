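test_that("colour-space conversion hits the reference identities", {
  green <- convert_colorspace(solid_rgb(c(0, 255, 0), 1, 1), "HSV")[1, 1, ]
  expect_equal(green, c(120, 1, 1), tolerance = 1e-6)
  gray <- convert_colorspace(solid_rgb(c(128, 128, 128), 1, 1),
                             "CIELAB")[1, 1, ]
  expect_equal(gray[2:3], c(0, 0), tolerance = 1e-6)
  white <- convert_colorspace(solid_rgb(c(255, 255, 255), 1, 1),
                              "CIELAB")[1, 1, ]
  expect_equal(white[1], 100, tolerance = 1e-6)
  expect_error(convert_colorspace(matrix(0, 2, 2), "HSV"), "3")
})

test_that("channel thresholding is inclusive on both bounds", {
  ch <- matrix(c(1, 9, 5, 3), 2, 2)
  expect_equal(threshold_channel(ch, 4, 10), matrix(c(F, T, T, F), 2, 2))
  expect_true(all(threshold_channel(ch, min(ch), max(ch))))
  expect_equal(threshold_channel(ch, 5, 5), ch == 5)
  expect_error(threshold_channel(ch, 10, 4), "low")
})

test_that("mask combination evaluates the boolean rule over named masks", {
  a <- matrix(c(T, F, F, F), 2, 2)
  b <- matrix(c(F, F, F, T), 2, 2)
  expect_equal(combine_and_clean(list(a = a, b = b), "a | b"), a | b)
  expect_equal(combine_and_clean(list(a = a, b = b), "a & b"),
               matrix(FALSE, 2, 2))
  expect_error(combine_and_clean(list(a = a), "a | c"), "unknown mask")
})

test_that("cleanup removes small specks and fills small holes", {
  m <- matrix(FALSE, 12, 12)
  m[3:8, 3:8] <- TRUE       # 36-px blob
  m[11, 11] <- TRUE; m[11, 12] <- TRUE; m[12, 11] <- TRUE  # 3-px speck
  cleaned <- combine_and_clean(list(m = m), min_object_px = 5)
  expect_false(any(cleaned[10:12, 10:12]))
  expect_true(all(cleaned[3:8, 3:8]))

  holed <- matrix(FALSE, 12, 12)
  holed[3:9, 3:9] <- TRUE
  holed[5, 5:6] <- FALSE    # 2-px hole
  filled <- combine_and_clean(list(m = holed), fill_hole_px = 4)
  expect_true(all(filled[3:9, 3:9]))
  # a hole at least fill_hole_px survives
  holed[6:7, 5:6] <- FALSE
  kept <- combine_and_clean(list(m = holed), fill_hole_px = 4)
  expect_false(all(kept[3:9, 3:9]))
})

test_that("cleanup is monotone in min_object_px", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(runif(400) > 0.55, 20, 20)
    prev <- combine_and_clean(list(m = m), min_object_px = 0)
    for (mo in c(2, 5, 10, 20)) {
      cur <- combine_and_clean(list(m = m), min_object_px = mo)
      expect_true(all(cur <= prev))
      prev <- cur
    }
  }
})

test_that("mask application zeroes background and is idempotent", {
  r <- solid_rgb(c(10, 20, 30), 3, 3)
  all_true <- matrix(TRUE, 3, 3)
  expect_equal(apply_mask(r, all_true), r)
  expect_true(all(apply_mask(r, matrix(FALSE, 3, 3)) == 0))
  half <- matrix(c(rep(TRUE, 4), rep(FALSE, 5)), 3, 3)
  once <- apply_mask(r, half)
  expect_equal(apply_mask(once, half), once)
  expect_error(apply_mask(r, matrix(TRUE, 2, 2)), "shape")
})

test_that("default thresholds recover synthetic plant pixels almost exactly", {
  for (seed in c(1, 5, 9)) {
    g <- genotype_params(flowering_onset_das = 45, branches_k = 2)
    out <- render_plant(g, 49, seed = seed)
    mask <- segment_plant(out$rgb_top)
    truth <- out$truth$mask_top
    expect_gt(sum(mask & truth) / sum(truth), 0.99)
    expect_lt(sum(mask & !truth) / sum(!truth), 0.01)
  }
})

test_that("segmentation config validates thresholds and round-trips YAML", {
  expect_error(segmentation_config(hsv = list(s = c(0.9, 0.1))), "low")
  cfg <- default_segmentation_config()
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(hsv = cfg$hsv, lab = cfg$lab,
                        combine_rule = cfg$combine_rule,
                        min_object_px = cfg$min_object_px,
                        fill_hole_px = cfg$fill_hole_px), f)
  back <- read_segmentation_config(f)
  expect_equal(back$combine_rule, cfg$combine_rule)
  expect_equal(back$lab$b, cfg$lab$b)
})
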