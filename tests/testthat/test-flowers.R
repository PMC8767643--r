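# Build an RGB image with a green plant disc and optional yellow flower
# discs at given (x, y) centres.
plant_with_flowers <- function(size = 60, plant_r = 22, flower_r = 6,
                               centers = NULL) {
  img <- array(0, dim = c(size, size, 3))
  img[, , 1] <- 70; img[, , 2] <- 65; img[, , 3] <- 60
  ctr <- size / 2
  plant <- outer(seq_len(size), seq_len(size),
                 function(r, c) (r - ctr)^2 + (c - ctr)^2 <= plant_r^2)
  for (k in 1:3) { ch <- img[, , k]; ch[plant] <- c(45, 120, 55)[k]; img[, , k] <- ch }
  if (!is.null(centers)) for (i in seq_len(nrow(centers))) {
    fl <- outer(seq_len(size), seq_len(size),
                function(r, c) (r - centers[i, 2])^2 +
                  (c - centers[i, 1])^2 <= flower_r^2)
    for (k in 1:3) { ch <- img[, , k]; ch[fl] <- c(235, 215, 40)[k]; img[, , k] <- ch }
  }
  list(img = img, plant = plant)
}

test_that("flower mask is the thresholded b channel inside the plant mask", {
  noflower <- plant_with_flowers()
  fm <- flower_mask(noflower$img, noflower$plant, das = 45)
  expect_false(any(fm))

  withf <- plant_with_flowers(centers = cbind(30, 30))
  fm2 <- flower_mask(withf$img, withf$plant, das = 45)
  expect_gt(sum(fm2), 80)
  expect_true(all(fm2 <= withf$plant))

  # a yellow region outside the plant mask is excluded
  outside <- plant_with_flowers(centers = cbind(6, 6))
  fm3 <- flower_mask(outside$img, outside$plant, das = 45)
  expect_false(any(fm3))
})

test_that("policy rules are matched on age and treatment, first hit wins", {
  pol <- flower_threshold_policy(data.frame(
    das_min = c(1, 40), das_max = c(39, 99),
    treatment = c("any", "drought"), b_low = c(50, 60)))
  img <- plant_with_flowers(centers = cbind(30, 30))
  expect_silent(flower_mask(img$img, img$plant, pol, das = 30,
                            treatment = "control"))
  expect_error(flower_mask(img$img, img$plant, pol, das = 45,
                           treatment = "control"), "no flower-threshold rule")
})

test_that("component extraction filters below 100 px but keeps exactly 100", {
  m <- matrix(FALSE, 60, 80)
  m[2:11, 2:6] <- TRUE                    # 50 px
  m[20:29, 1:10] <- TRUE                  # 100 px exactly
  m[40:59, 41:60] <- TRUE                 # 400 px
  comps <- extract_components(m)
  expect_equal(nrow(comps), 2)
  expect_setequal(comps$pixel_count, c(100, 400))
  expect_equal(nrow(extract_components(matrix(FALSE, 5, 5))), 0)
})

test_that("anthesis is the first day with a surviving component", {
  expect_equal(detect_anthesis(c(35, 37, 39), c(0, 0, 1)), 39)
  expect_true(is.na(detect_anthesis(c(35, 37, 39), c(0, 0, 0))))
  expect_equal(detect_anthesis(c(35, 37), c(2, 3)), 35)
  # order of the series does not matter
  expect_equal(detect_anthesis(c(39, 35, 37), c(1, 0, 1)), 37)
})

test_that("flower counting splits large components by the reference size", {
  expect_equal(estimate_flower_count(data.frame(pixel_count = 120), 150), 1)
  expect_equal(estimate_flower_count(data.frame(pixel_count = 450), 150), 3)
  expect_equal(estimate_flower_count(data.frame(pixel_count = 225), 150), 1)
  expect_equal(estimate_flower_count(data.frame(pixel_count = 226), 150), 2)
  expect_equal(
    estimate_flower_count(data.frame(pixel_count = c(120, 450)), 150), 4)
  expect_equal(estimate_flower_count(empty_df <- data.frame(
    pixel_count = numeric()), 150), 0L)
  expect_error(estimate_flower_count(data.frame(pixel_count = 1), 0),
               "positive")
})

test_that("canopy metrics derive width and apex angle from components", {
  comps <- data.frame(min_x = c(10, 60), max_x = c(40, 110))
  cm <- canopy_metrics(comps, plant_height_px = 50)
  expect_equal(cm$canopy_width_px, 100)
  expect_equal(cm$canopy_angle_deg, 90)
  expect_true(is.na(canopy_metrics(comps[0, ], 50)$canopy_width_px))
})

test_that("raceme clustering recovers well-separated branch groups", {
  comps <- data.frame(
    min_x = c(10, 12, 14, 510, 512, 514),
    max_x = c(20, 22, 24, 520, 522, 524),
    min_y = c(10, 14, 18, 10, 14, 18),
    max_y = c(20, 24, 28, 20, 24, 28),
    centroid_x = c(15, 17, 19, 515, 517, 519),
    centroid_y = c(15, 19, 23, 15, 19, 23))
  lab <- cluster_racemes(comps, 2)
  expect_equal(lab[1:3], rep(lab[1], 3))
  expect_equal(lab[4:6], rep(lab[4], 3))
  expect_true(lab[1] != lab[4])

  expect_equal(cluster_racemes(comps, 1), rep(1L, 6))
  expect_equal(sort(cluster_racemes(comps, 6)), 1:6)
  expect_error(cluster_racemes(comps, 7), "exceeds")

  # invariance to component input order (as a partition)
  set.seed(13)
  perm <- sample(6)
  lab2 <- cluster_racemes(comps[perm, ], 2)
  same <- outer(lab, lab, "==")
  same2 <- outer(lab2, lab2, "==")[order(perm), order(perm)]
  expect_equal(same, same2)
})
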