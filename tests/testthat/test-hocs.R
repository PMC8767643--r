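test_that("boundary tracing finds exactly the pixels touching background", {
  sq <- matrix(TRUE, 3, 3)
  expect_equal(nrow(trace_boundary(sq)), 8)   # all but the centre

  line <- matrix(TRUE, 1, 5)
  expect_equal(nrow(trace_boundary(line)), 5)

  two <- matrix(FALSE, 8, 8)
  two[1:2, 1:2] <- TRUE; two[6:8, 6:8] <- TRUE
  b <- trace_boundary(two)
  expect_equal(nrow(b), 4 + 8)                # full blob + square ring
  expect_error(trace_boundary(matrix(FALSE, 3, 3)), "empty")
})

test_that("hole boundaries are part of the traced boundary", {
  m <- matrix(TRUE, 9, 9)
  m[5, 5] <- FALSE
  b <- trace_boundary(m)
  keys <- paste(b[, 1], b[, 2])
  # the 8 pixels around the interior hole are boundary pixels
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    expect_true(paste(5 + dx, 5 + dy) %in% keys)
  }
})

test_that("the area integral invariant reflects local geometry", {
  # discrete discs include the centre row/column, biasing the edge value
  # slightly above the continuum limit
  half <- matrix(FALSE, 41, 41); half[, 1:20] <- TRUE
  v_edge <- area_integral_invariant(half, cbind(20, 21), 5)
  expect_lt(abs(v_edge - 0.5), 0.1)

  big <- matrix(FALSE, 80, 80); big[11:70, 11:70] <- TRUE
  v_corner <- area_integral_invariant(big, cbind(11, 11), 10)
  expect_lt(abs(v_corner - 0.25), 0.08)

  v_deep <- area_integral_invariant(big, cbind(40, 40), 10)
  expect_equal(v_deep, 1.0)
})

test_that("FFT disc counts equal the brute-force oracle exactly", {
  set.seed(7)
  shapes <- list(
    matrix(runif(64 * 64) > 0.6, 64, 64),
    matrix(runif(40 * 64) > 0.35, 40, 64),
    {m <- matrix(FALSE, 50, 50); m[10:40, 15:35] <- TRUE; m[20, 20] <- FALSE; m}
  )
  for (m in shapes) {
    bnd <- trace_boundary(m)
    for (r in c(1, 2, 5, 9, 15)) {
      expect_equal(area_integral_invariant(m, bnd, r),
                   aii_oracle(m, bnd, r), tolerance = 1e-12)
    }
  }
})

test_that("descriptor has the documented shape and normalization", {
  out <- render_plant(genotype_params(), 45, seed = 4)
  d <- hocs_descriptor(out$truth$mask_top)
  expect_equal(dim(d$matrix), c(25, 5))
  expect_equal(d$radii, seq(5, 125, by = 5))
  expect_true(all(abs(rowSums(d$matrix) - 1) < 1e-9))
  expect_true(all(d$matrix >= 0))
  f <- hocs_features(d)
  expect_length(f, 125)
  expect_equal(unname(f[1:5]), unname(d$matrix[1, ]))
})

test_that("descriptor is exactly invariant to translation and right-angle rotation", {
  m <- matrix(FALSE, 48, 48)
  m[10:25, 12:30] <- TRUE; m[15:20, 8:11] <- TRUE; m[26:35, 20:24] <- TRUE
  radii <- c(3, 5, 9)
  base <- hocs_descriptor(m, radii = radii)$matrix

  shifted <- matrix(FALSE, 58, 58)
  shifted[6:53, 9:56] <- m
  expect_equal(hocs_descriptor(shifted, radii = radii)$matrix, base)

  r90 <- t(m)[, nrow(m):1]
  r180 <- m[nrow(m):1, ncol(m):1]
  expect_equal(hocs_descriptor(r90, radii = radii)$matrix, base)
  expect_equal(hocs_descriptor(r180, radii = radii)$matrix, base)
})

test_that("a filled disc concentrates small-radius curvature near 0.5", {
  m <- matrix(FALSE, 90, 90)
  ctr <- 45.5
  for (r in 1:90) for (c in 1:90)
    if ((r - ctr)^2 + (c - ctr)^2 <= 35^2) m[r, c] <- TRUE
  d <- hocs_descriptor(m, radii = c(5, 10), n_bins = 5)
  # bin 3 covers [0.4, 0.6): a circular arc is locally near-straight, up to
  # the pixel staircase of the rasterized boundary
  expect_gt(d$matrix["r5", 3], 0.5)
  expect_equal(which.max(d$matrix["r5", ]), 3L, ignore_attr = TRUE)
})

test_that("boundary ruffling moves curvature mass away from the central bin", {
  g <- genotype_params(flowering_onset_das = Inf)
  ctrl <- render_plant(g, 49, seed = 3)
  strs <- render_plant(g, 49, stress = stress_params(), seed = 3)
  hc <- hocs_descriptor(segment_plant(ctrl$rgb_top), radii = c(5, 10))
  hs <- hocs_descriptor(segment_plant(strs$rgb_top), radii = c(5, 10))
  expect_lt(hs$matrix[1, 3], hc$matrix[1, 3])
})
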