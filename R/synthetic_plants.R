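#' Genotype parameters for the synthetic plant generator
#'
#' Each synthetic genotype is a rosette recipe: leaf number, size and
#' elongation, hue, growth rate, flowering onset, raceme branch number, and
#' flower output. Defaults emulate a mid-size spring rosette imaged at
#' roughly 160 px across.
#'
#' @param n_leaves Number of rosette leaves.
#' @param leaf_length_px Mature leaf length, px.
#' @param leaf_aspect Leaf minor/major axis ratio.
#' @param hue_center,hue_jitter Leaf hue (HSV degrees) and per-leaf jitter.
#' @param growth_rate Fractional size gain per day (size saturates at 1).
#' @param flowering_onset_das First day with open flowers; `Inf` for a
#'   plant that does not flower within the experiment.
#' @param branches_k Number of raceme branches once flowering.
#' @param flowers_per_branch_per_day Mean open flowers per branch per
#'   imaging day.
#' @param flower_radius_px Radius of one fully opened flower disc.
#' @param height_rate Side-view height gain, px per day.
#' @return A `genotype_params` list.
#' @export
genotype_params <- function(n_leaves = 10, leaf_length_px = 48,
                            leaf_aspect = 0.45, hue_center = 120,
                            hue_jitter = 8, growth_rate = 0.07,
                            flowering_onset_das = 45, branches_k = 3,
                            flowers_per_branch_per_day = 4,
                            flower_radius_px = 7, height_rate = 2.7) {
  stopifnot(n_leaves > 0, leaf_length_px > 0, leaf_aspect > 0,
            growth_rate > 0, branches_k >= 1,
            flowers_per_branch_per_day > 0, flower_radius_px > 0)
  structure(as.list(environment()), class = "genotype_params")
}

#' Drought-stress parameters for the synthetic generator
#'
#' Mild drought symptoms: per-day area shrinkage (turgor loss), sinusoidal
#' ruffling of leaf boundaries (leaf rolling seen from above), a greenness
#' shift (hue toward yellow-green), and an NIR intensity drop (lower tissue
#' water), all starting at `onset_das`.
#'
#' @param area_shrink_fraction Leaf-size shrink per day after onset.
#' @param boundary_ruffle_amplitude Relative amplitude of the boundary
#'   ruffle (0 = smooth).
#' @param boundary_ruffle_frequency Ruffle lobes per leaf circumference.
#' @param hue_shift Leaf hue shift in HSV degrees (negative = toward
#'   yellow), lowering ExG.
#' @param nir_shift Additive NIR intensity change (negative = drier).
#' @param onset_das First day the symptoms apply.
#' @return A `stress_params` list.
#' @export
stress_params <- function(area_shrink_fraction = 0.012,
                          boundary_ruffle_amplitude = 0.18,
                          boundary_ruffle_frequency = 9,
                          hue_shift = -12, nir_shift = -30,
                          onset_das = 35) {
  stopifnot(area_shrink_fraction >= 0, area_shrink_fraction <= 1,
            boundary_ruffle_amplitude >= 0, boundary_ruffle_amplitude < 1)
  structure(as.list(environment()), class = "stress_params")
}

#' Image geometry of the synthetic cameras
#'
#' The NIR camera renders at half the RGB resolution with a small fixed
#' frame offset, so transferring RGB masks to the NIR frame is a real
#' resampling task.
#'
#' @param rgb_size,nir_size Square image sizes, px.
#' @param nir_scale,nir_offset Registration truth: `nir = rgb * scale +
#'   offset`.
#' @param rim_row Side-view pot rim row.
#' @return A list of geometry constants.
#' @export
synth_geometry <- function(rgb_size = 160, nir_size = 80, nir_scale = 0.5,
                           nir_offset = c(x = 2, y = 2), rim_row = 118) {
  list(rgb_size = rgb_size, nir_size = nir_size, nir_scale = nir_scale,
       nir_offset = nir_offset, rim_row = rim_row)
}

# Pixels inside a rotated (optionally ruffled) ellipse, on a canvas of the
# given size. Returns a logical matrix. The ruffle multiplies the ellipse
# radius by 1 + amp * sin(freq * phi + phase), phi being the angle in the
# ellipse frame, which corrugates the boundary without moving its centroid.
ellipse_mask <- function(size_r, size_c, cx, cy, a, b, theta,
                         ruffle_amp = 0, ruffle_freq = 0, ruffle_phase = 0) {
  m <- matrix(FALSE, size_r, size_c)
  ext <- max(a, b) * (1 + ruffle_amp) + 1
  rows <- max(1, floor(cy - ext)):min(size_r, ceiling(cy + ext))
  cols <- max(1, floor(cx - ext)):min(size_c, ceiling(cx + ext))
  if (length(rows) == 0 || length(cols) == 0) return(m)
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  ex <- dx * cos(theta) + dy * sin(theta)
  ey <- -dx * sin(theta) + dy * cos(theta)
  q <- sqrt((ex / a)^2 + (ey / b)^2)
  lim <- if (ruffle_amp > 0) {
    phi <- atan2(ey / b, ex / a)
    1 + ruffle_amp * sin(ruffle_freq * phi + ruffle_phase)
  } else 1
  m[rows, cols] <- q <= lim
  m
}

disc_mask <- function(size_r, size_c, cx, cy, r) {
  ellipse_mask(size_r, size_c, cx, cy, r, r, 0)
}

# Paint a mask region onto RGB channel matrices with a base colour (0-255)
# and per-pixel gaussian noise.
paint <- function(channels, region, rgb, noise_sd = 4) {
  n <- sum(region)
  if (n == 0) return(channels)
  for (k in 1:3) {
    ch <- channels[[k]]
    ch[region] <- pmin(255, pmax(0, rgb[k] + rnorm(n, 0, noise_sd)))
    channels[[k]] <- ch
  }
  channels
}

hsv255 <- function(h, s, v) {
  as.numeric(col2rgb(hsv(max(0, min(1, h / 360)), max(0, min(1, s)),
                         max(0, min(1, v)))))
}

# Deterministic placement of flower discs in branch clusters: gaussian
# scatter around each branch centre with rejection of overlaps (minimum
# centre distance 2r + 3) and of positions too close to the frame edge.
place_flowers <- function(k, per_branch, center, spread_radius, r_f,
                          frame, max_try = 60) {
  angles <- seq(0, 2 * pi, length.out = k + 1)[seq_len(k)] +
    runif(1, 0, 2 * pi / k)
  bc <- cbind(center[1] + spread_radius * cos(angles),
              center[2] + spread_radius * sin(angles))
  placed <- matrix(numeric(0), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "branch")))
  for (j in seq_len(k)) {
    for (f in seq_len(per_branch[j])) {
      for (t in seq_len(max_try)) {
        # scatter widens with failed attempts so crowded branches still
        # place their full flower complement
        p <- bc[j, ] + rnorm(2, 0, 6 + 0.4 * t)
        if (p[1] < r_f + 2 || p[1] > frame - r_f - 1 ||
            p[2] < r_f + 2 || p[2] > frame - r_f - 1) next
        if (nrow(placed) > 0 &&
            min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2)) <
              2 * r_f + 3) next
        placed <- rbind(placed, c(p, j))
        break
      }
    }
  }
  placed
}

#' Render one synthetic plant on one day
#'
#' Draws the top-view RGB rosette (elliptical leaves with per-leaf rotation
#' and colour jitter around the genotype hue), the side-view silhouette
#' (stem, canopy, drooping leaves below the pot rim), and the NIR top view
#' rendered independently in the NIR camera geometry (half resolution,
#' offset frame). Once `das` reaches the flowering onset, yellow flower
#' discs are placed in `branches_k` spatial clusters. Drought stress
#' shrinks leaf area, ruffles leaf boundaries, shifts leaf hue and lowers
#' NIR intensity. Identical seeds give bit-identical images.
#'
#' @param genotype A [genotype_params()].
#' @param das Day after seeding.
#' @param stress A [stress_params()] or `NULL` for a well-watered plant.
#' @param seed Integer seed.
#' @param geometry A [synth_geometry()].
#' @return List with `rgb_top`, `rgb_side` (arrays, 0-255), `nir_top`
#'   (matrix), and `truth` (masks, NIR plant region, flower centres and
#'   count, branch count, flowering onset, stress flag, registration).
#' @export
render_plant <- function(genotype, das, stress = NULL, seed = 1,
                         geometry = synth_geometry()) {
  stopifnot(inherits(genotype, "genotype_params"), das >= 1)
  g <- genotype
  if (g$flower_radius_px * 2 >= geometry$rgb_size)
    stop("flower radius exceeds the image frame")
  with_seed(seed, {
    sz <- geometry$rgb_size
    nsz <- geometry$nir_size
    stressed_now <- !is.null(stress) && das >= stress$onset_das
    shrink <- if (stressed_now)
      max(0.55, 1 - stress$area_shrink_fraction * (das - stress$onset_das))
    else 1
    size_f <- min(1, 0.25 + g$growth_rate * max(0, das - 21))
    L <- g$leaf_length_px * size_f * shrink
    center <- c(sz / 2, sz / 2)

    # --- top view -----------------------------------------------------
    bgR <- matrix(pmin(255, pmax(0, 70 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    bgG <- matrix(pmin(255, pmax(0, 65 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    bgB <- matrix(pmin(255, pmax(0, 60 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    ch <- list(bgR, bgG, bgB)
    pot <- disc_mask(sz, sz, center[1], center[2], 0.42 * sz)
    ch <- paint(ch, pot, c(52, 50, 52), 2)

    plant_mask <- matrix(FALSE, sz, sz)
    leaf_params <- vector("list", g$n_leaves)
    for (i in seq_len(g$n_leaves)) {
      theta <- 2 * pi * (i - 1) / g$n_leaves + rnorm(1, 0, 0.06)
      a <- L / 2 * runif(1, 0.85, 1.05)
      b <- a * g$leaf_aspect * runif(1, 0.9, 1.1)
      d <- 0.58 * L
      cx <- center[1] + d * cos(theta)
      cy <- center[2] + d * sin(theta)
      phase <- runif(1, 0, 2 * pi)
      leaf_params[[i]] <- list(cx = cx, cy = cy, a = a, b = b,
                               theta = theta, phase = phase)
      lm <- ellipse_mask(sz, sz, cx, cy, a, b, theta,
                         ruffle_amp = if (stressed_now)
                           stress$boundary_ruffle_amplitude else 0,
                         ruffle_freq = if (stressed_now)
                           stress$boundary_ruffle_frequency else 0,
                         ruffle_phase = phase)
      hue <- g$hue_center + rnorm(1, 0, g$hue_jitter) +
        if (stressed_now) stress$hue_shift else 0
      col <- hsv255(hue, runif(1, 0.55, 0.68), runif(1, 0.40, 0.55))
      ch <- paint(ch, lm, col, 4)
      plant_mask <- plant_mask | lm
    }

    # flowers
    flowers <- matrix(numeric(0), ncol = 3)
    flower_mask_truth <- matrix(FALSE, sz, sz)
    flowering <- is.finite(g$flowering_onset_das) &&
      das >= g$flowering_onset_das
    if (flowering) {
      per_branch <- pmax(1, g$flowers_per_branch_per_day +
                           sample(c(-1L, 0L, 1L), g$branches_k, TRUE,
                                  c(0.1, 0.8, 0.1)))
      flowers <- place_flowers(g$branches_k, per_branch, center,
                               spread_radius = max(16, 0.45 * L),
                               r_f = g$flower_radius_px, frame = sz)
      if (nrow(flowers) > 0) {
        radii <- runif(nrow(flowers), g$flower_radius_px - 0.4,
                       g$flower_radius_px + 0.4)
        for (f in seq_len(nrow(flowers))) {
          fm <- disc_mask(sz, sz, flowers[f, 1], flowers[f, 2], radii[f])
          col <- c(235, 215, 40) + rnorm(3, 0, 4)
          ch <- paint(ch, fm, col, 3)
          flower_mask_truth <- flower_mask_truth | fm
          plant_mask <- plant_mask | fm
        }
      }
    }
    rgb_top <- array(c(ch[[1]], ch[[2]], ch[[3]]), dim = c(sz, sz, 3))

    # --- NIR top view (independent analytic render in NIR frame) -------
    s <- geometry$nir_scale
    ox <- geometry$nir_offset[["x"]]; oy <- geometry$nir_offset[["y"]]
    nir <- matrix(pmin(255, pmax(0, 45 + rnorm(nsz * nsz, 0, 3))), nsz, nsz)
    nir_region <- matrix(FALSE, nsz, nsz)
    for (lp in leaf_params) {
      lm <- ellipse_mask(nsz, nsz, lp$cx * s + ox, lp$cy * s + oy,
                         lp$a * s, lp$b * s, lp$theta,
                         ruffle_amp = if (stressed_now)
                           stress$boundary_ruffle_amplitude else 0,
                         ruffle_freq = if (stressed_now)
                           stress$boundary_ruffle_frequency else 0,
                         ruffle_phase = lp$phase)
      nir_region <- nir_region | lm
    }
    leaf_nir <- 170 + if (stressed_now) stress$nir_shift else 0
    nir[nir_region] <- pmin(255, pmax(0, leaf_nir +
                                        rnorm(sum(nir_region), 0, 6)))
    if (nrow(flowers) > 0) {
      for (f in seq_len(nrow(flowers))) {
        fm <- disc_mask(nsz, nsz, flowers[f, 1] * s + ox,
                        flowers[f, 2] * s + oy, g$flower_radius_px * s)
        nir[fm] <- pmin(255, pmax(0, 205 + rnorm(sum(fm), 0, 5)))
        nir_region <- nir_region | fm
      }
    }

    # --- side view ------------------------------------------------------
    rim <- geometry$rim_row
    sR <- matrix(pmin(255, pmax(0, 70 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    sG <- matrix(pmin(255, pmax(0, 65 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    sB <- matrix(pmin(255, pmax(0, 60 + rnorm(sz * sz, 0, 2.5))), sz, sz)
    sch <- list(sR, sG, sB)
    pot_mask <- matrix(FALSE, sz, sz)
    pot_mask[(rim + 1):min(sz, rim + 34),
             round(sz * 0.35):round(sz * 0.65)] <- TRUE
    sch <- paint(sch, pot_mask, c(45, 44, 46), 2)

    droop_turgor <- if (stressed_now)
      max(0.6, 1 - 0.012 * (das - stress$onset_das)) else 1
    h <- max(12, (14 + g$height_rate * max(0, das - 21)) * droop_turgor)
    top_row <- max(6, rim - h)
    side_mask <- matrix(FALSE, sz, sz)
    stem_w <- 2
    side_mask[ceiling(top_row):rim,
              (round(sz / 2) - stem_w):(round(sz / 2) + stem_w)] <- TRUE
    canopy_w <- max(10, L * runif(1, 0.85, 1.0))
    n_side_leaves <- 4
    for (i in seq_len(n_side_leaves)) {
      frac <- i / (n_side_leaves + 1)
      lw <- canopy_w * (0.45 + 0.3 * frac)
      droop_angle <- (0.15 + (1 - droop_turgor) * 1.8) * pi / 6
      side_dir <- if (i %% 2 == 0) 1 else -1
      lm <- ellipse_mask(sz, sz,
                         sz / 2 + side_dir * lw / 3,
                         rim - h * (1 - frac) + 2,
                         lw / 2, lw / 6,
                         side_dir * droop_angle,
                         ruffle_amp = if (stressed_now)
                           stress$boundary_ruffle_amplitude / 2 else 0,
                         ruffle_freq = if (stressed_now)
                           stress$boundary_ruffle_frequency else 0,
                         ruffle_phase = runif(1, 0, 2 * pi))
      side_mask <- side_mask | lm
    }
    # drooping tissue below the pot rim; grows with stress
    droop_len <- 6 + runif(1, 0, 8) + (1 - droop_turgor) * 90
    lm <- ellipse_mask(sz, sz, round(sz * 0.33) + sample(-6:6, 1),
                       rim + droop_len / 2 + 2,
                       droop_len / 2 + 2, 3.2 + runif(1, 0, 1.5), pi / 2.2)
    lm[seq_len(rim), ] <- FALSE
    side_mask <- side_mask | lm
    hue <- g$hue_center + if (stressed_now) stress$hue_shift else 0
    sch <- paint(sch, side_mask, hsv255(hue, 0.6, 0.47), 4)
    rgb_side <- array(c(sch[[1]], sch[[2]], sch[[3]]), dim = c(sz, sz, 3))

    list(
      rgb_top = rgb_top, rgb_side = rgb_side, nir_top = nir,
      truth = list(
        mask_top = plant_mask, mask_side = side_mask,
        nir_region = nir_region, flower_mask = flower_mask_truth,
        flower_centers = flowers[, 1:2, drop = FALSE],
        flower_count = nrow(flowers),
        flower_branch = if (nrow(flowers) > 0) flowers[, 3] else integer(),
        branch_count = g$branches_k,
        flowering = flowering,
        flowering_onset_das = g$flowering_onset_das,
        stressed = stressed_now,
        rim_row = rim,
        registration = camera_registration(s, s, ox, oy)
      )
    )
  })
}

#' Generate a synthetic phenotyping cohort on disk
#'
#' Draws `n_genotypes` genotype recipes, grows `reps_per_treatment`
#' replicates under each of the control and drought regimes across the
#' imaging schedule, renders every plant-day (top RGB, side RGB, top NIR),
#' and writes the dataset in the pipeline's input layout: 8-bit PNG images,
#' a `metadata.csv` sidecar (including simulated pot weights before and
#' after watering), a `truth.csv` ground-truth table, and a
#' `registration.yaml` with the true camera registration. All randomness
#' descends from `seed` through per-plant-day subseeds, so any plant-day
#' can be re-rendered independently.
#'
#' @param n_genotypes Number of genotypes.
#' @param reps_per_treatment Replicates per genotype per watering regime.
#' @param schedule Integer vector of imaging days (DAS).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param geometry A [synth_geometry()].
#' @param stress A [stress_params()] applied to the drought group.
#' @return Invisibly, a list with `dir`, `metadata` and `truth` data
#'   frames.
#' @export
generate_cohort <- function(n_genotypes = 10, reps_per_treatment = 3,
                            schedule = seq(37, 55, by = 2), seed = 1,
                            out_dir = tempfile("cohort"),
                            geometry = synth_geometry(),
                            stress = stress_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genotypes <- sample_genotypes(n_genotypes, seed)
  plants <- expand.grid(rep = seq_len(reps_per_treatment),
                        treatment = c("control", "drought"),
                        genotype = seq_len(n_genotypes),
                        stringsAsFactors = FALSE)
  plants$plant_id <- sprintf("G%02d_%s%d", plants$genotype,
                             ifelse(plants$treatment == "control", "C", "D"),
                             plants$rep)
  n_pd <- nrow(plants) * length(schedule)
  subseeds <- with_seed(seed, matrix(sample.int(.Machine$integer.max, n_pd),
                                     nrow(plants), length(schedule)))
  md <- list(); truth <- list()
  for (p in seq_len(nrow(plants))) {
    gt <- genotypes[[plants$genotype[p]]]
    # per-plant onset jitter keeps replicates from flowering in lockstep
    gt$flowering_onset_das <- gt$flowering_onset_das +
      with_seed(subseeds[p, 1] %/% 7L + p, sample(0:2, 1))
    st <- if (plants$treatment[p] == "drought") stress else NULL
    for (d in seq_along(schedule)) {
      das <- schedule[d]
      out <- render_plant(gt, das, stress = st, seed = subseeds[p, d],
                          geometry = geometry)
      base <- sprintf("%s_das%02d", plants$plant_id[p], das)
      f_top <- paste0(base, "_top_rgb.png")
      f_side <- paste0(base, "_side_rgb.png")
      f_nir <- paste0(base, "_top_nir.png")
      png::writePNG(round(out$rgb_top) / 255, file.path(out_dir, f_top))
      png::writePNG(round(out$rgb_side) / 255, file.path(out_dir, f_side))
      png::writePNG(round(out$nir_top) / 255, file.path(out_dir, f_nir))
      w <- with_seed(subseeds[p, d] %/% 3L + 11L, {
        size_proxy <- sum(out$truth$mask_top)
        before <- (if (plants$treatment[p] == "control") 900 else 640) +
          0.05 * size_proxy + rnorm(1, 0, 15)
        c(before = before,
          after = before +
            (if (plants$treatment[p] == "control") 250 else 80) +
            rnorm(1, 0, 10))
      })
      row <- data.frame(plant_id = plants$plant_id[p],
                        genotype = sprintf("G%02d", plants$genotype[p]),
                        das = das, treatment = plants$treatment[p],
                        weight_before = round(w[["before"]], 1),
                        weight_after = round(w[["after"]], 1))
      md[[length(md) + 1]] <-
        rbind(cbind(row, view = "top", modality = "RGB", path = f_top),
              cbind(row, view = "side", modality = "RGB", path = f_side),
              cbind(row, view = "top", modality = "NIR", path = f_nir))
      truth[[length(truth) + 1]] <- data.frame(
        plant_id = plants$plant_id[p], genotype = row$genotype, das = das,
        treatment = plants$treatment[p],
        stressed = as.integer(out$truth$stressed),
        branch_count = out$truth$branch_count,
        flower_count = out$truth$flower_count,
        flowering_onset_das = gt$flowering_onset_das,
        pixels_top = sum(out$truth$mask_top),
        pixels_side = sum(out$truth$mask_side),
        nir_pixels = sum(out$truth$nir_region))
    }
  }
  metadata <- do.call(rbind, md)
  metadata <- metadata[, c("plant_id", "genotype", "das", "treatment",
                           "view", "modality", "path", "weight_before",
                           "weight_after")]
  truth <- do.call(rbind, truth)
  write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(scale_x = geometry$nir_scale,
                        scale_y = geometry$nir_scale,
                        offset_x = geometry$nir_offset[["x"]],
                        offset_y = geometry$nir_offset[["y"]]),
                   file.path(out_dir, "registration.yaml"))
  invisible(list(dir = out_dir, metadata = metadata, truth = truth))
}

# Draw genotype recipes from fixed ranges; deterministic in the seed.
sample_genotypes <- function(n, seed) {
  with_seed(seed, lapply(seq_len(n), function(i) {
    genotype_params(
      n_leaves = sample(8:13, 1),
      leaf_length_px = runif(1, 38, 58),
      leaf_aspect = runif(1, 0.35, 0.55),
      hue_center = runif(1, 105, 135),
      hue_jitter = 8,
      growth_rate = runif(1, 0.05, 0.09),
      flowering_onset_das = sample(c(39:53, Inf), 1,
                                   prob = c(rep(1, 15), 2) / 17),
      branches_k = sample(1:6, 1),
      flowers_per_branch_per_day = 4,
      flower_radius_px = 7,
      height_rate = runif(1, 2.2, 3.2)
    )
  }))
}
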