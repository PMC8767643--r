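#' Build a run configuration
#'
#' Collects every knob of the end-to-end pipeline: input paths, the
#' segmentation config, flower policy, camera registration, HOCS settings,
#' and machine-learning options. `run_config()` validates and fills
#' defaults; [read_run_config()] loads the same structure from YAML.
#'
#' @param root Dataset directory (images + `metadata.csv`).
#' @param metadata Metadata CSV path (default `root/metadata.csv`).
#' @param out_dir Output directory for CSV/JSON products.
#' @param segmentation A [segmentation_config()].
#' @param flower_policy A [flower_threshold_policy()].
#' @param registration A [camera_registration()] for the RGB-to-NIR mask
#'   transfer, or path of a YAML file with `scale_x/scale_y/offset_x/offset_y`.
#' @param flower_ref_px Pixel count of one fully opened flower.
#' @param min_component_px Flower-component size filter.
#' @param das_window RGB/NIR pairing window.
#' @param rim_row Side-view pot rim row.
#' @param hocs List: `enabled`, `das`, `radii`, `n_bins`.
#' @param ml List: `target_das`, `k`, `regression_algorithms`,
#'   `classification_algorithms`.
#' @param seed Seed used for all stochastic stages; recorded in outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(root, metadata = file.path(root, "metadata.csv"),
                       out_dir = file.path(root, "out"),
                       segmentation = default_segmentation_config(),
                       flower_policy = default_flower_policy(),
                       registration = camera_registration(),
                       flower_ref_px = 150, min_component_px = 100,
                       das_window = c(37, 59), rim_row = 118,
                       hocs = list(enabled = TRUE, das = 49,
                                   radii = seq(5, 125, by = 5), n_bins = 5),
                       ml = list(target_das = 49, k = 5,
                                 regression_algorithms = c("linear", "huber"),
                                 classification_algorithms =
                                   c("random_forest", "lda", "logistic",
                                     "knn", "decision_tree", "svm")),
                       seed = 1) {
  if (!dir.exists(root)) stop("run config: root directory not found: ", root)
  if (!file.exists(metadata))
    stop("run config: metadata file not found: ", metadata)
  if (is.character(registration)) {
    if (!file.exists(registration))
      stop("run config: registration file not found: ", registration)
    y <- yaml::read_yaml(registration)
    registration <- camera_registration(y$scale_x, y$scale_y,
                                        y$offset_x, y$offset_y)
  }
  stopifnot(inherits(segmentation, "segmentation_config"),
            inherits(flower_policy, "flower_threshold_policy"),
            inherits(registration, "camera_registration"))
  structure(list(root = root, metadata = metadata, out_dir = out_dir,
                 segmentation = segmentation, flower_policy = flower_policy,
                 registration = registration, flower_ref_px = flower_ref_px,
                 min_component_px = min_component_px,
                 das_window = das_window, rim_row = rim_row,
                 hocs = hocs, ml = ml, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML run-configuration file; relative paths resolve against
#'   the file's directory.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || grepl("^/", p)) p
  else file.path(base, p)
  args <- list(root = resolve(y$root))
  if (!is.null(y$metadata)) args$metadata <- resolve(y$metadata)
  if (!is.null(y$out_dir)) args$out_dir <- resolve(y$out_dir)
  if (!is.null(y$segmentation))
    args$segmentation <- read_segmentation_config(resolve(y$segmentation))
  if (!is.null(y$flower_policy))
    args$flower_policy <- read_flower_policy(resolve(y$flower_policy))
  if (!is.null(y$registration)) args$registration <- resolve(y$registration)
  for (f in c("flower_ref_px", "min_component_px", "das_window", "rim_row",
              "hocs", "ml", "seed"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  do.call(run_config, args)
}

#' Run the full phenotyping pipeline
#'
#' Executes the stages in dependency order: index the dataset, segment
#' every RGB image, extract holistic traits (with per-trait per-day outlier
#' flagging and day-to-day deltas), transfer top-view masks to paired NIR
#' frames and summarize intensities, detect flowers and derive phenology
#' and canopy metrics, compute boundary-shape (HOCS) descriptors on the
#' configured day, and - when the dataset carries ground-truth labels
#' (`truth.csv` with `branch_count` and `stressed`) - run the
#' cross-validated branch regression and stress classification. All
#' products are written as plain CSV/JSON under `config$out_dir` together
#' with a run manifest (config hash, seed, stage tallies). Identical config
#' and seed give identical outputs.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list of the output tables and CV reports.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  obs <- index_dataset(config$root, config$metadata)
  failures <- attr(obs, "failures")
  say("indexed ", length(obs), " observations (",
      nrow(failures), " rows failed)")

  key_of <- function(o) paste(o$plant_id, o$das, sep = "@")
  nir_obs <- Filter(function(o) o$modality == "NIR" && o$view == "top", obs)
  nir_by_key <- setNames(nir_obs, vapply(nir_obs, key_of, ""))

  trait_rows <- list(); nir_rows <- list(); flower_rows <- list()
  hocs_rows <- list(); components_by_key <- list()
  rgb_obs <- Filter(function(o) o$modality == "RGB", obs)
  ord <- order(vapply(rgb_obs, function(o) o$plant_id, ""),
               vapply(rgb_obs, function(o) o$das, 1L),
               vapply(rgb_obs, function(o) o$view, ""))
  for (o in rgb_obs[ord]) {
    raster <- tryCatch(obs_raster(o), error = function(e) {
      stop("segmentation stage failed for ", key_of(o), " (", o$view,
           "): ", conditionMessage(e))
    })
    mask <- segment_plant(raster, config$segmentation)
    tr <- extract_holistic(mask, view = o$view,
                           rim_row = if (o$view == "side")
                             config$rim_row else NULL)
    exg <- excess_green(raster, mask)
    trait_rows[[length(trait_rows) + 1]] <- data.frame(
      plant_id = o$plant_id, genotype = o$genotype, das = o$das,
      treatment = o$treatment, view = o$view,
      pixels = tr$pixels, hull_area = tr$hull_area, height = tr$height,
      width = tr$width, area_below_rim = tr$area_below_rim,
      exg_mean = as.numeric(exg), empty = tr$empty,
      weight_before = o$weight_before, weight_after = o$weight_after)

    if (o$view == "top") {
      # flowers
      fm <- flower_mask(raster, mask, config$flower_policy, o$das,
                        o$treatment)
      comps <- extract_components(fm, config$min_component_px)
      components_by_key[[key_of(o)]] <- comps
      flower_rows[[length(flower_rows) + 1]] <- data.frame(
        plant_id = o$plant_id, das = o$das, treatment = o$treatment,
        flower_pixels = sum(fm), n_components = nrow(comps),
        est_flowers = estimate_flower_count(comps, config$flower_ref_px))
      # NIR partner
      partner <- nir_by_key[[key_of(o)]]
      if (!is.null(partner) && o$das >= config$das_window[1] &&
          o$das <= config$das_window[2]) {
        nir_raster <- obs_raster(partner)
        tmask <- transfer_mask(mask, config$registration, dim(nir_raster))
        sm <- summarize_nir(nir_raster, tmask)
        nir_rows[[length(nir_rows) + 1]] <- data.frame(
          plant_id = o$plant_id, das = o$das, nir_mean = sm$mean,
          nir_p75 = sm$p75, nir_mask_px = sum(tmask))
      }
      # HOCS on the configured day
      if (isTRUE(config$hocs$enabled) && o$das == config$hocs$das &&
          any(mask)) {
        desc <- hocs_descriptor(mask, radii = config$hocs$radii,
                                n_bins = config$hocs$n_bins)
        hocs_rows[[length(hocs_rows) + 1]] <-
          cbind(data.frame(plant_id = o$plant_id, das = o$das),
                as.data.frame(t(hocs_features(desc))))
      }
    }
  }
  traits <- do.call(rbind, trait_rows)
  nir <- if (length(nir_rows) > 0) do.call(rbind, nir_rows) else NULL
  flowers <- do.call(rbind, flower_rows)
  hocs_tab <- if (length(hocs_rows) > 0) do.call(rbind, hocs_rows) else NULL
  say("segmented ", nrow(traits), " images; ",
      if (is.null(nir)) 0 else nrow(nir), " NIR pairs; ",
      if (is.null(hocs_tab)) 0 else nrow(hocs_tab), " HOCS descriptors")

  # outlier flagging per trait/view/day
  traits$outlier <- FALSE
  for (v in unique(traits$view)) for (d in unique(traits$das)) {
    sel <- which(traits$view == v & traits$das == d)
    if (length(sel) < 2) next
    for (col in c("pixels", "hull_area", "height", "width")) {
      rem <- remove_outliers(traits[[col]][sel])$removed
      traits$outlier[sel[rem]] <- TRUE
    }
  }

  # wide per-plant-day table with deltas and derived traits
  wide <- build_wide_traits(traits, nir, flowers, config)
  anth <- anthesis_table(flowers)

  # persist
  out <- config$out_dir
  write.csv(traits, file.path(out, "traits.csv"), row.names = FALSE)
  write.csv(flowers, file.path(out, "flowers.csv"), row.names = FALSE)
  if (!is.null(nir)) write.csv(nir, file.path(out, "nir.csv"),
                               row.names = FALSE)
  if (!is.null(hocs_tab)) write.csv(hocs_tab, file.path(out, "hocs.csv"),
                                    row.names = FALSE)
  write.csv(wide, file.path(out, "plantday_features.csv"), row.names = FALSE)
  write.csv(anth, file.path(out, "anthesis.csv"), row.names = FALSE)

  # machine learning (only when ground-truth labels ship with the dataset)
  ml_reports <- NULL
  truth_path <- file.path(config$root, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- read.csv(truth_path, stringsAsFactors = FALSE)
    ml_reports <- run_ml_stage(wide, flowers, anth, truth, config, say)
    jsonlite::write_json(ml_reports_to_list(ml_reports),
                         file.path(out, "ml_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenotyper")),
    seed = config$seed,
    config_hash = config_hash(config),
    n_observations = length(obs), n_failed_rows = nrow(failures),
    n_trait_rows = nrow(traits),
    n_outlier_flagged = sum(traits$outlier),
    n_nir_pairs = if (is.null(nir)) 0L else nrow(nir),
    n_hocs = if (is.null(hocs_tab)) 0L else nrow(hocs_tab))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(traits = traits, flowers = flowers, nir = nir,
                 hocs = hocs_tab, wide = wide, anthesis = anth,
                 ml = ml_reports, manifest = manifest))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config[setdiff(names(config), c("root", "metadata", "out_dir"))],
          f, compress = FALSE)
  unname(tools::md5sum(f))
}

# Pivot per-view traits into one row per plant-day and attach deltas,
# biovolume, NIR summaries and flower outputs.
build_wide_traits <- function(traits, nir, flowers, config) {
  top <- traits[traits$view == "top", ]
  side <- traits[traits$view == "side", ]
  wide <- merge(
    setNames(top[, c("plant_id", "genotype", "das", "treatment", "pixels",
                     "hull_area", "exg_mean", "weight_before",
                     "weight_after")],
             c("plant_id", "genotype", "das", "treatment", "pixels_tv",
               "hull_tv", "exg", "weight_before", "weight_after")),
    setNames(side[, c("plant_id", "das", "pixels", "hull_area", "height",
                      "width", "area_below_rim")],
             c("plant_id", "das", "pixels_sv", "hull_sv", "height",
               "width", "area_below_rim")),
    by = c("plant_id", "das"), all = TRUE)
  if (!is.null(nir)) {
    wide <- merge(wide, nir[, c("plant_id", "das", "nir_mean", "nir_p75")],
                  by = c("plant_id", "das"), all.x = TRUE)
  } else {
    wide$nir_mean <- NA_real_; wide$nir_p75 <- NA_real_
  }
  wide <- merge(wide,
                flowers[, c("plant_id", "das", "flower_pixels",
                            "n_components", "est_flowers")],
                by = c("plant_id", "das"), all.x = TRUE)
  wide$biovolume <- ifelse(is.na(wide$pixels_sv) | is.na(wide$pixels_tv),
                           NA_real_,
                           biovolume(wide$pixels_sv, wide$pixels_tv))
  wide <- wide[order(wide$plant_id, wide$das), ]
  for (col in c("pixels_tv", "hull_tv", "pixels_sv", "hull_sv", "height",
                "width")) {
    dname <- paste0("d_", sub("_area", "", col))
    wide[[dname]] <- NA_real_
    for (pid in unique(wide$plant_id)) {
      sel <- which(wide$plant_id == pid & !is.na(wide[[col]]))
      if (length(sel) < 2) next
      dd <- day_deltas(wide$das[sel], wide[[col]][sel])
      wide[[dname]][sel[match(dd$das, wide$das[sel])]] <- dd$delta
    }
  }
  rownames(wide) <- NULL
  wide
}

anthesis_table <- function(flowers) {
  ids <- unique(flowers$plant_id)
  data.frame(
    plant_id = ids,
    anthesis_das = vapply(ids, function(pid) {
      sel <- flowers$plant_id == pid
      detect_anthesis(flowers$das[sel], flowers$n_components[sel])
    }, integer(1)))
}

run_ml_stage <- function(wide, flowers, anth, truth, config, say) {
  reports <- list()
  # raceme-branch regression on flowering plant-days
  if ("branch_count" %in% names(truth)) {
    br <- merge(flowers,
                truth[, c("plant_id", "das", "branch_count")],
                by = c("plant_id", "das"))
    br <- br[br$n_components > 0, , drop = FALSE]
    if (nrow(br) >= config$ml$k) {
      tab <- assemble_branch_features(br)
      for (alg in config$ml$regression_algorithms) {
        reports[[paste0("branches_", alg)]] <-
          cv_regression(tab, alg, k = config$ml$k, seed = config$seed)
      }
      say("branch regression on ", nrow(tab), " flowering plant-days")
    }
  }
  # drought-stress classification on the target day
  if ("stressed" %in% names(truth)) {
    target <- config$ml$target_das
    stress_df <- merge(wide, truth[, c("plant_id", "das", "stressed",
                                       "branch_count")],
                       by = c("plant_id", "das"))
    stress_df <- merge(stress_df, anth, by = "plant_id", all.x = TRUE)
    stress_df$flowering_group <- flowering_group(stress_df$anthesis_das)
    stress_df$branches <- stress_df$branch_count
    stress_df$stress <- stress_df$stressed
    tab <- assemble_stress_features(stress_df, das = target)
    if (length(unique(tab$label)) == 2) {
      tab <- downsample_balance(tab, seed = config$seed)
      for (alg in config$ml$classification_algorithms) {
        reports[[paste0("stress_", alg)]] <-
          cv_classification(tab, alg, k = config$ml$k, seed = config$seed)
      }
      say("stress classification on ", nrow(tab),
          " balanced day-", target, " observations (",
          attr(tab, "n_dropped") %||% 0, " rows dropped)")
    }
  }
  reports
}

ml_reports_to_list <- function(reports) {
  lapply(reports, function(r) {
    r[c("algorithm", "metric", "per_fold", "mean", "sd", "n_total",
        "n_train", "n_test", "seed",
        intersect(c("accuracy_mean", "accuracy_sd"), names(r)))]
  })
}
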