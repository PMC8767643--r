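#' @title Dataset indexing and RGB/NIR pairing
#' @name dataset_io
#' @description Index a directory of per-plant, per-day images against a CSV
#'   metadata sidecar, validate it, and pair RGB and NIR top-view
#'   observations for mask transfer.
NULL

METADATA_REQUIRED <- c("plant_id", "genotype", "das", "treatment", "view",
                       "modality", "path")
METADATA_OPTIONAL <- c("weight_before", "weight_after")

#' Read and validate a metadata CSV
#'
#' The metadata sidecar is authoritative: one row per image with columns
#' `plant_id, genotype, das, treatment, view, modality, path` and optional
#' `weight_before, weight_after` (grams; pot weight before/after watering).
#' `treatment` is `control`/`drought`, `view` is `top`/`side`, `modality` is
#' `RGB`/`NIR`, `das` (days after seeding) is a positive integer.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  missing_cols <- setdiff(METADATA_REQUIRED, names(md))
  if (length(missing_cols) > 0)
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  for (col in METADATA_OPTIONAL) if (!col %in% names(md)) md[[col]] <- NA_real_
  md$das <- as.integer(md$das)
  if (anyNA(md$das) || any(md$das < 1))
    stop("metadata column 'das' must be integer >= 1")
  check_enum <- function(col, allowed) {
    bad <- setdiff(unique(md[[col]]), allowed)
    if (length(bad) > 0)
      stop("metadata column '", col, "' has invalid value(s): ",
           paste(bad, collapse = ", "))
  }
  check_enum("treatment", c("control", "drought"))
  check_enum("view", c("top", "side"))
  check_enum("modality", c("RGB", "NIR"))
  key <- paste(md$plant_id, md$das, md$view, md$modality, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (plant_id, das, view, modality) metadata rows: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = "; "))
  md
}

#' Index an image dataset
#'
#' Builds one observation per metadata row. Rasters are loaded lazily via
#' [obs_raster()]; rows whose image file is missing are excluded and reported
#' in the `failures` attribute instead of aborting the run.
#'
#' @param root Directory that image `path`s are relative to.
#' @param metadata A metadata data frame or the path of a metadata CSV
#'   (see [read_metadata()]).
#' @return An object of class `plant_observation_set`: a list of
#'   `plant_observation` records (fields `plant_id`, `genotype`, `das`,
#'   `treatment`, `view`, `modality`, `file`, `weight_before`,
#'   `weight_after`), with attribute `failures` (data frame of skipped rows).
#' @export
index_dataset <- function(root, metadata) {
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- read_metadata(metadata)
  else metadata <- validate_metadata(metadata)
  files <- file.path(root, metadata$path)
  ok <- file.exists(files)
  obs <- lapply(which(ok), function(i) {
    structure(list(
      plant_id = metadata$plant_id[i], genotype = metadata$genotype[i],
      das = metadata$das[i], treatment = metadata$treatment[i],
      view = metadata$view[i], modality = metadata$modality[i],
      file = files[i],
      weight_before = as.numeric(metadata$weight_before[i]),
      weight_after = as.numeric(metadata$weight_after[i])
    ), class = "plant_observation")
  })
  failures <- metadata[!ok, , drop = FALSE]
  if (nrow(failures) > 0)
    failures$reason <- "image file not found"
  structure(obs, class = "plant_observation_set", failures = failures)
}

#' @export
print.plant_observation_set <- function(x, ...) {
  cat("<plant_observation_set> ", length(x), " observations, ",
      nrow(attr(x, "failures")), " failed rows\n", sep = "")
  invisible(x)
}

#' Load the raster of an observation
#'
#' Reads the PNG or TIFF image behind an observation. RGB observations load
#' as an `rows x cols x 3` array, NIR observations as a matrix; pixel values
#' are rescaled to 0-255.
#'
#' @param obs A `plant_observation`.
#' @return Numeric array (RGB) or matrix (NIR), values in \[0, 255\].
#' @export
obs_raster <- function(obs) {
  stopifnot(inherits(obs, "plant_observation"))
  ext <- tolower(tools::file_ext(obs$file))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(obs$file)
  } else {
    png::readPNG(obs$file)
  }
  img <- img * 255
  if (obs$modality == "RGB") {
    if (length(dim(img)) != 3 || dim(img)[3] < 3)
      stop("RGB observation ", obs$file, " does not have 3 channels")
    img[, , 1:3, drop = FALSE]
  } else {
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
}

#' Pair RGB and NIR top-view observations
#'
#' Matches RGB top-view with NIR top-view observations of the same plant on
#' the same imaging day, restricted to a DAS window (default 37-59, the span
#' over which the two cameras' fields of view overlap usefully). The result
#' is deterministic: pairs are sorted by plant and day regardless of input
#' order.
#'
#' @param observations A `plant_observation_set` or list of observations.
#' @param das_window Length-2 integer vector `c(min, max)`, inclusive.
#' @return A list with `pairs` (list of `list(rgb =, nir =)` observation
#'   pairs) and `n_unpaired` (count of top-view observations in the window
#'   lacking a partner).
#' @export
pair_rgb_nir <- function(observations, das_window = c(37, 59)) {
  stopifnot(length(das_window) == 2, das_window[1] <= das_window[2])
  tops <- Filter(function(o) o$view == "top" &&
                   o$das >= das_window[1] && o$das <= das_window[2],
                 observations)
  key <- vapply(tops, function(o) paste(o$plant_id, o$das, sep = "\r"), "")
  mod <- vapply(tops, function(o) o$modality, "")
  rgb_i <- which(mod == "RGB"); nir_i <- which(mod == "NIR")
  m <- match(key[rgb_i], key[nir_i])
  paired <- which(!is.na(m))
  ord <- order(key[rgb_i][paired])
  pairs <- lapply(paired[ord], function(j) {
    list(rgb = tops[[rgb_i[j]]], nir = tops[[nir_i[m[j]]]])
  })
  n_unpaired <- (length(rgb_i) - length(paired)) +
    (length(nir_i) - length(paired))
  list(pairs = pairs, n_unpaired = n_unpaired)
}

#' Define an experiment schedule
#'
#' @param imaging_days Strictly increasing integer DAS values on which
#'   imaging took place.
#' @param treatment_window Length-2 vector: first and last DAS of the
#'   differential-watering phase; must lie within the imaging span.
#' @param treatment_map Named character vector `plant_id -> treatment`.
#' @return An `experiment_schedule` list.
#' @export
experiment_schedule <- function(imaging_days,
                                treatment_window = range(imaging_days),
                                treatment_map = character()) {
  imaging_days <- as.integer(imaging_days)
  if (any(diff(imaging_days) <= 0))
    stop("imaging_days must be strictly increasing")
  if (treatment_window[1] < min(imaging_days) ||
      treatment_window[2] > max(imaging_days))
    stop("treatment window must lie within the imaging span")
  structure(list(imaging_days = imaging_days,
                 treatment_window = as.integer(treatment_window),
                 treatment_map = treatment_map),
            class = "experiment_schedule")
}
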