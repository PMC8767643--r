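#' Flower thresholding policy on the CIELAB blue-yellow channel
#'
#' Flowers are detected as high blue-yellow (b) pixels inside the plant
#' mask; because canopy greenness and flower colour drift with plant age and
#' watering, the b threshold is rule-based: the first rule matching the
#' observation's DAS and treatment wins. `treatment = "any"` matches both
#' groups.
#'
#' @param rules Data frame with columns `das_min`, `das_max`, `treatment`
#'   (`"control"`, `"drought"` or `"any"`) and `b_low`.
#' @return A `flower_threshold_policy`.
#' @export
flower_threshold_policy <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("das_min", "das_max", "treatment", "b_low") %in%
                  names(rules)),
            all(rules$das_min <= rules$das_max),
            all(rules$treatment %in% c("control", "drought", "any")))
  structure(list(rules = rules), class = "flower_threshold_policy")
}

#' @rdname flower_threshold_policy
#' @details `default_flower_policy()` ships a single all-ages rule at
#'   `b_low = 55`, calibrated on the synthetic generator where leaf tissue
#'   sits below b = 40 and open flowers above b = 65.
#' @export
default_flower_policy <- function(b_low = 55) {
  flower_threshold_policy(data.frame(
    das_min = 1, das_max = 1000, treatment = "any", b_low = b_low))
}

#' Read a flower threshold policy from YAML
#'
#' @param path YAML file with a `rules:` list of
#'   `{das_min, das_max, treatment, b_low}` entries.
#' @return A `flower_threshold_policy`.
#' @export
read_flower_policy <- function(path) {
  y <- yaml::read_yaml(path)
  flower_threshold_policy(do.call(rbind, lapply(y$rules, as.data.frame)))
}

#' Detect flower pixels inside the plant mask
#'
#' Thresholds the CIELAB blue-yellow channel of the top-view RGB image at
#' the policy rule matching the plant's age and treatment, and intersects
#' with the plant mask, so flower pixels are always a subset of plant
#' pixels.
#'
#' @param rgb_top `rows x cols x 3` RGB array, 0-255.
#' @param plant_mask Logical plant mask from segmentation.
#' @param policy A [flower_threshold_policy()].
#' @param das Days after seeding of the observation.
#' @param treatment `"control"` or `"drought"`.
#' @return Logical flower mask.
#' @export
flower_mask <- function(rgb_top, plant_mask, policy = default_flower_policy(),
                        das, treatment = "control") {
  stopifnot(inherits(policy, "flower_threshold_policy"))
  r <- policy$rules
  hit <- which(das >= r$das_min & das <= r$das_max &
                 (r$treatment == "any" | r$treatment == treatment))
  if (length(hit) == 0)
    stop("no flower-threshold rule matches das = ", das,
         ", treatment = ", treatment)
  b <- convert_colorspace(rgb_top, "CIELAB")[, , 3]
  (b >= r$b_low[hit[1]]) & plant_mask
}

#' Extract filtered flower components
#'
#' 8-connected components of the flower mask; components with fewer than
#' `min_component_px` pixels (default 100, dropping sub-flower specks and
#' protruding bud petals) are discarded, and descriptive properties are
#' computed for the survivors. A component of exactly `min_component_px`
#' pixels is kept.
#'
#' @param flower_mask Logical flower mask.
#' @param min_component_px Minimum component size kept.
#' @return A component data frame (see [component_table()]); zero rows when
#'   nothing survives.
#' @export
extract_components <- function(flower_mask, min_component_px = 100) {
  tab <- component_table(flower_mask)
  tab[tab$pixel_count >= min_component_px, , drop = FALSE]
}

#' Call anthesis from a per-day component series
#'
#' Anthesis (first open flower) is the earliest imaging day with at least
#' one surviving flower component.
#'
#' @param das Integer vector of imaging days.
#' @param n_components Number of surviving components per day.
#' @return The anthesis DAS, or `NA` for a plant that never flowered.
#' @export
detect_anthesis <- function(das, n_components) {
  stopifnot(length(das) == length(n_components))
  o <- order(das)
  hit <- which(n_components[o] >= 1)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(das[o][hit[1]])
}

#' Estimate the number of flowers from components
#'
#' A component close to the size of one fully opened flower counts as one;
#' a large component (more than `split_factor` reference flowers) likely
#' holds several overlapping flowers and is split by dividing its pixel
#' count by the reference flower size (round half up, at least one).
#'
#' @param components Component data frame from [extract_components()].
#' @param flower_ref_px Approximate pixel count of one fully opened flower
#'   seen from the top (calibrated per image scale).
#' @param split_factor Components larger than `split_factor * flower_ref_px`
#'   are split.
#' @return Estimated total flower count (integer).
#' @export
estimate_flower_count <- function(components, flower_ref_px,
                                  split_factor = 1.5) {
  if (flower_ref_px <= 0) stop("flower_ref_px must be positive")
  if (nrow(components) == 0) return(0L)
  pc <- components$pixel_count
  n <- ifelse(pc <= split_factor * flower_ref_px, 1,
              pmax(1, round_half_up(pc / flower_ref_px)))
  as.integer(sum(n))
}

#' Canopy width and approximate canopy angle
#'
#' Canopy width is the horizontal span of all flower-component bounding
#' boxes in the top view; the canopy angle is the apex angle of the
#' isoceles triangle with that width as base and the side-view plant height:
#' `2 * atan(width / (2 * height))`, in degrees. Wide, flat inflorescences
#' give large angles; compact, tall ones give small angles.
#'
#' @param components Component data frame.
#' @param plant_height_px Side-view plant height, px (> 0).
#' @return List with `canopy_width_px` and `canopy_angle_deg`; both `NA`
#'   when there are no components.
#' @export
canopy_metrics <- function(components, plant_height_px) {
  if (nrow(components) == 0)
    return(list(canopy_width_px = NA_real_, canopy_angle_deg = NA_real_))
  stopifnot(plant_height_px > 0)
  width <- max(components$max_x) - min(components$min_x)
  angle <- 2 * atan(width / (2 * plant_height_px)) * 180 / pi
  list(canopy_width_px = width, canopy_angle_deg = angle)
}

#' Cluster flower components into raceme branches
#'
#' Agglomerative hierarchical clustering (complete linkage, Euclidean
#' distance) on the six positional features per component (min x, max x,
#' min y, max y, centroid x, centroid y), with the tree cut at `k`, the
#' number of raceme branches. Spatial flower clusters in the top view
#' approximate branches.
#'
#' @param components Component data frame with at least one row.
#' @param k Number of branches, `1 <= k <= nrow(components)`.
#' @param method Linkage passed to [stats::hclust()].
#' @return Integer branch labels in 1..k, one per component row.
#' @export
cluster_racemes <- function(components, k, method = "complete") {
  n <- nrow(components)
  if (k > n) stop("k = ", k, " exceeds the number of components (", n, ")")
  if (k < 1) stop("k must be >= 1")
  feats <- as.matrix(components[, c("min_x", "max_x", "min_y", "max_y",
                                    "centroid_x", "centroid_y")])
  if (n == 1) return(1L)
  hc <- hclust(dist(feats), method = method)
  unname(cutree(hc, k = k))
}
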