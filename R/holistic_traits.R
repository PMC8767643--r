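#' Extract holistic traits from a plant mask
#'
#' Holistic traits summarize the whole binary plant silhouette: projected
#' leaf area (pixel count), convex hull area of the pixel centres, and the
#' inclusive bounding extents (a single pixel has height = width = 1). For
#' side views, `area_below_rim` counts plant pixels below the pot rim row
#' (drooping/overhanging tissue). An empty mask yields all-zero traits with
#' `empty = TRUE` rather than an error, so sparse early time points do not
#' break a run.
#'
#' @param mask Logical plant mask.
#' @param view `"top"` or `"side"`.
#' @param rim_row For side views, the image row (1-based) of the pot rim;
#'   pixels with row greater than `rim_row` count as below the rim.
#' @return A list with `pixels`, `hull_area`, `height`, `width`,
#'   `area_below_rim` (NA for top views), and `empty`.
#' @export
extract_holistic <- function(mask, view = c("top", "side"), rim_row = NULL) {
  view <- match.arg(view)
  stopifnot(is.matrix(mask))
  idx <- which(mask)
  if (length(idx) == 0) {
    return(list(pixels = 0, hull_area = 0, height = 0, width = 0,
                area_below_rim = if (view == "side") 0 else NA_real_,
                empty = TRUE))
  }
  y <- ((idx - 1L) %% nrow(mask)) + 1L
  x <- ((idx - 1L) %/% nrow(mask)) + 1L
  abr <- if (view == "side") {
    if (is.null(rim_row)) NA_real_ else sum(y > rim_row)
  } else NA_real_
  list(pixels = length(idx),
       hull_area = hull_area_px(x, y),
       height = max(y) - min(y) + 1L,
       width = max(x) - min(x) + 1L,
       area_below_rim = abr,
       empty = FALSE)
}

#' Mean Excess Green Index over masked pixels
#'
#' The default (`variant = "paper"`) uses ExG = 2G - R + B; the canonical
#' Woebbecke index 2G - R - B is available as `variant = "canonical"`.
#' Channels are taken on the 0-255 scale. The variant used is recorded as an
#' attribute of the returned value.
#'
#' @param rgb_raster `rows x cols x 3` array, 0-255.
#' @param mask Logical mask of plant pixels.
#' @param variant `"paper"` or `"canonical"`.
#' @return Mean ExG (numeric scalar, attribute `variant`); `NA` for an
#'   empty mask.
#' @export
excess_green <- function(rgb_raster, mask, variant = c("paper", "canonical")) {
  variant <- match.arg(variant)
  d <- dim(rgb_raster)
  stopifnot(length(d) == 3, d[3] == 3, identical(as.integer(d[1:2]),
                                                as.integer(dim(mask))))
  if (!any(mask)) return(structure(NA_real_, variant = variant))
  r <- rgb_raster[, , 1][mask]
  g <- rgb_raster[, , 2][mask]
  b <- rgb_raster[, , 3][mask]
  v <- if (variant == "paper") 2 * g - r + b else 2 * g - r - b
  structure(mean(v), variant = variant)
}

#' Estimated biovolume from two projected leaf areas
#'
#' Biomass proxy combining side and top projections:
#' sqrt(side^2 * top), in px^1.5 scale.
#'
#' @param side_pixels,top_pixels Projected leaf areas (pixel counts) from
#'   the side and top views.
#' @return Numeric biovolume; monotone nondecreasing in both arguments.
#' @examples
#' biovolume(4, 9)  # 12
#' @export
biovolume <- function(side_pixels, top_pixels) {
  if (any(side_pixels < 0) || any(top_pixels < 0))
    stop("projected leaf areas must be nonnegative")
  sqrt(side_pixels^2 * top_pixels)
}

#' Day-to-day trait differences
#'
#' Delta traits track development: for each imaging day after the first,
#' the difference from the previous *available* imaging day (gaps bridge to
#' the last day that has a value).
#'
#' @param das Integer vector of imaging days.
#' @param values Numeric trait values, same length as `das`.
#' @return Data frame with columns `das` and `delta`; empty if fewer than
#'   two days.
#' @export
day_deltas <- function(das, values) {
  stopifnot(length(das) == length(values))
  o <- order(das)
  das <- das[o]; values <- values[o]
  if (anyDuplicated(das)) stop("one value per imaging day required")
  if (length(das) < 2)
    return(data.frame(das = integer(), delta = numeric()))
  data.frame(das = das[-1], delta = diff(values))
}

#' Threshold-based outlier removal for one trait on one day
#'
#' Removes values lying outside median +/- 3 standard deviations, computed
#' over that day's values for that trait (sample SD, n - 1 denominator).
#' With fewer than two finite values everything passes through.
#'
#' @param values Numeric vector (one trait, one day, across plants).
#' @return List with `kept` (values retained, original order) and `removed`
#'   (integer indices of removed values).
#' @export
remove_outliers <- function(values) {
  fin <- is.finite(values)
  if (sum(fin) < 2) return(list(kept = values, removed = integer()))
  m <- median(values[fin])
  s <- sd(values[fin])
  lo <- m - 3 * s; hi <- m + 3 * s
  removed <- which(fin & (values < lo | values > hi))
  kept <- if (length(removed) > 0) values[-removed] else values
  list(kept = kept, removed = removed)
}
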