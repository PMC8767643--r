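#' Label connected components of a binary mask
#'
#' Components are 8-connected by default (diagonal neighbours touch), the
#' convention used throughout the pipeline so that diagonal leaf tips and
#' petal edges stay attached to their plant.
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 = background, components are
#'   numbered 1..n in raster-scan order of their first pixel.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' max(label_components(m))                   # 1: diagonal pixels connect
#' max(label_components(m, connectivity = 4)) # 2
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  .cc_label_cpp(matrix(as.logical(mask), nrow(mask), ncol(mask)),
                as.integer(connectivity))
}

#' Tabulate connected components with descriptive properties
#'
#' Computes, per component, the pixel count, centroid, bounding box
#' (inclusive pixel coordinates, x = column, y = row), bounding-box area and
#' convex hull area of the pixel centres.
#'
#' @param labels Integer label matrix from [label_components()], or a logical
#'   mask (labelled internally).
#' @return A data frame with one row per component and columns `label`,
#'   `pixel_count`, `centroid_x`, `centroid_y`, `min_x`, `min_y`, `max_x`,
#'   `max_y`, `bbox_area`, `hull_area`.
#' @export
component_table <- function(labels) {
  if (is.logical(labels)) labels <- label_components(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) return(empty_component_table())
  lab <- labels[idx]
  row <- ((idx - 1L) %% nrow(labels)) + 1L
  col <- ((idx - 1L) %/% nrow(labels)) + 1L
  ids <- sort(unique(lab))
  out <- lapply(ids, function(id) {
    sel <- lab == id
    x <- col[sel]; y <- row[sel]
    data.frame(
      label = id, pixel_count = sum(sel),
      centroid_x = mean(x), centroid_y = mean(y),
      min_x = min(x), min_y = min(y), max_x = max(x), max_y = max(y),
      bbox_area = (max(x) - min(x) + 1) * (max(y) - min(y) + 1),
      hull_area = hull_area_px(x, y)
    )
  })
  do.call(rbind, out)
}

empty_component_table <- function() {
  data.frame(label = integer(), pixel_count = integer(),
             centroid_x = numeric(), centroid_y = numeric(),
             min_x = integer(), min_y = integer(),
             max_x = integer(), max_y = integer(),
             bbox_area = numeric(), hull_area = numeric())
}

#' Convex hull area of a pixel set
#'
#' Area of the convex hull of the pixel centres, by the shoelace formula on
#' the hull returned by [grDevices::chull()]. Degenerate sets (a single
#' pixel, collinear pixels) have area 0.
#'
#' @param x,y Pixel coordinates (columns and rows).
#' @return Hull area in px^2.
#' @export
hull_area_px <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  h <- chull(pts[, 1], pts[, 2])
  hx <- pts[h, 1]; hy <- pts[h, 2]
  n <- length(h)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}
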