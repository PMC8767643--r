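#' Camera registration between the RGB and NIR frames
#'
#' The two overhead cameras differ in field of view; a scale-plus-offset
#' affine map (no rotation, both cameras are fixed overhead) takes RGB
#' coordinates to NIR coordinates: `nir = rgb * scale + offset`, per axis.
#'
#' @param scale_x,scale_y Positive scale ratios (NIR px per RGB px).
#' @param offset_x,offset_y Offsets in the NIR frame, px.
#' @return A `camera_registration` list.
#' @export
camera_registration <- function(scale_x = 1, scale_y = 1,
                                offset_x = 0, offset_y = 0) {
  stopifnot(scale_x > 0, scale_y > 0)
  structure(list(scale_x = scale_x, scale_y = scale_y,
                 offset_x = offset_x, offset_y = offset_y),
            class = "camera_registration")
}

#' Transfer an RGB plant mask into the NIR frame
#'
#' Resamples the mask with nearest-neighbour lookup under the registration
#' map: each NIR pixel takes the mask value of the nearest RGB pixel, with
#' positions outside the RGB frame treated as background. An all-background
#' result is flagged (`attr(, "empty")`), signalling that downstream NIR
#' summaries should be missing.
#'
#' @param rgb_mask Logical mask in the RGB frame.
#' @param registration A [camera_registration()].
#' @param nir_shape `c(rows, cols)` of the NIR image.
#' @return Logical mask of shape `nir_shape`.
#' @export
transfer_mask <- function(rgb_mask, registration, nir_shape) {
  stopifnot(inherits(registration, "camera_registration"),
            length(nir_shape) == 2)
  nr <- nir_shape[1]; nc <- nir_shape[2]
  src_row <- round((seq_len(nr) - registration$offset_y) / registration$scale_y)
  src_col <- round((seq_len(nc) - registration$offset_x) / registration$scale_x)
  row_ok <- src_row >= 1 & src_row <= nrow(rgb_mask)
  col_ok <- src_col >= 1 & src_col <= ncol(rgb_mask)
  out <- matrix(FALSE, nr, nc)
  if (any(row_ok) && any(col_ok)) {
    out[row_ok, col_ok] <- rgb_mask[src_row[row_ok], src_col[col_ok],
                                    drop = FALSE]
  }
  attr(out, "empty") <- !any(out)
  out
}

#' Summarize NIR intensities under a mask
#'
#' Mean and 75th percentile of the masked NIR pixel intensities; the
#' percentile uses linear interpolation between order statistics
#' ([stats::quantile()] type 7).
#'
#' @param nir_raster Numeric NIR matrix.
#' @param mask Logical mask in the NIR frame.
#' @return List with `mean` and `p75`; both `NA` when the mask is empty.
#' @examples
#' summarize_nir(matrix(c(10, 20, 30, 40), 2), matrix(TRUE, 2, 2))
#' # mean 25, p75 32.5
#' @export
summarize_nir <- function(nir_raster, mask) {
  stopifnot(identical(dim(nir_raster), dim(mask)))
  v <- nir_raster[mask]
  if (length(v) == 0) return(list(mean = NA_real_, p75 = NA_real_))
  list(mean = mean(v), p75 = unname(quantile(v, 0.75, type = 7)))
}

#' Calibrate the RGB-to-NIR registration on a bright fixture
#'
#' Grid-searches scale and offset to maximize the Jaccard overlap between
#' the transferred RGB mask and a reference NIR foreground region (e.g. a
#' bright calibration target visible to both cameras).
#'
#' @param rgb_mask Logical mask in the RGB frame.
#' @param nir_region Logical reference region in the NIR frame.
#' @param scales Candidate scale factors (applied to both axes).
#' @param offsets Candidate integer offsets (applied to both axes).
#' @return The best-scoring [camera_registration()], with attribute
#'   `jaccard`.
#' @export
calibrate_registration <- function(rgb_mask, nir_region,
                                   scales = seq(0.4, 1, by = 0.05),
                                   offsets = -10:10) {
  best <- NULL; best_j <- -1
  for (s in scales) for (ox in offsets) for (oy in offsets) {
    reg <- camera_registration(s, s, ox, oy)
    tm <- transfer_mask(rgb_mask, reg, dim(nir_region))
    j <- jaccard(tm, nir_region)
    if (!is.na(j) && j > best_j) { best_j <- j; best <- reg }
  }
  attr(best, "jaccard") <- best_j
  best
}

jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(NA_real_)
  sum(a & b) / u
}
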