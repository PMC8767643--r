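#' Convert an RGB raster to HSV or CIELAB
#'
#' HSV channels come back as H in degrees [0, 360), S and V in \[0, 1\]
#' (via [grDevices::rgb2hsv()]); CIELAB is computed under the D65/2-degree
#' reference white (via [grDevices::convertColor()]) with L in \[0, 100\] and
#' a, b roughly in \[-128, 127\].
#'
#' @param rgb_raster `rows x cols x 3` array, values 0-255.
#' @param target `"HSV"` or `"CIELAB"`.
#' @return `rows x cols x 3` array; channels H,S,V or L,a,b.
#' @examples
#' px <- array(c(0, 255, 0), dim = c(1, 1, 3))
#' convert_colorspace(px, "HSV")[1, 1, ]    # H = 120, S = 1, V = 1
#' @export
convert_colorspace <- function(rgb_raster, target = c("HSV", "CIELAB")) {
  target <- match.arg(target)
  d <- dim(rgb_raster)
  if (length(d) != 3 || d[3] != 3)
    stop("rgb_raster must be a rows x cols x 3 array")
  flat <- matrix(rgb_raster, ncol = 3)
  out <- if (target == "HSV") {
    h <- t(rgb2hsv(t(flat), maxColorValue = 255))
    h[, 1] <- h[, 1] * 360
    h[, 1][h[, 1] >= 360] <- 0
    h
  } else {
    convertColor(flat / 255, from = "sRGB", to = "Lab")
  }
  array(out, dim = d)
}

#' Threshold a scalar channel into a binary mask
#'
#' @param channel_raster Numeric matrix (one colour channel).
#' @param low,high Inclusive bounds; pixels with `low <= value <= high`
#'   become foreground.
#' @return Logical matrix of the same shape.
#' @export
threshold_channel <- function(channel_raster, low, high) {
  if (low > high) stop("threshold low must be <= high")
  stopifnot(is.matrix(channel_raster))
  channel_raster >= low & channel_raster <= high
}

#' Combine named sub-masks and clean the result
#'
#' Evaluates a boolean combine rule (an R expression over the mask names,
#' e.g. `"(hsv_s | lab_b) & hsv_v"`) pixelwise, then removes foreground
#' objects smaller than `min_object_px` and fills background holes smaller
#' than `fill_hole_px`. Components use 8-connectivity; a hole is a
#' background component not touching the image border.
#'
#' @param named_masks Named list of logical matrices, all the same shape.
#' @param combine_rule Character scalar; defaults to the OR of all masks.
#' @param min_object_px Minimum object size kept, in pixels.
#' @param fill_hole_px Holes strictly smaller than this are filled.
#' @return Logical matrix.
#' @export
combine_and_clean <- function(named_masks, combine_rule = NULL,
                              min_object_px = 0, fill_hole_px = 0) {
  stopifnot(length(named_masks) >= 1, !is.null(names(named_masks)))
  shapes <- vapply(named_masks, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1) stop("all masks must share one shape")
  if (is.null(combine_rule))
    combine_rule <- paste(names(named_masks), collapse = " | ")
  expr <- str2lang(combine_rule)
  used <- all.vars(expr)
  unknown <- setdiff(used, names(named_masks))
  if (length(unknown) > 0)
    stop("combine rule references unknown mask name(s): ",
         paste(unknown, collapse = ", "))
  mask <- eval(expr, envir = named_masks, enclos = baseenv())
  mask <- matrix(as.logical(mask), nrow(named_masks[[1]]),
                 ncol(named_masks[[1]]))
  if (min_object_px > 0 && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0])
    mask[lab > 0 & sizes[pmax(lab, 1)] < min_object_px] <- FALSE
  }
  if (fill_hole_px > 0 && any(!mask)) {
    bg <- label_components(!mask)
    border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    sizes <- tabulate(bg[bg > 0])
    hole <- bg > 0 & !(bg %in% border_labels) & sizes[pmax(bg, 1)] < fill_hole_px
    mask[hole] <- TRUE
  }
  mask
}

#' Apply a binary mask to a raster
#'
#' Background pixels are zeroed, foreground pixels kept unchanged; applying
#' a mask twice equals applying it once.
#'
#' @param raster Matrix or `rows x cols x k` array.
#' @param mask Logical matrix matching the raster's spatial shape.
#' @return Masked raster of the same shape.
#' @export
apply_mask <- function(raster, mask) {
  d <- dim(raster)
  if (!identical(as.integer(d[1:2]), as.integer(dim(mask))))
    stop("raster and mask shapes do not match")
  if (length(d) == 2) {
    raster[!mask] <- 0
  } else {
    for (k in seq_len(d[3])) {
      ch <- raster[, , k]
      ch[!mask] <- 0
      raster[, , k] <- ch
    }
  }
  raster
}

#' Build a segmentation configuration
#'
#' A configuration holds, per view, a set of named channel thresholds in HSV
#' and CIELAB space, a combine rule over the resulting sub-mask names
#' (`hsv_h`, `hsv_s`, `hsv_v`, `lab_l`, `lab_a`, `lab_b`), and cleanup
#' sizes. The shipped defaults were tuned on the synthetic generator:
#' chromatic plant tissue is caught by saturation or by the CIELAB
#' blue-yellow channel, guarded by a brightness floor.
#'
#' @param hsv Named list of `c(low, high)` per HSV channel (`h`, `s`, `v`).
#' @param lab Named list of `c(low, high)` per CIELAB channel (`l`,`a`,`b`).
#' @param combine_rule Boolean expression over sub-mask names.
#' @param min_object_px,fill_hole_px Cleanup sizes, px.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(hsv = list(), lab = list(),
                                combine_rule = NULL,
                                min_object_px = 0, fill_hole_px = 0) {
  chk <- function(x, allowed, what) {
    stopifnot(all(names(x) %in% allowed))
    for (nm in names(x)) {
      if (length(x[[nm]]) != 2 || x[[nm]][1] > x[[nm]][2])
        stop("invalid ", what, " threshold for channel '", nm,
             "': need c(low, high) with low <= high")
    }
  }
  chk(hsv, c("h", "s", "v"), "HSV")
  chk(lab, c("l", "a", "b"), "CIELAB")
  stopifnot(min_object_px >= 0, fill_hole_px >= 0)
  structure(list(hsv = hsv, lab = lab, combine_rule = combine_rule,
                 min_object_px = min_object_px, fill_hole_px = fill_hole_px),
            class = "segmentation_config")
}

#' @rdname segmentation_config
#' @export
default_segmentation_config <- function() {
  segmentation_config(
    hsv = list(s = c(0.30, 1), v = c(0.08, 1)),
    lab = list(b = c(15, 128)),
    combine_rule = "(hsv_s | lab_b) & hsv_v",
    min_object_px = 25, fill_hole_px = 64
  )
}

#' Read a segmentation configuration from YAML
#'
#' @param path YAML file mirroring the [segmentation_config()] fields.
#' @return A `segmentation_config`.
#' @export
read_segmentation_config <- function(path) {
  y <- yaml::read_yaml(path)
  segmentation_config(
    hsv = lapply(y$hsv, as.numeric),
    lab = lapply(y$lab, as.numeric),
    combine_rule = y$combine_rule,
    min_object_px = y$min_object_px %||% 0,
    fill_hole_px = y$fill_hole_px %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment a plant from an RGB image
#'
#' Runs the full workflow: colour-space conversion, per-channel thresholds,
#' combine rule, small-object removal and hole filling.
#'
#' @param rgb_raster `rows x cols x 3` array, 0-255.
#' @param config A [segmentation_config()].
#' @return Logical plant mask.
#' @export
segment_plant <- function(rgb_raster, config = default_segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  masks <- list()
  if (length(config$hsv) > 0) {
    hsv <- convert_colorspace(rgb_raster, "HSV")
    ch <- c(h = 1, s = 2, v = 3)
    for (nm in names(config$hsv))
      masks[[paste0("hsv_", nm)]] <-
        threshold_channel(hsv[, , ch[[nm]]], config$hsv[[nm]][1],
                          config$hsv[[nm]][2])
  }
  if (length(config$lab) > 0) {
    lab <- convert_colorspace(rgb_raster, "CIELAB")
    ch <- c(l = 1, a = 2, b = 3)
    for (nm in names(config$lab))
      masks[[paste0("lab_", nm)]] <-
        threshold_channel(lab[, , ch[[nm]]], config$lab[[nm]][1],
                          config$lab[[nm]][2])
  }
  combine_and_clean(masks, config$combine_rule,
                    config$min_object_px, config$fill_hole_px)
}
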