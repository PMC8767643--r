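#' Trace the boundary of a binary mask
#'
#' Boundary pixels are foreground pixels 8-adjacent to background (pixels
#' outside the frame count as background), so interior hole boundaries are
#' included. Points are ordered by contour following: chains of 8-adjacent
#' boundary pixels are walked greedily from each component's first pixel,
#' and the boundaries of multiple components are concatenated.
#'
#' @param mask Logical matrix with at least one foreground pixel.
#' @return Two-column matrix `cbind(x, y)` of boundary pixel coordinates
#'   (x = column, y = row, 1-based).
#' @export
trace_boundary <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stop("cannot trace the boundary of an empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  # interior count of 8-neighbours that are foreground
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + padded[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  is_boundary <- mask & nb < 8L
  comp <- label_components(mask)
  idx <- which(is_boundary)
  ord <- integer(0)
  remaining <- rep(TRUE, length(idx))
  names(remaining) <- idx
  pos <- cbind(row = ((idx - 1L) %% nr) + 1L, col = ((idx - 1L) %/% nr) + 1L)
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(idx)) assign(as.character(idx[i]), i, envir = lookup)
  taken <- rep(FALSE, length(idx))
  for (comp_id in sort(unique(comp[idx]))) {
    members <- which(comp[idx] == comp_id)
    while (any(!taken[members])) {
      cur <- members[which(!taken[members])[1]]
      repeat {
        taken[cur] <- TRUE
        ord <- c(ord, cur)
        r <- pos[cur, 1]; c <- pos[cur, 2]
        nxt <- NA_integer_
        for (dc in -1:1) for (dr in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- c + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          key <- as.character((c2 - 1L) * nr + r2)
          j <- mget(key, envir = lookup, ifnotfound = list(NULL))[[1]]
          if (!is.null(j) && !taken[j]) { nxt <- j; break }
        }
        if (is.na(nxt)) break
        cur <- nxt
      }
    }
  }
  cbind(x = pos[ord, 2], y = pos[ord, 1])
}

# Map of foreground counts within a disc of the given radius centred at
# every pixel, by FFT convolution with the disc indicator. Pixels outside
# the frame count as background (zero padding). Counts are integers; the
# convolution result is rounded to remove FFT noise.
disc_count_map <- function(mask, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  k <- 2L * as.integer(radius) + 1L
  off <- seq(-radius, radius)
  disc <- outer(off^2, off^2, "+") <= radius^2
  pr <- nextn(nr + k - 1L, c(2, 3, 5))
  pc <- nextn(nc + k - 1L, c(2, 3, 5))
  a <- matrix(0, pr, pc); a[1:nr, 1:nc] <- mask
  b <- matrix(0, pr, pc); b[1:k, 1:k] <- disc
  conv <- Re(fft(fft(a) * fft(b), inverse = TRUE)) / (pr * pc)
  # full convolution index (radius + i) picks the disc centred at pixel i
  round(conv[(radius + 1):(radius + nr), (radius + 1):(radius + nc)])
}

#' Normalized area integral invariant at boundary points
#'
#' The area integral invariant at a point is the fraction of the discrete
#' disc of the given radius (pixels at squared distance <= radius^2 from the
#' centre) that lies in the foreground; pixels beyond the image frame count
#' as background. It behaves like a curvature surrogate: about 0.5 on a
#' straight edge, below 0.5 at convex points, above 0.5 at concave points.
#'
#' @param mask Logical matrix.
#' @param points Two-column matrix `cbind(x, y)` of pixel coordinates
#'   (x = column, y = row), e.g. from [trace_boundary()].
#' @param radius Disc radius in px, >= 1.
#' @return Numeric vector of fractions in \[0, 1\], one per point.
#' @export
area_integral_invariant <- function(mask, points, radius) {
  stopifnot(radius >= 1)
  points <- matrix(as.integer(points), ncol = 2)
  cnt <- disc_count_map(mask, radius)
  off <- seq(-radius, radius)
  disc_size <- sum(outer(off^2, off^2, "+") <= radius^2)
  cnt[cbind(points[, 2], points[, 1])] / disc_size
}

#' Histogram-of-curvature-over-scale boundary descriptor
#'
#' For each radius (scale), the area integral invariant is evaluated at
#' every boundary point and binned into `n_bins` uniform bins on \[0, 1\]
#' (left-closed; the last bin also closes on the right); each scale's
#' histogram is normalized to sum to one, making scales comparable. The
#' default grid of 25 radii from 5 to 125 px in steps of 5 with 5 bins gives
#' a 25 x 5 descriptor. The descriptor is invariant to translation and to
#' grid-exact rotations.
#'
#' @param mask Logical plant mask with nonempty boundary.
#' @param radii Increasing vector of disc radii, px.
#' @param n_bins Number of histogram bins on \[0, 1\].
#' @return Object of class `hocs_descriptor`: list with `matrix`
#'   (`length(radii) x n_bins`, rows sum to 1), `radii`, `bin_edges`.
#' @export
hocs_descriptor <- function(mask, radii = seq(5, 125, by = 5), n_bins = 5) {
  stopifnot(n_bins >= 1, all(radii >= 1), !is.unsorted(radii))
  bnd <- trace_boundary(mask)
  edges <- seq(0, 1, length.out = n_bins + 1)
  hmat <- matrix(0, length(radii), n_bins,
                 dimnames = list(paste0("r", radii),
                                 paste0("bin", seq_len(n_bins))))
  for (i in seq_along(radii)) {
    v <- area_integral_invariant(mask, bnd, radii[i])
    bin <- pmin(floor(v * n_bins) + 1L, n_bins)
    hmat[i, ] <- tabulate(bin, nbins = n_bins) / length(bin)
  }
  structure(list(matrix = hmat, radii = radii, bin_edges = edges),
            class = "hocs_descriptor")
}

#' Flatten a HOCS descriptor to a named feature vector
#'
#' @param x A `hocs_descriptor`.
#' @return Named numeric vector `r<radius>_bin<j>` in row-major order.
#' @export
hocs_features <- function(x) {
  stopifnot(inherits(x, "hocs_descriptor"))
  m <- t(x$matrix)
  setNames(as.vector(m),
           as.vector(outer(colnames(x$matrix), rownames(x$matrix),
                           function(b, r) paste0(r, "_", b))))
}
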