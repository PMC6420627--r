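#' Otsu's threshold
#'
#' Global threshold maximising between-class variance over a 256-bin
#' histogram of the image range. Returns `NA` (with a warning) for a
#' constant image, where the criterion is undefined.
#'
#' @param image Numeric matrix of intensities.
#' @param n_bins Histogram bins.
#' @return Threshold on the intensity scale, or `NA_real_`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  rng <- range(image)
  if (!is.finite(diff(rng)) || diff(rng) == 0) {
    warning("constant image: Otsu threshold undefined")
    return(NA_real_)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(image, breaks, all.inside = TRUE),
                           n_bins))
  w <- cumsum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  m <- cumsum(h * mids)
  n <- w[n_bins]
  mt <- m[n_bins]
  w0 <- w[-n_bins]
  w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (mt - m[-n_bins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  (breaks[k + 1L])
}

# Shift a logical matrix by (dy, dx), padding with `fill`.
shift_logical <- function(m, dy, dx, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dy
  cs <- seq_len(nc) - dx
  rok <- rs >= 1 & rs <= nr
  cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

disc_offsets <- function(radius) {
  d <- seq(-radius, radius)
  g <- expand.grid(dy = d, dx = d)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

#' Binary morphological opening with a disc
#'
#' Erosion followed by dilation with a disc structuring element; removes
#' speckle smaller than the disc while preserving larger components'
#' shape.
#'
#' @param mask Logical matrix.
#' @param radius Disc radius in pixels.
#' @return Logical matrix.
#' @export
binary_opening <- function(mask, radius = 2) {
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  ero <- mask
  for (i in seq_len(nrow(off)))
    ero <- ero & shift_logical(mask, off$dy[i], off$dx[i], FALSE)
  dil <- ero
  for (i in seq_len(nrow(off)))
    dil <- dil | shift_logical(ero, off$dy[i], off$dx[i], FALSE)
  dil
}

#' Circularity shape factor
#'
#' `C = 4 * pi * A / P^2`: 1 for a perfect circle, smaller for elongated
#' or irregular shapes. Raster perimeter estimators can nudge the ratio
#' above 1 for near-circular shapes, so the value is clipped to 1.
#'
#' @param area Area(s), px^2 (or any consistent unit); must be > 0.
#' @param perimeter Perimeter(s) in matching units; must be > 0.
#' @return Circularity in `(0, 1]`, vectorised over inputs.
#' @export
#' @examples
#' circularity(pi * 20^2, 2 * pi * 20)  # 1
#' circularity(40^2, 4 * 40)            # pi / 4
circularity <- function(area, perimeter) {
  fl_check(is.numeric(area) && all(is.finite(area)) && all(area > 0),
           "area must be > 0")
  fl_check(is.numeric(perimeter) && all(is.finite(perimeter)) &&
             all(perimeter > 0), "perimeter must be > 0")
  pmin(4 * pi * area / perimeter^2, 1)
}

# Sub-pixel perimeter of one labelled component: marching-squares contour
# length of the intensity field at the segmentation level, restricted to
# a dilated neighbourhood of the component so neighbouring cells and
# background speckle contribute nothing.
component_perimeter <- function(image, labels, label, level, pad = 3L) {
  idx <- which(labels == label, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(image), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(image), max(idx[, 2]) + pad)
  sub <- image[r0:r1, c0:c1, drop = FALSE]
  inside <- labels[r0:r1, c0:c1, drop = FALSE] == label
  keep <- inside
  for (k in seq_len(pad - 1L)) {
    keep <- keep | shift_logical(keep, 1, 0) | shift_logical(keep, -1, 0) |
      shift_logical(keep, 0, 1) | shift_logical(keep, 0, -1)
  }
  lo <- level - max(1, abs(level))   # safely below the iso-level
  field <- matrix(lo, nrow(sub), ncol(sub))
  field[keep] <- sub[keep]
  cpp_contour_length(field, level)
}

#' Segment cells in a single-channel image
#'
#' The unsupervised-trigger segmentation pipeline: Otsu global threshold,
#' binary mask, morphological opening (disc), connected components,
#' then per-component area, sub-pixel perimeter, centroid and
#' circularity. Components smaller than `min_area` or touching the image
#' border (partial cells bias circularity) are discarded. A constant
#' image yields zero cells with a warning.
#'
#' @param image Numeric matrix (single-channel intensities), at least
#'   64 x 64 px.
#' @param min_area Exclusion floor on component area, px^2.
#' @param opening_radius Disc radius of the opening, px.
#' @param exclude_border Drop components touching the border.
#' @param level Optional fixed threshold; default Otsu.
#' @return Data frame with one row per cell: `label`, `area`,
#'   `perimeter`, `cx`, `cy`, `circularity`.
#' @export
segment_cells <- function(image, min_area = 200, opening_radius = 2,
                          exclude_border = TRUE, level = NULL) {
  fl_check(is.matrix(image) && is.numeric(image) &&
             nrow(image) >= 64 && ncol(image) >= 64,
           "image must be a numeric matrix of at least 64 x 64 px")
  empty <- data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), cx = numeric(), cy = numeric(),
                      circularity = numeric())
  if (is.null(level)) level <- otsu_threshold(image)
  if (is.na(level)) return(empty)
  mask <- image > level
  mask <- binary_opening(mask, opening_radius)
  labels <- cpp_label_components(mask, 8L)
  n <- attr(labels, "n_labels")
  if (n == 0) return(empty)
  props <- cpp_region_props(labels, n)
  keep <- props$area >= min_area
  if (exclude_border) keep <- keep & !props$border
  keep_labels <- which(keep)
  if (!length(keep_labels)) return(empty)
  per <- vapply(keep_labels, function(l)
    component_perimeter(image, labels, l, level), numeric(1))
  ok <- per > 0
  keep_labels <- keep_labels[ok]
  per <- per[ok]
  if (!length(keep_labels)) return(empty)
  data.frame(label = keep_labels,
             area = props$area[keep_labels],
             perimeter = per,
             cx = props$cx[keep_labels],
             cy = props$cy[keep_labels],
             circularity = circularity(props$area[keep_labels], per))
}
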