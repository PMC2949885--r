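#' Otsu threshold of a saliency map
#'
#' Picks the threshold maximizing the between-class variance of the map's
#' 256-bin histogram; the mask is 1 strictly above the threshold. When the
#' criterion has several maximizers the lowest threshold is used.
#'
#' @param saliency numeric matrix with at least two distinct values.
#' @return logical matrix of the same shape, with the chosen threshold in
#'   attribute `"threshold"`.
#' @export
otsu_threshold <- function(saliency) {
  v <- as.vector(saliency)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant saliency map: no threshold exists", call. = FALSE)
  nbins <- 256L
  centers <- seq(rng[1], rng[2], length.out = nbins)
  idx <- pmin(pmax(findInterval(v, centers + diff(centers[1:2]) / 2) + 1L,
                   1L), nbins)
  counts <- tabulate(idx, nbins)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  t_op <- centers[which.max(sigma_b)]   # which.max returns the first maximum
  mask <- matrix(v > t_op, nrow(saliency), ncol(saliency))
  attr(mask, "threshold") <- t_op
  mask
}

# Binary dilation/erosion with an exact Euclidean disc of the given radius.
binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  d <- cpp_edt(!mask)       # distance to the nearest foreground pixel
  mask | d <= radius
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  !binary_dilate(!mask, radius)
}

#' Fill holes in a binary mask
#'
#' Morphological closing (dilation then erosion) with a disc structuring
#' element; fills holes narrower than twice the radius and never removes a
#' foreground pixel.
#'
#' @param mask logical matrix.
#' @param radius disc radius in pixels (default 5 at the 800 x 600
#'   reference size).
#' @return logical matrix, pixelwise `>=` the input.
#' @export
fill_holes <- function(mask, radius = 5) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce to logical
  closed <- binary_erode(binary_dilate(mask, radius), radius)
  closed | mask  # guard: closing with a disc SE is extensive anyway
}

#' Remove small connected regions
#'
#' 8-connected labeling; components whose area is strictly below
#' `min_fraction` of the image pixels are removed (a region exactly at the
#' threshold survives).
#'
#' @param mask logical matrix.
#' @param min_fraction minimum surviving area as a fraction of `H * W`
#'   (default 0.03).
#' @return list with `mask` (cleaned logical matrix), `labels` (integer
#'   matrix, relabeled 1..K), and `ids` (surviving label ids).
#' @export
remove_small_regions <- function(mask, min_fraction = 0.03) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  lab <- cpp_label8(mask & TRUE)
  k <- max(lab)
  if (k == 0L)
    return(list(mask = mask & FALSE, labels = lab, ids = integer(0)))
  areas <- tabulate(lab[lab > 0L], k)
  keep <- which(areas >= min_fraction * length(mask))
  relab <- integer(k)
  relab[keep] <- seq_along(keep)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[lab > 0L] <- relab[lab[lab > 0L]]
  list(mask = labels > 0L, labels = labels, ids = seq_along(keep))
}

#' Initial attention windows by X-Y projection
#'
#' One rectangular window per labeled component: the span of its nonzero
#' row projection by the span of its nonzero column projection, i.e. the
#' tight bounding box. Coordinates are 1-based (row, col).
#'
#' @param labels integer label matrix (as from [remove_small_regions()]).
#' @return data.frame with columns `label`, `x` (first column), `y` (first
#'   row), `width`, `height`, ordered by label.
#' @export
initial_windows <- function(labels) {
  ids <- sort(unique(labels[labels > 0L]))
  out <- lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    data.frame(label = id,
               x = min(w[, 2]), y = min(w[, 1]),
               width = diff(range(w[, 2])) + 1L,
               height = diff(range(w[, 1])) + 1L)
  })
  if (length(out) == 0L)
    return(data.frame(label = integer(0), x = integer(0), y = integer(0),
                      width = integer(0), height = integer(0)))
  do.call(rbind, out)
}

#' Fit an elliptical attention window to a rectangular one
#'
#' Center at the window's centroid, semi-axes at half the window extents;
#' the ellipse is clipped (semi-axes reduced) so its bounding box stays
#' inside the image.
#'
#' @param window one-row data.frame as returned by [initial_windows()].
#' @param shape image `c(height, width)` used for clipping.
#' @return data.frame with `label`, `cx`, `cy` (pixel-center coordinates,
#'   1-based) and semi-axes `rx`, `ry`.
#' @export
fit_ellipse <- function(window, shape) {
  cx <- window$x + (window$width - 1) / 2
  cy <- window$y + (window$height - 1) / 2
  rx <- window$width / 2
  ry <- window$height / 2
  # clip so [cx - rx, cx + rx] stays within the pixel span [0.5, W + 0.5]
  rx <- min(rx, cx - 0.5, shape[2] + 0.5 - cx)
  ry <- min(ry, cy - 0.5, shape[1] + 0.5 - cy)
  data.frame(label = window$label, cx = cx, cy = cy,
             rx = max(rx, 0.5), ry = max(ry, 0.5))
}

# Rasterize the union of open ellipse interiors as a logical matrix.
rasterize_ellipses <- function(eaws, shape) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (nrow(eaws) == 0L) return(mask)
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(eaws))) {
    e <- eaws[k, ]
    mask <- mask |
      (((cols - e$cx) / e$rx)^2 + ((rows - e$cy) / e$ry)^2 < 1)
  }
  mask
}

#' Distance-transform strength of the elliptical attention windows
#'
#' Exact Euclidean distance from every pixel inside the union of ellipse
#' interiors to the nearest pixel outside it (zero outside), min-max
#' normalized to `[0, 255]`. The strength therefore peaks at each window's
#' center and falls to zero at its boundary.
#'
#' @param eaws data.frame of ellipses (`cx`, `cy`, `rx`, `ry`).
#' @param shape output `c(height, width)`.
#' @param normalize rescale to `[0, 255]` (default); if `FALSE`, raw
#'   distances in pixels are returned.
#' @return matrix in `[0, 255]` (or raw pixel distances).
#' @export
eaw_strength <- function(eaws, shape, normalize = TRUE) {
  mask <- rasterize_ellipses(eaws, shape)
  if (!any(mask)) {
    warning("no elliptical attention windows: strength map is all zero")
    return(matrix(0, shape[1], shape[2]))
  }
  d <- cpp_edt(mask)
  if (normalize) d / max(d) * 255 else d
}

#' Detect elliptical attention windows in a saliency map
#'
#' Runs the full window-extraction chain: Otsu thresholding, hole filling
#' by morphological closing, removal of regions below `min_fraction` of the
#' image area, X-Y projection windows, and ellipse fitting.
#'
#' @param cm saliency map (matrix).
#' @param closing_radius disc radius for [fill_holes()].
#' @param min_fraction minimum region area fraction (default 0.03).
#' @return list with `eaws` (data.frame of ellipses), `windows`, `mask`
#'   (cleaned binary mask), `labels`, and `threshold`.
#' @export
detect_eaws <- function(cm, closing_radius = 5, min_fraction = 0.03) {
  mask <- otsu_threshold(cm)
  filled <- fill_holes(mask, closing_radius)
  cleaned <- remove_small_regions(filled, min_fraction)
  windows <- initial_windows(cleaned$labels)
  eaws <- do.call(rbind, lapply(seq_len(nrow(windows)), function(i)
    fit_ellipse(windows[i, ], dim(cm))))
  if (is.null(eaws))
    eaws <- data.frame(label = integer(0), cx = numeric(0), cy = numeric(0),
                       rx = numeric(0), ry = numeric(0))
  list(eaws = eaws, windows = windows, mask = cleaned$mask,
       labels = cleaned$labels, threshold = attr(mask, "threshold"))
}

#' Export elliptical attention windows as JSON
#'
#' Writes one record per window with 0-based center coordinates (an
#' `"indexing"` field records the convention).
#'
#' @param eaws data.frame of ellipses.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eaws_json <- function(eaws, path) {
  rec <- list(indexing = "0-based",
              coordinates = "(x = column, y = row)",
              eaws = data.frame(label = eaws$label,
                                cx = eaws$cx - 1, cy = eaws$cy - 1,
                                rx = eaws$rx, ry = eaws$ry))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
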