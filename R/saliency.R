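#' Saliency configuration
#'
#' Parameters of the visual-attention saliency map: center-surround filter
#' scales, feature weights, and the wavelet used for the orientation
#' features. The filter scales are stated at a reference image size of
#' 800 x 600 and scale linearly with the input dimensions (rounded to the
#' nearest odd integer, minimum 3): a 400 x 300 input uses half-size
#' windows.
#'
#' @param filter_scales odd square window sizes at reference size
#'   (default `c(11, 13)`).
#' @param w_color,w_orient,w_sat non-negative fusion weights summing to 1
#'   (defaults 0.6, 0.2, 0.2; color dominates because stained nuclei are
#'   mainly distinguished by chromatic contrast).
#' @param wavelet wavelet used for the one-level orientation decomposition;
#'   only `"haar"` is built in.
#' @param reference_size `c(height, width)` the scales refer to.
#' @return a `saliency_config` list.
#' @export
saliency_config <- function(filter_scales = c(11, 13),
                            w_color = 0.6, w_orient = 0.2, w_sat = 0.2,
                            wavelet = "haar",
                            reference_size = c(600, 800)) {
  filter_scales <- as.integer(filter_scales)
  if (any(filter_scales < 3L) || any(filter_scales %% 2L == 0L))
    stop("filter scales must be odd and >= 3", call. = FALSE)
  w <- c(w_color, w_orient, w_sat)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  if (!identical(wavelet, "haar"))
    stop("only the 'haar' wavelet is implemented", call. = FALSE)
  structure(list(filter_scales = filter_scales, w_color = w_color,
                 w_orient = w_orient, w_sat = w_sat, wavelet = wavelet,
                 reference_size = as.integer(reference_size)),
            class = "saliency_config")
}

# Round to nearest odd integer >= 3.
round_odd <- function(x) pmax(3L, as.integer(2L * round((x - 1) / 2) + 1L))

# Filter scales adapted to an image of the given (height, width): linear in
# the dimension ratio relative to the reference size.
scaled_filter_scales <- function(cfg, shape) {
  f <- mean(shape / cfg$reference_size)
  round_odd(cfg$filter_scales * f)
}

# Reflect (symmetric, edge-duplicating) padding of a matrix by r pixels.
pad_reflect <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  if (r >= h || r >= w)
    stop("padding radius exceeds image size", call. = FALSE)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  if (r == 0) return(x)
  x[ri, ci]
}

# Box sum over s x s windows via a summed-area table on reflect-padded input.
box_sum <- function(x, s) {
  r <- (s - 1L) %/% 2L
  p <- pad_reflect(x, r)
  sat <- apply(apply(p, 2, cumsum), 1, cumsum)   # transposed cumulative sums
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  h <- nrow(x); w <- ncol(x)
  i1 <- 1:h; i2 <- i1 + 2L * r
  j1 <- 1:w; j2 <- j1 + 2L * r
  sat[i2 + 1L, j2 + 1L] - sat[i1, j2 + 1L] - sat[i2 + 1L, j1] + sat[i1, j1]
}

#' Center-surround contrast of a feature channel
#'
#' Per-pixel response `|value(p) - mean of the s x s window around p,
#' excluding p|`, with reflect padding at the borders. A constant channel
#' therefore yields an exactly zero map.
#'
#' @param channel numeric matrix.
#' @param scale odd window size, at most `min(dim(channel))`.
#' @return non-negative matrix of the same shape.
#' @export
center_surround <- function(channel, scale) {
  scale <- as.integer(scale)
  if (scale %% 2L == 0L || scale < 3L)
    stop("filter scale must be odd and >= 3", call. = FALSE)
  if (scale > min(dim(channel)))
    stop("filter scale exceeds channel size", call. = FALSE)
  s2 <- as.numeric(scale)^2
  surround <- (box_sum(channel, scale) - channel) / (s2 - 1)
  abs(channel - surround)
}

# Downsample a channel to half size (bilinear).
half_size <- function(x) {
  resize_bilinear(x, ceiling(nrow(x) / 2), ceiling(ncol(x) / 2))
}

#' One-level 2-D Haar wavelet analysis
#'
#' Orthonormal 2x2 Haar step; odd dimensions are edge-padded to even before
#' the transform, so every sub-band is `ceiling(H/2) x ceiling(W/2)`.
#'
#' @param x numeric matrix with `min(dim) >= 2`.
#' @return list of sub-band matrices `LL`, `LH` (horizontal detail),
#'   `HL` (vertical detail), `HH` (diagonal detail).
#' @export
haar_dwt2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  if (h < 2 || w < 2)
    stop("image too small for a one-level wavelet transform", call. = FALSE)
  if (h %% 2L == 1L) x <- rbind(x, x[h, ])
  if (w %% 2L == 1L) x <- cbind(x, x[, w])
  odd_r <- seq(1, nrow(x), by = 2); odd_c <- seq(1, ncol(x), by = 2)
  p00 <- x[odd_r, odd_c, drop = FALSE]
  p01 <- x[odd_r, odd_c + 1, drop = FALSE]
  p10 <- x[odd_r + 1, odd_c, drop = FALSE]
  p11 <- x[odd_r + 1, odd_c + 1, drop = FALSE]
  list(LL = (p00 + p01 + p10 + p11) / 2,
       LH = (p00 + p01 - p10 - p11) / 2,
       HL = (p00 - p01 + p10 - p11) / 2,
       HH = (p00 - p01 - p10 + p11) / 2)
}

#' Color feature map
#'
#' CIE Lab `a*` and `b*` channels, down-sampled to half size, passed through
#' [center_surround()] at every configured filter scale; the returned map is
#' the mean of the four channel-by-scale responses.
#'
#' @param img an [rgb_image].
#' @param cfg a [saliency_config()].
#' @return half-size non-negative feature map.
#' @export
compute_color_map <- function(img, cfg = saliency_config()) {
  img <- check_rgb(img, min_side = 32L)
  lab <- rgb_to_lab(img)
  scales <- scaled_filter_scales(cfg, dim(img)[1:2])
  chans <- list(half_size(lab$a), half_size(lab$b))
  maps <- list()
  for (ch in chans) for (s in scales)
    maps[[length(maps) + 1L]] <- center_surround(ch, s)
  Reduce(`+`, maps) / length(maps)
}

#' Orientation feature map
#'
#' One-level Haar decomposition of the CIE `L*` channel; the `LH`, `HL` and
#' `HH` detail sub-bands (each half size) are passed through
#' [center_surround()] at every configured filter scale; the map is the mean
#' of the six responses.
#'
#' @inheritParams compute_color_map
#' @return half-size non-negative feature map.
#' @export
compute_orientation_map <- function(img, cfg = saliency_config()) {
  img <- check_rgb(img, min_side = 32L)
  lum <- rgb_to_lab(img)$L
  sub <- haar_dwt2(lum)
  scales <- scaled_filter_scales(cfg, dim(img)[1:2])
  maps <- list()
  for (ch in list(sub$HH, sub$HL, sub$LH)) for (s in scales)
    maps[[length(maps) + 1L]] <- center_surround(ch, s)
  Reduce(`+`, maps) / length(maps)
}

#' Saturation feature map
#'
#' HSI saturation channel, down-sampled to half size, passed through
#' [center_surround()] at every configured filter scale; the map is the mean
#' of the per-scale responses.
#'
#' @inheritParams compute_color_map
#' @return half-size non-negative feature map.
#' @export
compute_saturation_map <- function(img, cfg = saliency_config()) {
  img <- check_rgb(img, min_side = 32L)
  sat <- half_size(hsi_saturation(img))
  scales <- scaled_filter_scales(cfg, dim(img)[1:2])
  maps <- lapply(scales, function(s) center_surround(sat, s))
  Reduce(`+`, maps) / length(maps)
}

#' Fuse feature maps into the saliency map
#'
#' Each feature map is min-max normalized to `[0, 1]`, the three are
#' combined as `w_color * color + w_sat * saturation + w_orient *
#' orientation`, and the result is bilinearly up-sampled to `out_shape`
#' (normally the original image size).
#'
#' @param color,orient,sat feature maps of one common shape.
#' @param cfg a [saliency_config()] supplying the weights.
#' @param out_shape `c(height, width)` of the returned map.
#' @return saliency map `C_m` in `[0, 1]` of shape `out_shape`.
#' @export
combine_saliency <- function(color, orient, sat, cfg = saliency_config(),
                             out_shape = dim(color)) {
  if (!identical(dim(color), dim(orient)) || !identical(dim(color), dim(sat)))
    stop("feature maps must share one shape", call. = FALSE)
  cm <- cfg$w_color * normalize01(color) +
    cfg$w_sat * normalize01(sat) +
    cfg$w_orient * normalize01(orient)
  resize_bilinear(cm, out_shape[1], out_shape[2])
}

#' Full-resolution saliency map
#'
#' Convenience wrapper running the three feature maps and fusing them,
#' returning `C_m` at the original image size.
#'
#' @inheritParams compute_color_map
#' @return saliency map in `[0, 1]`, same height/width as `img`.
#' @export
saliency_map <- function(img, cfg = saliency_config()) {
  img <- check_rgb(img, min_side = 32L)
  combine_saliency(compute_color_map(img, cfg),
                   compute_orientation_map(img, cfg),
                   compute_saturation_map(img, cfg),
                   cfg, out_shape = dim(img)[1:2])
}
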