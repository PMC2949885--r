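#' Specification of a synthetic blood smear
#'
#' States the world the generator renders: a pale field, pinkish red-cell
#' clutter, and a few large near-round purple nuclei with chromatin clumps
#' and optional pale vacuoles (real nuclei are textured; the clumps also
#' give the center-surround features interior contrast, and the vacuoles
#' exercise hole filling). Defaults emulate a nominal 800 x 600 stained
#' peripheral-blood micrograph in which every nucleus covers at least 3%
#' of the image pixels.
#'
#' @param height,width image size (default 600 x 800).
#' @param n_nuclei number of nuclei (default 3).
#' @param nucleus_radius range of the horizontal semi-axis in pixels
#'   (default 75-95).
#' @param ellipticity range of the vertical/horizontal semi-axis ratio
#'   (default 0.85-1).
#' @param nucleus_color,rbc_color,background base RGB triples.
#' @param n_rbc number of red cells (default 150: smears are densely tiled).
#' @param rbc_radius red-cell radius range (default 26-36).
#' @param n_vacuoles range of pale vacuoles per nucleus (default 0-2).
#' @param noise_sigma additive Gaussian noise s.d. (default 2).
#' @param min_gap minimum boundary gap between nuclei in pixels (default
#'   60, so neighboring center-surround responses never merge).
#' @param border_margin minimum nucleus distance from the border beyond
#'   its radius (default 25).
#' @param seed integer seed making the rendering deterministic.
#' @return a `smear_spec` list.
#' @export
smear_spec <- function(height = 600, width = 800, n_nuclei = 3,
                       nucleus_radius = c(75, 95), ellipticity = c(0.85, 1),
                       nucleus_color = c(120, 60, 150),
                       rbc_color = c(230, 170, 170),
                       background = c(245, 240, 235),
                       n_rbc = 150, rbc_radius = c(26, 36),
                       n_vacuoles = c(0, 2), noise_sigma = 2,
                       min_gap = 60, border_margin = 25, seed = 1L) {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_nuclei = as.integer(n_nuclei),
               nucleus_radius = nucleus_radius, ellipticity = ellipticity,
               nucleus_color = nucleus_color, rbc_color = rbc_color,
               background = background, n_rbc = as.integer(n_rbc),
               rbc_radius = rbc_radius, n_vacuoles = as.integer(n_vacuoles),
               noise_sigma = noise_sigma, min_gap = min_gap,
               border_margin = border_margin, seed = as.integer(seed))
  if (spec$height < 32 || spec$width < 32)
    stop("smear must be at least 32 x 32", call. = FALSE)
  structure(spec, class = "smear_spec")
}

# Paint an axis-aligned ellipse into the three channel matrices; only the
# bounding box of the ellipse is touched.
paint_ellipse <- function(chans, cx, cy, rx, ry, color, rows, cols) {
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  ii <- max(1, floor(cy - ry)):min(h, ceiling(cy + ry))
  jj <- max(1, floor(cx - rx)):min(w, ceiling(cx + rx))
  local_inside <- outer(((ii - cy) / ry)^2, ((jj - cx) / rx)^2, `+`) < 1
  for (k in 1:3) {
    sub <- chans[[k]][ii, jj, drop = FALSE]
    sub[local_inside] <- color[k]
    chans[[k]][ii, jj] <- sub
  }
  chans
}

#' Render a synthetic blood smear with ground truth
#'
#' Deterministic for a fixed `spec$seed`. Nuclei are placed by rejection
#' sampling so they are pairwise separated and away from the borders;
#' their exact elliptical masks (including clump and vacuole pixels) are
#' returned as ground truth.
#'
#' @param spec a [smear_spec()].
#' @return list with `image` (an [rgb_image]) and `truth`: `masks` (list
#'   of logical matrices, one per nucleus), and `nuclei` (data.frame of
#'   `cx`, `cy`, `rx`, `ry`).
#' @export
generate_smear <- function(spec = smear_spec()) {
  stopifnot(inherits(spec, "smear_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  chans <- lapply(spec$background, function(v) matrix(v, h, w))

  # --- nucleus placement by rejection sampling ---------------------------
  nuclei <- data.frame(cx = numeric(0), cy = numeric(0),
                       rx = numeric(0), ry = numeric(0))
  tries <- 0L
  while (nrow(nuclei) < spec$n_nuclei) {
    if ((tries <- tries + 1L) > 500L)
      stop("could not place nuclei: spec too crowded", call. = FALSE)
    rx <- stats::runif(1, spec$nucleus_radius[1], spec$nucleus_radius[2])
    ry <- rx * stats::runif(1, spec$ellipticity[1], spec$ellipticity[2])
    if (pi * rx * ry < 0.03 * h * w) next
    pad <- max(rx, ry) + spec$border_margin
    if (2 * pad >= min(h, w)) stop("nuclei do not fit the image", call. = FALSE)
    cx <- stats::runif(1, pad, w - pad)
    cy <- stats::runif(1, pad, h - pad)
    ok <- TRUE
    if (nrow(nuclei) > 0) {
      dist <- sqrt((nuclei$cx - cx)^2 + (nuclei$cy - cy)^2)
      gap <- dist - (pmax(nuclei$rx, nuclei$ry) + max(rx, ry))
      ok <- all(gap >= spec$min_gap)
    }
    if (ok) nuclei <- rbind(nuclei, data.frame(cx = cx, cy = cy,
                                               rx = rx, ry = ry))
  }

  # --- red-cell clutter --------------------------------------------------
  for (i in seq_len(spec$n_rbc)) {
    r <- stats::runif(1, spec$rbc_radius[1], spec$rbc_radius[2])
    repeat {
      cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
      if (nrow(nuclei) == 0) break
      d <- sqrt((nuclei$cx - cx)^2 + (nuclei$cy - cy)^2)
      if (all(d > pmax(nuclei$rx, nuclei$ry) + r + 30)) break
    }
    col <- spec$rbc_color + stats::rnorm(3, 0, 4)
    chans <- paint_ellipse(chans, cx, cy, r, r, col, rows, cols)
    # pale biconcave center
    chans <- paint_ellipse(chans, cx, cy, r * 0.45, r * 0.45,
                           col + 12, rows, cols)
  }

  # --- nuclei with chromatin clumps and vacuoles -------------------------
  masks <- vector("list", nrow(nuclei))
  for (i in seq_len(nrow(nuclei))) {
    n <- nuclei[i, ]
    base <- spec$nucleus_color + stats::rnorm(3, 0, 6)
    chans <- paint_ellipse(chans, n$cx, n$cy, n$rx, n$ry, base, rows, cols)
    # dense chromatin clumping: dark, hue-shifted granules covering most of
    # the interior so the nucleus is textured throughout, as real nuclei are
    n_clump <- max(30L, round(pi * n$rx * n$ry / 150))
    for (j in seq_len(n_clump)) {
      theta <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.9
      ccx <- n$cx + rad * n$rx * cos(theta)
      ccy <- n$cy + rad * n$ry * sin(theta)
      cr <- stats::runif(1, 4, 9)
      # heterochromatin: darker, strongly saturated deep violet
      dark <- pmax(base * c(0.7, 0.1, 1.0) + stats::rnorm(3, 0, 6), 0)
      chans <- paint_ellipse(chans, ccx, ccy,
                             cr, cr * stats::runif(1, 0.7, 1),
                             dark, rows, cols)
    }
    nv <- if (spec$n_vacuoles[2] > 0)
      sample(spec$n_vacuoles[1]:spec$n_vacuoles[2], 1L) else 0L
    for (j in seq_len(nv)) {
      theta <- stats::runif(1, 0, 2 * pi)
      rad <- sqrt(stats::runif(1)) * 0.5
      vr <- stats::runif(1, 3, 5)
      chans <- paint_ellipse(chans, n$cx + rad * n$rx * cos(theta),
                             n$cy + rad * n$ry * sin(theta),
                             vr, vr, c(215, 205, 215), rows, cols)
    }
    masks[[i]] <- ((cols - n$cx) / n$rx)^2 + ((rows - n$cy) / n$ry)^2 < 1
    # faint stain granularity, at the level of the camera noise so the
    # nucleus interior stays smooth in the gradient sense
    npix <- sum(masks[[i]])
    for (k in 1:3)
      chans[[k]][masks[[i]]] <- chans[[k]][masks[[i]]] +
        stats::rnorm(npix, 0, 2)
  }

  a <- array(c(pmin(pmax(chans[[1]], 0), 255),
               pmin(pmax(chans[[2]], 0), 255),
               pmin(pmax(chans[[3]], 0), 255)), c(h, w, 3L))
  img <- rgb_image(round(a))
  if (spec$noise_sigma > 0)
    img <- degrade(img, spec$noise_sigma)   # continues the seeded stream
  list(image = img, truth = list(masks = masks, nuclei = nuclei))
}

#' Add clipped Gaussian pixel noise
#'
#' @param image an [rgb_image].
#' @param noise_sigma noise standard deviation in intensity levels;
#'   0 returns the image unchanged.
#' @param seed optional seed; by default the current RNG stream is used.
#' @return degraded [rgb_image] (values rounded back to 0..255).
#' @export
degrade <- function(image, noise_sigma, seed = NULL) {
  image <- check_rgb(image)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  if (noise_sigma == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  a <- as_array(image)
  a <- a + stats::rnorm(length(a), 0, noise_sigma)
  rgb_image(round(pmin(pmax(a, 0), 255)))
}
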