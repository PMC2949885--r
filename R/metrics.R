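#' Mean squared error between two image regions
#'
#' @param a,b numeric arrays/matrices of one shape; the mean runs over all
#'   pixels and channels.
#' @return non-negative scalar.
#' @export
mse <- function(a, b) {
  if (!identical(dim(unclass(a)), dim(unclass(b))))
    stop("regions must share one shape", call. = FALSE)
  mean((as.numeric(a) - as.numeric(b))^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_value^2 / MSE)` in dB; `Inf` when the regions are
#' identical.
#'
#' @inheritParams mse
#' @param max_value peak intensity (default 255).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 255) {
  m <- mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Ratio of Distortion of a nucleus
#'
#' Fraction of original nucleus pixels lost in the resized image:
#' `|M \\ (M intersect S)| / |M|`, where `M` is the nucleus pixel set in
#' the original frame and `S` the resized nucleus pixel set pulled back
#' into that frame.
#'
#' @param original,resized logical matrices in the original image frame.
#' @return ratio in `[0, 1]`.
#' @export
rod <- function(original, resized) {
  if (!identical(dim(original), dim(resized)))
    stop("masks must share the original frame", call. = FALSE)
  m <- sum(original)
  if (m == 0) stop("empty original nucleus mask", call. = FALSE)
  sum(original & !resized) / m
}

#' Pull a resized-frame mask back to the original frame
#'
#' Uses the per-pixel original-coordinate rasters logged during carving:
#' each surviving pixel knows where it came from, so the pullback is exact.
#'
#' @param mask logical/numeric matrix in the resized frame.
#' @param orig_rows,orig_cols integer rasters from [seam_carve()].
#' @param orig_shape original `c(height, width)`.
#' @return logical matrix in the original frame.
#' @export
pullback_mask <- function(mask, orig_rows, orig_cols, orig_shape) {
  if (!identical(dim(mask), dim(orig_rows)))
    stop("mask must share the resized frame", call. = FALSE)
  out <- matrix(FALSE, orig_shape[1], orig_shape[2])
  sel <- mask > 0.5
  out[cbind(as.vector(orig_rows[sel]), as.vector(orig_cols[sel]))] <- TRUE
  out
}

#' Quality report for a carved image
#'
#' Per-nucleus Ratio of Distortion and PSNR, plus whole-image figures. The
#' resized masks are pulled back into the original frame through the seam
#' bookkeeping; the per-nucleus PSNR compares, inside the tight bounding
#' box of each original mask, the original pixels that survived carving
#' with their values in the resized image.
#'
#' @param original,resized [rgb_image]s before and after carving.
#' @param masks_orig list of logical masks in the original frame, one per
#'   nucleus.
#' @param masks_resized list of numeric/logical masks in the resized frame,
#'   paired by position with `masks_orig`. An unpaired original mask is
#'   scored as fully lost (ROD 1) with a warning.
#' @param orig_rows,orig_cols coordinate rasters from [seam_carve()].
#' @return list of class `quality_report`: `mse`, `psnr` (whole surviving
#'   area), `rod` (per nucleus), `mean_rod`, `psnr_nuclei` (per nucleus).
#' @export
evaluate <- function(original, resized, masks_orig, masks_resized,
                     orig_rows, orig_cols) {
  original <- check_rgb(original); resized <- check_rgb(resized)
  oshape <- dim(original)[1:2]
  ao <- as_array(original); ar <- as_array(resized)
  # whole-image comparison over surviving pixels
  idx_r <- as.vector(orig_rows); idx_c <- as.vector(orig_cols)
  surv_orig <- vapply(1:3, function(k) ao[cbind(idx_r, idx_c, k)],
                      numeric(length(idx_r)))
  surv_res <- vapply(1:3, function(k) as.vector(ar[, , k]),
                     numeric(length(idx_r)))
  overall_mse <- mse(surv_orig, surv_res)
  rods <- numeric(length(masks_orig))
  psnrs <- numeric(length(masks_orig))
  for (k in seq_along(masks_orig)) {
    m <- masks_orig[[k]]
    if (k > length(masks_resized) || is.null(masks_resized[[k]])) {
      warning("nucleus ", k, " has no resized mask: scored as fully lost")
      rods[k] <- 1; psnrs[k] <- NA_real_
      next
    }
    s <- pullback_mask(masks_resized[[k]], orig_rows, orig_cols, oshape)
    rods[k] <- rod(m, s)
    # bounding box of M; compare surviving pixels inside it
    wi <- which(m, arr.ind = TRUE)
    rr <- range(wi[, 1]); cc <- range(wi[, 2])
    inbox <- which(idx_r >= rr[1] & idx_r <= rr[2] &
                     idx_c >= cc[1] & idx_c <= cc[2])
    if (length(inbox) == 0L) {
      psnrs[k] <- NA_real_
    } else {
      psnrs[k] <- psnr(surv_orig[inbox, , drop = FALSE],
                       surv_res[inbox, , drop = FALSE])
    }
  }
  structure(list(mse = overall_mse,
                 psnr = if (overall_mse == 0) Inf else
                   10 * log10(255^2 / overall_mse),
                 rod = rods, mean_rod = mean(rods),
                 psnr_nuclei = psnrs),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> PSNR %.2f dB | mean ROD %.4f over %d nuclei\n",
              x$psnr, x$mean_rod, length(x$rod)))
  invisible(x)
}
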