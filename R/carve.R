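#' Forward-energy step costs at one pixel
#'
#' The three candidate transition costs of a vertical seam passing through
#' `(i, j)`: `cU = |E(i,j+1) - E(i,j-1)|`, `cL = cU + |E(i-1,j) -
#' E(i,j-1)|`, `cR = cU + |E(i-1,j) - E(i,j+1)|`. They price the new pixel
#' adjacencies created by removing `(i, j)`. Any difference whose neighbor
#' falls outside the raster contributes 0.
#'
#' @param energy numeric matrix (normally the SSM).
#' @param i,j 1-based pixel position.
#' @return named numeric vector `c(cL, cU, cR)`.
#' @export
forward_costs <- function(energy, i, j) {
  h <- nrow(energy); w <- ncol(energy)
  if (i < 1 || i > h || j < 1 || j > w)
    stop("pixel position out of range", call. = FALSE)
  cpp_step_costs(energy, as.integer(i) - 1L, as.integer(j) - 1L)
}

#' Cumulative forward-energy cost matrix
#'
#' Row-by-row dynamic program `M(i,j) = P(i,j) + min(M(i-1,j-1)+cL,
#' M(i-1,j)+cU, M(i-1,j+1)+cR)` where `P` is the L1 gradient magnitude of
#' the energy raster ([ssm_gradient()]). Out-of-grid predecessors cost
#' `+Inf`; ties prefer the smallest predecessor column.
#'
#' @param energy numeric matrix.
#' @return list with `values` (the cumulative cost matrix) and `back`
#'   (backpointers in `{-1, 0, 1}`).
#' @export
build_cost_matrix <- function(energy) {
  cpp_cost_matrix(energy)
}

#' L1 gradient magnitude of a raster
#'
#' `|dx| + |dy|` with central differences in the interior and one-sided
#' differences at the borders; this is the `P` term of the seam-cost
#' recurrence.
#'
#' @param x numeric matrix.
#' @return non-negative matrix of the same shape.
#' @export
ssm_gradient <- function(x) cpp_grad_l1(x)

#' Minimum-cost vertical seam
#'
#' Starts at the leftmost minimum of the last row of the cost matrix and
#' follows the backpointers upward. The result is a monotone 8-connected
#' top-to-bottom path: one column index per row, consecutive entries
#' differing by at most 1.
#'
#' @param m cost matrix as returned by [build_cost_matrix()].
#' @return integer vector of 1-based column indices, length `nrow`, with
#'   attribute `orientation = "vertical"`.
#' @export
find_min_seam <- function(m) {
  seam <- cpp_trace_seam(m$values, m$back)
  attr(seam, "orientation") <- "vertical"
  seam
}

#' Remove a vertical seam
#'
#' Deletes one pixel per row and shifts the remainder left; every non-seam
#' pixel value is preserved bit-exactly.
#'
#' @param x an [rgb_image] or a numeric matrix.
#' @param seam integer vector, one column per row.
#' @return object of the same kind with one column fewer.
#' @export
remove_seam <- function(x, seam) UseMethod("remove_seam")

#' @export
remove_seam.matrix <- function(x, seam) cpp_remove_seam(x, as.integer(seam))

#' @export
remove_seam.rgb_image <- function(x, seam) {
  a <- as_array(x)
  out <- vapply(1:3, function(k) cpp_remove_seam(a[, , k], as.integer(seam)),
                matrix(0, dim(a)[1], dim(a)[2] - 1L))
  rgb_image(out)
}

#' Gradient-magnitude baseline energy
#'
#' The conventional seam-carving energy: per-pixel L1 gradient magnitude of
#' the luminance channel (Rec. 601 luma), central differences in the
#' interior and one-sided at the borders.
#'
#' @param img an [rgb_image].
#' @return non-negative matrix of the image's height and width.
#' @export
gradient_energy <- function(img) {
  img <- check_rgb(img)
  a <- as_array(img)
  lum <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  cpp_grad_l1(lum)
}

#' Automatic target size from the elliptical attention windows
#'
#' The target is just large enough to keep every detected nucleus plus a
#' margin: with the default `"union"` policy, the horizontal target is the
#' extent of the union of EAW bounding boxes plus `2 * margin`, clamped
#' between that extent and the image width (vertical analogous). The
#' `"extent-sum"` policy instead sums the individual EAW extents.
#'
#' @param eaws data.frame of ellipses (`cx`, `cy`, `rx`, `ry`).
#' @param shape image `c(height, width)`.
#' @param margin pixels added on each side (default 10).
#' @param policy `"union"` (default) or `"extent-sum"`.
#' @return integer `c(height, width)` target.
#' @export
auto_target_size <- function(eaws, shape, margin = 10,
                             policy = c("union", "extent-sum")) {
  policy <- match.arg(policy)
  if (is.null(eaws) || nrow(eaws) == 0L)
    stop(structure(class = c("cellcarve_no_eaws", "error", "condition"),
                   list(message = paste(
                     "no elliptical attention windows detected;",
                     "specify an explicit target size"),
                     call = sys.call(-1))))
  if (policy == "union") {
    wspan <- max(eaws$cx + eaws$rx) - min(eaws$cx - eaws$rx)
    hspan <- max(eaws$cy + eaws$ry) - min(eaws$cy - eaws$ry)
  } else {
    wspan <- sum(2 * eaws$rx)
    hspan <- sum(2 * eaws$ry)
  }
  w_t <- min(shape[2], max(ceiling(wspan), ceiling(wspan + 2 * margin)))
  h_t <- min(shape[1], max(ceiling(hspan), ceiling(hspan + 2 * margin)))
  c(height = as.integer(h_t), width = as.integer(w_t))
}

# Transpose helpers for horizontal seams (single DP code path).
t_img <- function(a) aperm(a, c(2L, 1L, 3L))

#' Seam-carve an image to a target size
#'
#' Iteratively removes minimum-cost forward-energy seams, alternating
#' vertical and horizontal (horizontal seams are carved on the transposed
#' rasters), until the target size is reached. The energy raster has the
#' seam entries removed at every step; optionally the energy is recomputed
#' from the current image every `recompute_every` seams.
#'
#' @param img an [rgb_image].
#' @param target integer `c(height, width)`, at most the input size.
#' @param energy numeric energy matrix of the image's shape (an SSM or
#'   [gradient_energy()] output).
#' @param aux named list of numeric matrices carved alongside the image
#'   (e.g. ground-truth masks). Original-coordinate index rasters are
#'   always carried, so every surviving pixel can be mapped back.
#' @param recompute_every recompute the energy every this many seams
#'   (0 = never, the default).
#' @param recompute_fn `function(img) -> matrix` used for recomputation.
#' @return list with `image` (carved [rgb_image]), `energy` (carved energy
#'   raster), `aux` (carved matrices), `orig_rows`/`orig_cols` (integer
#'   rasters of each surviving pixel's original coordinates) and `seams`
#'   (the removal log: orientation and path per step, in the frame current
#'   at removal time).
#' @export
seam_carve <- function(img, target, energy, aux = list(),
                       recompute_every = 0L, recompute_fn = NULL) {
  img <- check_rgb(img)
  h <- img_height(img); w <- img_width(img)
  target <- as.integer(round(target))
  if (length(target) != 2L || any(target < 1L))
    stop("target must be positive c(height, width)", call. = FALSE)
  if (target[1] > h || target[2] > w)
    stop("target larger than source: seam insertion is not supported",
         call. = FALSE)
  if (!identical(dim(energy), c(h, w)))
    stop("energy raster must match the image shape", call. = FALSE)
  a <- as_array(img)
  chans <- list(a[, , 1], a[, , 2], a[, , 3])
  aux <- c(aux, list(
    .orig_rows = matrix(as.numeric(seq_len(h)), h, w),
    .orig_cols = matrix(as.numeric(seq_len(w)), h, w, byrow = TRUE)))
  log <- list()
  transposed <- FALSE
  last_vertical <- FALSE   # first seam (when both are needed) is vertical
  flip <- function() {
    chans <<- lapply(chans, t)
    aux <<- lapply(aux, t)
    energy <<- t(energy)
    transposed <<- !transposed
  }
  since_recompute <- 0L
  cur <- function() if (transposed) rev(dim(chans[[1]])) else dim(chans[[1]])
  repeat {
    d <- cur()
    dv <- d[2] - target[2]   # vertical seams still to remove
    dh <- d[1] - target[1]
    if (dv == 0L && dh == 0L) break
    # strict alternation while both orientations still need removals
    want_vertical <- if (dv > 0L && dh > 0L) !last_vertical else dv > 0L
    last_vertical <- want_vertical
    if (want_vertical == transposed) flip()
    if (recompute_every > 0L && !is.null(recompute_fn) &&
        since_recompute >= recompute_every) {
      cur_a <- array(c(chans[[1]], chans[[2]], chans[[3]]),
                     c(dim(chans[[1]]), 3L))
      if (transposed) {
        energy <- t(recompute_fn(rgb_image(t_img(cur_a))))
      } else {
        energy <- recompute_fn(rgb_image(cur_a))
      }
      since_recompute <- 0L
    }
    m <- cpp_cost_matrix(energy)
    seam <- cpp_trace_seam(m$values, m$back)
    energy <- cpp_remove_seam(energy, seam)
    chans <- lapply(chans, cpp_remove_seam, seam = seam)
    aux <- lapply(aux, cpp_remove_seam, seam = seam)
    log[[length(log) + 1L]] <- list(
      orientation = if (transposed) "horizontal" else "vertical",
      path = as.integer(seam))
    since_recompute <- since_recompute + 1L
  }
  if (transposed) flip()
  out <- rgb_image(array(c(chans[[1]], chans[[2]], chans[[3]]),
                         c(dim(chans[[1]]), 3L)))
  orig_rows <- matrix(as.integer(aux$.orig_rows), nrow(aux$.orig_rows))
  orig_cols <- matrix(as.integer(aux$.orig_cols), nrow(aux$.orig_cols))
  aux$.orig_rows <- NULL; aux$.orig_cols <- NULL
  list(image = out, energy = energy, aux = aux,
       orig_rows = orig_rows, orig_cols = orig_cols, seams = log)
}
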