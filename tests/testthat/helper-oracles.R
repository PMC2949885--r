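# Independent brute-force oracles, deliberately written with plain loops and
# no calls into the package's computational kernels.

# center-surround: |x - mean of s x s window excluding center| with
# symmetric (edge-duplicating) padding
brute_center_surround <- function(x, s) {
  r <- (s - 1) / 2
  h <- nrow(x); w <- ncol(x)
  ri <- c(r:1, 1:h, h:(h - r + 1))
  ci <- c(r:1, 1:w, w:(w - r + 1))
  p <- x[ri, ci]
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    win <- p[i:(i + 2 * r), j:(j + 2 * r)]
    out[i, j] <- abs(x[i, j] - (sum(win) - x[i, j]) / (s^2 - 1))
  }
  out
}

# exact Euclidean distance to the nearest FALSE pixel, by enumeration
brute_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    if (!mask[i, j]) next
    out[i, j] <- sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2))
  }
  out
}

# binary closing with an exact disc structuring element, by enumeration
brute_closing <- function(mask, radius) {
  h <- nrow(mask); w <- ncol(mask)
  offs <- expand.grid(di = -ceiling(radius):ceiling(radius),
                      dj = -ceiling(radius):ceiling(radius))
  offs <- offs[offs$di^2 + offs$dj^2 <= radius^2, ]
  hit <- function(m, i, j) {   # any SE-covered pixel set?
    ii <- i + offs$di; jj <- j + offs$dj
    inb <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    any(m[cbind(ii[inb], jj[inb])])
  }
  dil <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) dil[i, j] <- hit(mask, i, j)
  ero <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) ero[i, j] <- !hit(!dil, i, j)
  ero
}

# L1 gradient magnitude: central differences, one-sided at borders
brute_grad <- function(v) {
  h <- nrow(v); w <- ncol(v)
  g <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    dx <- if (w == 1) 0
    else if (j == 1) abs(v[i, 2] - v[i, 1])
    else if (j == w) abs(v[i, w] - v[i, w - 1])
    else abs(v[i, j + 1] - v[i, j - 1]) / 2
    dy <- if (h == 1) 0
    else if (i == 1) abs(v[2, j] - v[1, j])
    else if (i == h) abs(v[h, j] - v[h - 1, j])
    else abs(v[i + 1, j] - v[i - 1, j]) / 2
    g[i, j] <- dx + dy
  }
  g
}

# forward step costs by direct transcription; out-of-range difference = 0
brute_step <- function(v, i, j) {
  w <- ncol(v)
  dH <- if (j > 1 && j < w) abs(v[i, j + 1] - v[i, j - 1]) else 0
  cL <- dH + if (i > 1 && j > 1) abs(v[i - 1, j] - v[i, j - 1]) else 0
  cR <- dH + if (i > 1 && j < w) abs(v[i - 1, j] - v[i, j + 1]) else 0
  c(cL = cL, cU = dH, cR = cR)
}

# minimum total forward-energy cost over ALL monotone 8-connected
# top-to-bottom paths, by exhaustive recursion (small rasters only)
brute_min_seam_cost <- function(v) {
  h <- nrow(v); w <- ncol(v)
  p <- brute_grad(v)
  best <- Inf
  recur <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == h) { best <<- min(best, acc); return(invisible()) }
    for (nj in (j - 1):(j + 1)) {
      if (nj < 1 || nj > w) next
      st <- brute_step(v, i + 1, nj)
      cost <- if (nj == j - 1) st["cR"] else if (nj == j) st["cU"] else st["cL"]
      # moving from column j at row i down to nj at row i+1: the predecessor
      # of (i+1, nj) at column j is its upper-right when j = nj + 1 (cost cR),
      # upper when j = nj (cU), upper-left when j = nj - 1 (cL)
      recur(i + 1, nj, acc + p[i + 1, nj] + cost)
    }
  }
  for (j in 1:w) recur(1, j, p[1, j])
  best
}

# small seeded random raster
rand_mat <- function(h, w, seed) {
  set.seed(seed)
  matrix(stats::runif(h * w, 0, 255), h, w)
}

# compact smear spec for pipeline-level tests (still >= 3% nuclei)
small_spec <- function(seed, ...) {
  smear_spec(height = 300, width = 400, n_nuclei = 2,
             nucleus_radius = c(40, 48), rbc_radius = c(13, 18),
             n_rbc = 140, min_gap = 30, border_margin = 15,
             seed = seed, ...)
}
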