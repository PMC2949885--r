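#' Gaussian smoothing configuration
#'
#' @param sigma standard deviation in pixels (default 2 at the 800 x 600
#'   reference size; the smoothing only has to suppress pixel-scale noise).
#' @param truncate kernel half-width in sigmas (default 3).
#' @return a `smoothing_config` list.
#' @export
smoothing_config <- function(sigma = 2, truncate = 3) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  structure(list(sigma = sigma, truncate = truncate),
            class = "smoothing_config")
}

#' Separable Gaussian blur with reflect borders
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels.
#' @param truncate kernel half-width in sigmas.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma, truncate = 3) {
  r <- max(1L, as.integer(ceiling(truncate * sigma)))
  r <- min(r, nrow(x) - 1L, ncol(x) - 1L)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_reflect(x, r)
  # vertical then horizontal pass
  v <- matrix(0, nrow(x), ncol(p))
  for (t in seq(-r, r))
    v <- v + k[t + r + 1L] * p[(1 + r + t):(nrow(x) + r + t), , drop = FALSE]
  out <- matrix(0, nrow(x), ncol(x))
  for (t in seq(-r, r))
    out <- out + k[t + r + 1L] * v[, (1 + r + t):(ncol(x) + r + t), drop = FALSE]
  out
}

#' Build the Saliency Strength Map
#'
#' Fuses the saliency map and the EAW strength: `SSM = g(0.5 * (Cm +
#' EAW_S))` where `g` is Gaussian smoothing, followed by min-max
#' normalization to `[0, 255]`. `cm` is expected in `[0, 1]` and is scaled
#' by 255 first so the two operands are commensurate.
#'
#' @param cm saliency map in `[0, 1]`.
#' @param eaw_s EAW strength map in `[0, 255]`, same shape.
#' @param smoothing a [smoothing_config()].
#' @return matrix in `[0, 255]` with attribute `"provenance"` naming the
#'   fused operands.
#' @export
build_ssm <- function(cm, eaw_s, smoothing = smoothing_config()) {
  if (!identical(dim(cm), dim(eaw_s)))
    stop("saliency map and EAW strength must share one shape", call. = FALSE)
  avg <- 0.5 * (255 * cm + eaw_s)
  sm <- gaussian_blur(avg, smoothing$sigma, smoothing$truncate)
  out <- normalize01(sm) * 255
  attr(out, "provenance") <- c("Cm", "EAW_S")
  out
}
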