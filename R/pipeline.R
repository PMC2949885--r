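#' Pipeline configuration
#'
#' Umbrella configuration for the whole resizing pipeline. All pixel-sized
#' parameters (filter scales, closing radius, smoothing sigma, margin) are
#' stated at the 800 x 600 reference size and scale linearly with the
#' input dimensions.
#'
#' @param saliency a [saliency_config()].
#' @param closing_radius disc radius for hole filling (default 5).
#' @param min_fraction minimum region area fraction (default 0.03).
#' @param sigma Gaussian smoothing s.d. for the SSM (default 2).
#' @param margin auto-target margin in pixels (default 10).
#' @param auto_policy `"union"` or `"extent-sum"` (see
#'   [auto_target_size()]).
#' @param energy `"ssm"` (default) or `"gradient"` baseline.
#' @param recompute_every recompute the energy from the carved image every
#'   this many seams (0 = never).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(saliency = saliency_config(),
                            closing_radius = 5, min_fraction = 0.03,
                            sigma = 2, margin = 10,
                            auto_policy = c("union", "extent-sum"),
                            energy = c("ssm", "gradient"),
                            recompute_every = 0L) {
  structure(list(saliency = saliency,
                 closing_radius = closing_radius,
                 min_fraction = min_fraction, sigma = sigma,
                 margin = margin, auto_policy = match.arg(auto_policy),
                 energy = match.arg(energy),
                 recompute_every = as.integer(recompute_every)),
            class = "pipeline_config")
}

# Linear size factor of an image relative to the configured reference.
size_factor <- function(cfg, shape) {
  mean(shape / cfg$saliency$reference_size)
}

#' Read / write a pipeline configuration
#'
#' JSON always works; YAML is used for `.yaml`/`.yml` paths when the
#' `yaml` package is installed. `load_config(save_config(cfg))` is the
#' identity.
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  sal <- raw$saliency
  cfg <- pipeline_config(
    saliency = saliency_config(
      filter_scales = sal$filter_scales %||% c(11, 13),
      w_color = sal$weights$color %||% 0.6,
      w_orient = sal$weights$orientation %||% 0.2,
      w_sat = sal$weights$saturation %||% 0.2,
      wavelet = sal$wavelet %||% "haar",
      reference_size = unlist(sal$reference_size) %||% c(600, 800)),
    closing_radius = raw$closing_radius %||% 5,
    min_fraction = raw$min_fraction %||% 0.03,
    sigma = raw$sigma %||% 2,
    margin = raw$margin %||% 10,
    auto_policy = raw$auto_policy %||% "union",
    energy = raw$energy %||% "ssm",
    recompute_every = raw$recompute_every %||% 0L)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_config
#' @param cfg a [pipeline_config()].
#' @export
save_config <- function(cfg, path) {
  raw <- list(
    saliency = list(
      filter_scales = cfg$saliency$filter_scales,
      weights = list(color = cfg$saliency$w_color,
                     orientation = cfg$saliency$w_orient,
                     saturation = cfg$saliency$w_sat),
      wavelet = cfg$saliency$wavelet,
      reference_size = cfg$saliency$reference_size),
    closing_radius = cfg$closing_radius, min_fraction = cfg$min_fraction,
    sigma = cfg$sigma, margin = cfg$margin,
    auto_policy = cfg$auto_policy, energy = cfg$energy,
    recompute_every = cfg$recompute_every)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML configs require the 'yaml' package; use JSON", call. = FALSE)
    yaml::write_yaml(raw, path)
  } else jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full content-aware resizing pipeline
#'
#' Saliency map, elliptical attention windows, Saliency Strength Map, and
#' forward-energy seam carving, in that order; with `energy = "gradient"`
#' the saliency stages are bypassed and the conventional gradient energy
#' is used. The pipeline has no random step, so identical inputs give
#' identical outputs.
#'
#' @param image an [rgb_image].
#' @param cfg a [pipeline_config()].
#' @param target `c(height, width)`, or `NULL` to size the target
#'   automatically from the detected EAWs.
#' @param aux named list of matrices carved alongside (e.g. truth masks).
#' @return list with `image` (resized), `target`, `ssm`, `cm`, `eaws`,
#'   `seams`, `aux`, `orig_rows`, `orig_cols`.
#' @export
run_pipeline <- function(image, cfg = pipeline_config(), target = NULL,
                         aux = list()) {
  image <- check_rgb(image, min_side = 32L)
  shape <- dim(image)[1:2]
  f <- size_factor(cfg, shape)
  cm <- NULL; eaws <- NULL; ssm <- NULL
  need_saliency <- cfg$energy == "ssm" || is.null(target)
  if (need_saliency) {
    cm <- saliency_map(image, cfg$saliency)
    det <- detect_eaws(cm, closing_radius = max(1, cfg$closing_radius * f),
                       min_fraction = cfg$min_fraction)
    eaws <- det$eaws
  }
  if (is.null(target))
    target <- auto_target_size(eaws, shape, margin = cfg$margin * f,
                               policy = cfg$auto_policy)
  if (cfg$energy == "ssm") {
    eaw_s <- eaw_strength(eaws, shape)
    ssm <- build_ssm(cm, eaw_s, smoothing_config(sigma = cfg$sigma * f))
    energy <- ssm
    recompute_fn <- NULL  # SSM is carved, not recomputed, by default
    if (cfg$recompute_every > 0L) {
      recompute_fn <- function(im) {
        cm2 <- saliency_map(im, cfg$saliency)
        det2 <- detect_eaws(cm2,
                            closing_radius = max(1, cfg$closing_radius * f),
                            min_fraction = cfg$min_fraction)
        build_ssm(cm2, eaw_strength(det2$eaws, dim(im)[1:2]),
                  smoothing_config(sigma = cfg$sigma * f))
      }
    }
  } else {
    energy <- gradient_energy(image)
    recompute_fn <- if (cfg$recompute_every > 0L)
      function(im) gradient_energy(im) else NULL
  }
  carved <- seam_carve(image, target, energy, aux = aux,
                       recompute_every = cfg$recompute_every,
                       recompute_fn = recompute_fn)
  c(list(target = target, ssm = ssm, cm = cm, eaws = eaws), carved)
}

#' Export a seam log as JSON
#'
#' One record per removed seam with its orientation and 0-based path in
#' the frame current at removal time.
#'
#' @param seams seam log from [seam_carve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seamlog_json <- function(seams, path) {
  rec <- list(indexing = "0-based",
              seams = lapply(seams, function(s)
                list(orientation = s$orientation, path = s$path - 1L)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
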