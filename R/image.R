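#' RGB image container
#'
#' A thin S3 wrapper around an `H x W x 3` numeric array of 8-bit channel
#' intensities in `[0, 255]`. All pipeline math is done on floating-point
#' copies; values are only quantized on write.
#'
#' @param pixels numeric `H x W x 3` array (or `H x W` matrix, promoted by
#'   channel replication) with values in `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 array", call. = FALSE)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel intensities must be finite and in [0, 255]", call. = FALSE)
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%.1f, %.1f]>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(unclass(x))

img_height <- function(img) dim(img)[1]
img_width <- function(img) dim(img)[2]

as_array <- function(img) {
  a <- unclass(img)
  attributes(a) <- list(dim = dim(a))
  a
}

check_rgb <- function(img, min_side = 1L) {
  if (!inherits(img, "rgb_image")) img <- rgb_image(img)
  if (any(dim(img)[1:2] < min_side))
    stop(sprintf("image must be at least %d x %d", min_side, min_side),
         call. = FALSE)
  img
}

#' Min-max normalize a raster to [0, 1]
#'
#' Degenerate rasters (max == min) are mapped to all zeros with a warning.
#'
#' @param x numeric matrix.
#' @return matrix of the same shape with values in `[0, 1]`.
#' @export
normalize01 <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("raster contains non-finite values", call. = FALSE)
  if (rng[1] == rng[2]) {
    warning("degenerate raster (max == min): normalized to all zeros")
    return(array(0, dim(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Bilinear resampling of a matrix
#'
#' Pixel centers are aligned as in standard image resampling: output center
#' `k` maps to input coordinate `(k - 0.5) * in/out + 0.5` (1-based),
#' clamped to the valid range.
#'
#' @param x numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return `out_h x out_w` matrix.
#' @export
resize_bilinear <- function(x, out_h, out_w) {
  h <- nrow(x); w <- ncol(x)
  if (out_h == h && out_w == w) return(x)
  coord <- function(n_out, n_in) {
    p <- (seq_len(n_out) - 0.5) * (n_in / n_out) + 0.5
    pmin(pmax(p, 1), n_in)
  }
  ri <- coord(out_h, h); ci <- coord(out_w, w)
  r0 <- pmin(floor(ri), h - 1L); r0[h == 1] <- 1
  c0 <- pmin(floor(ci), w - 1L); c0[w == 1] <- 1
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  top <- x[r0, c0, drop = FALSE] * (1 - fc)[col(matrix(0, out_h, out_w))] +
    x[r0, c1, drop = FALSE] * fc[col(matrix(0, out_h, out_w))]
  bot <- x[r1, c0, drop = FALSE] * (1 - fc)[col(matrix(0, out_h, out_w))] +
    x[r1, c1, drop = FALSE] * fc[col(matrix(0, out_h, out_w))]
  top * (1 - fr) + bot * fr
}

#' Convert an RGB image to CIE Lab channels
#'
#' Channels are interpreted as sRGB (D65). Returns the three Lab channels as
#' matrices; `L` in `[0, 100]`, `a`/`b` in their usual signed ranges.
#'
#' @param img an [rgb_image].
#' @return list with matrices `L`, `a`, `b`.
#' @export
rgb_to_lab <- function(img) {
  img <- check_rgb(img)
  d <- dim(img)
  m <- matrix(as.numeric(img), ncol = 3L) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  list(L = matrix(lab[, 1], d[1], d[2]),
       a = matrix(lab[, 2], d[1], d[2]),
       b = matrix(lab[, 3], d[1], d[2]))
}

#' HSI saturation channel
#'
#' Classical HSI saturation `S = 1 - 3 min(R,G,B) / (R+G+B)`, with `S = 0`
#' where `R+G+B = 0`.
#'
#' @param img an [rgb_image].
#' @return matrix in `[0, 1]`.
#' @export
hsi_saturation <- function(img) {
  img <- check_rgb(img)
  a <- as_array(img)
  s <- a[, , 1] + a[, , 2] + a[, , 3]
  mn <- pmin(a[, , 1], a[, , 2], a[, , 3])
  out <- array(0, dim(a)[1:2])
  nz <- s > 0
  out[nz] <- 1 - 3 * mn[nz] / s[nz]
  out
}

# --- image file I/O -------------------------------------------------------

#' Read an image file
#'
#' Reads PGM/PPM (ASCII `P2`/`P3` and binary `P5`/`P6`, 8- or 16-bit) with
#' the built-in reader, and PNG when the `png` package is installed.
#' Grayscale images are promoted to RGB by channel replication; an alpha
#' channel is dropped with a warning; 16-bit samples are rescaled to 8-bit
#' by division by 257.
#'
#' @param path file path; format chosen by extension (`.pgm`, `.ppm`,
#'   `.pnm`, `.png`).
#' @return an [rgb_image].
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package; use PPM/PGM instead",
           call. = FALSE)
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3] == 4L) {
      warning("alpha channel dropped: ", path)
      a <- a[, , 1:3, drop = FALSE]
    }
    if (dim(a)[3] == 2L) {  # gray + alpha
      warning("alpha channel dropped: ", path)
      a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
    }
    return(rgb_image(a * 255))
  }
  if (ext %in% c("pgm", "ppm", "pnm")) return(read_pnm(path))
  stop("unsupported image format: .", ext, " (", path, ")", call. = FALSE)
}

#' Write an image file
#'
#' @param img an [rgb_image]; values are rounded and clipped to 0..255.
#' @param path output path (`.ppm`, `.pgm` grayscale, or `.png` if the
#'   `png` package is installed).
#' @param ascii write ASCII (`P3`) instead of binary (`P6`) PNM.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path, ascii = FALSE) {
  img <- check_rgb(img)
  a <- pmin(pmax(round(as_array(img)), 0), 255)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package; use .ppm instead",
           call. = FALSE)
    png::writePNG(a / 255, path)
    return(invisible(path))
  }
  if (!ext %in% c("ppm", "pgm", "pnm"))
    stop("unsupported image format: .", ext, call. = FALSE)
  write_pnm(a, path, ascii = ascii, gray = ext == "pgm")
  invisible(path)
}

# Interleave an H x W x 3 array into RGBRGB... raster order (row-major).
interleave_rgb <- function(a) {
  as.vector(aperm(a, c(3L, 2L, 1L)))
}

read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tokens <- character(0)
  # header tokens: magic, width, height, (maxval unless P1/P4)
  read_token <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "") stop("truncated PNM header: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch %in% c("\n", "\r", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) next
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0 || ch == "" || grepl("[[:space:]]", ch)) break
        tok <- paste0(tok, ch)
      }
      return(tok)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1 || h < 1 || maxval < 1)
    stop("corrupt PNM header: ", path, call. = FALSE)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval < 256) {
      vals <- as.integer(readBin(con, "integer", n = n, size = 1L,
                                 signed = FALSE))
    } else {
      vals <- as.integer(readBin(con, "integer", n = n, size = 2L,
                                 signed = FALSE, endian = "big"))
    }
  }
  if (length(vals) != n) stop("truncated PNM data: ", path, call. = FALSE)
  if (maxval > 255) vals <- vals / 257
  else if (maxval != 255) vals <- vals * (255 / maxval)
  if (nch == 1L) {
    m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    return(rgb_image(m))
  }
  a <- aperm(array(vals, c(3L, w, h)), c(3L, 2L, 1L))
  rgb_image(a)
}

write_pnm <- function(a, path, ascii = FALSE, gray = FALSE) {
  h <- dim(a)[1]; w <- dim(a)[2]
  if (gray) {
    v <- round((a[, , 1] + a[, , 2] + a[, , 3]) / 3)
    flat <- as.vector(t(v))
    magic <- if (ascii) "P2" else "P5"
  } else {
    flat <- interleave_rgb(a)
    magic <- if (ascii) "P3" else "P6"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("%s\n%d %d\n255\n", magic, w, h), con, eos = NULL)
  if (ascii) {
    writeChar(paste(format(flat), collapse = "\n"), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.integer(flat), con, size = 1L)
  }
  invisible(path)
}
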