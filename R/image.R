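#' Create an 8-bit RGB image object
#'
#' Images are stored as a `width x height x 3` numeric array of 8-bit
#' values (0-255), channel order red, green, blue. The first array index
#' is the image column (x), the second the row (y); see the package help
#' for the coordinate conventions.
#'
#' @param pixels numeric array, `W x H x 3`, values in `[0, 255]`.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a W x H x 3 array")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must be finite and in [0, 255]")
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", dim(x)[1], dim(x)[2]))
  invisible(x)
}

image_width  <- function(img) dim(img)[1]
image_height <- function(img) dim(img)[2]

#' Read a PNG/JPEG raster as an `rgb_image`
#'
#' @param path file path to a PNG or JPEG image.
#' @return an [rgb_image()] with 8-bit values.
#' @export
read_image_rgb <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  im <- EBImage::readImage(path)
  d <- dim(im)
  a <- EBImage::imageData(im)
  if (length(d) == 2L) {
    a <- array(rep(a, 3L), dim = c(d[1], d[2], 3L))
  } else if (d[3] >= 3L) {
    a <- a[, , 1:3, drop = FALSE]
  } else {
    a <- array(rep(a[, , 1L], 3L), dim = c(d[1], d[2], 3L))
  }
  rgb_image(round(a * 255))
}

#' Write an `rgb_image` to disk
#'
#' @param img an [rgb_image()].
#' @param path output path; format follows the file extension
#'   (`.png`, `.jpg`).
#' @return `path`, invisibly.
#' @export
write_image_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Construct a binary mask
#'
#' A mask is a `W x H` logical matrix aligned with its source image;
#' dimension agreement is checked at construction when a reference image
#' is supplied.
#'
#' @param pixels logical matrix (`W x H`).
#' @param ref optional [rgb_image()] or mask whose dimensions the new
#'   mask must match.
#' @return a logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(pixels, ref = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  if (anyNA(pixels)) stop("mask may not contain NA")
  if (!is.null(ref)) {
    rd <- dim(ref)[1:2]
    if (!identical(dim(pixels), as.integer(rd)) &&
        !identical(as.integer(dim(pixels)), as.integer(rd)))
      stop("mask dimensions do not match the source image")
  }
  class(pixels) <- c("binary_mask", class(pixels))
  pixels
}

as_plain_mask <- function(m) {
  m <- unclass(m)
  attr(m, "class") <- NULL
  m
}

#' Read / write a binary mask as a single-channel PNG (0/255)
#'
#' @param mask a logical `W x H` matrix.
#' @param path file path.
#' @return `read_mask_png` returns a `binary_mask`; `write_mask_png`
#'   returns `path` invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_plain_mask(mask)
  EBImage::writeImage(EBImage::Image(m * 1.0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  binary_mask(a > 0.5)
}

#' YUV red-difference chroma (V) channel
#'
#' Converts an RGB image to the YUV colour system (BT.601, full range)
#' and returns the V (red-difference, Cr) channel on the 0-255 scale:
#' `V = 0.5 R - 0.418688 G - 0.081312 B + 128`.
#'
#' @param img an [rgb_image()].
#' @return numeric `W x H` matrix of V values in `[0, 255]`.
#' @export
yuv_v_channel <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img)
  v <- 0.5 * a[, , 1] - 0.418688 * a[, , 2] - 0.081312 * a[, , 3] + 128
  pmin(pmax(v, 0), 255)
}

#' Hue and brightness channels (HSB)
#'
#' Converts an RGB image to the hue-saturation-brightness system and
#' returns the hue on the 0-179 half-degree scale (so pure green, 120
#' degrees, is hue 60) and the brightness on the 0-255 scale, the
#' conventions under which the fluorescence thresholds are expressed.
#'
#' @param img an [rgb_image()].
#' @return list with numeric `W x H` matrices `h` (0-179+) and `b`
#'   (0-255). The hue of achromatic pixels (R = G = B) is 0.
#' @export
hsb_channels <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  a <- unclass(img)
  w <- dim(a)[1]; ht <- dim(a)[2]
  r <- as.vector(a[, , 1]); g <- as.vector(a[, , 2]); b <- as.vector(a[, , 3])
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  delta <- mx - mn
  hdeg <- numeric(length(r))
  is_r <- delta > 0 & mx == r
  is_g <- delta > 0 & mx == g & !is_r
  is_b <- delta > 0 & !is_r & !is_g
  hdeg[is_r] <- (60 * ((g[is_r] - b[is_r]) / delta[is_r]) + 360) %% 360
  hdeg[is_g] <- 60 * ((b[is_g] - r[is_g]) / delta[is_g]) + 120
  hdeg[is_b] <- 60 * ((r[is_b] - g[is_b]) / delta[is_b]) + 240
  list(h = matrix(hdeg / 2, w, ht), b = matrix(mx, w, ht))
}

#' Otsu global threshold of a channel matrix
#'
#' Finds the threshold maximizing the between-class variance of the
#' 256-bin histogram of an 8-bit channel. Used by [segment_hand()].
#'
#' @param channel numeric matrix with values in `[0, 255]`.
#' @return scalar threshold on the 0-255 scale; pixels strictly above it
#'   form the higher-mean class.
#' @export
otsu_threshold <- function(channel) {
  if (diff(range(channel)) == 0)
    stop("no-threshold: channel is constant, Otsu split undefined")
  thr <- EBImage::otsu(EBImage::Image(channel / 255), range = c(0, 1),
                       levels = 256)
  thr * 255
}
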