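#' @useDynLib drcctnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Internal conventions: a raster image is a numeric H x W x 3 array holding
# whole-number intensities in [0, 255], channel order R, G, B. All module
# boundaries exchange RGB; YUV exists only inside the CLAHE stage.

#' Validate and coerce a raster image
#'
#' Checks that `x` is a height x width x 3 array of intensities in
#' \[0, 255\] and returns it as a numeric array of whole-valued doubles.
#'
#' @param x An H x W x 3 numeric array.
#' @return The validated array.
#' @export
as_raster <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("raster image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("raster image must have positive dimensions", call. = FALSE)
  x <- x * 1.0
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("raster intensities must lie in [0, 255]", call. = FALSE)
  x
}

# round half away from zero, the convention used for all fractional
# intermediate values before storing back into 8-bit range
round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# quantize a real-valued image back to the 8-bit integer grid
quantize255 <- function(x) round_away(clamp255(x))

#' Luminance (grayscale) plane of an RGB image
#'
#' Standard BT.601 luma weighting 0.299 R + 0.587 G + 0.114 B, rounded half
#' away from zero to the 8-bit grid.
#'
#' @param image A raster image (see [as_raster()]).
#' @return An H x W matrix of intensities in \[0, 255\].
#' @export
raster_gray <- function(image) {
  image <- as_raster(image)
  round_away(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
}

#' RGB to analog YUV conversion (BT.601)
#'
#' Converts to the analog YUV colour space used by the contrast-enhancement
#' stage: Y = 0.299 R + 0.587 G + 0.114 B, U = 0.492 (B - Y),
#' V = 0.877 (R - Y). Values are kept in double precision; Y lies in
#' \[0, 255\], U and V are signed.
#'
#' @param image A raster image.
#' @return An H x W x 3 double array with planes Y, U, V.
#' @export
rgb_to_yuv <- function(image) {
  image <- as_raster(image)
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  u <- 0.492 * (image[, , 3] - y)
  v <- 0.877 * (image[, , 1] - y)
  out <- array(0, dim = dim(image))
  out[, , 1] <- y; out[, , 2] <- u; out[, , 3] <- v
  out
}

#' Analog YUV back to RGB (BT.601)
#'
#' Inverse of [rgb_to_yuv()]; output is quantized to the 8-bit grid and
#' clamped to \[0, 255\].
#'
#' @param yuv An H x W x 3 array with planes Y, U, V.
#' @return A raster image.
#' @export
yuv_to_rgb <- function(yuv) {
  stopifnot(is.array(yuv), length(dim(yuv)) == 3L, dim(yuv)[3] == 3L)
  y <- yuv[, , 1]; u <- yuv[, , 2]; v <- yuv[, , 3]
  r <- y + v / 0.877
  b <- y + u / 0.492
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, dim = dim(yuv))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  quantize255(out)
}

#' Read a raster image from disk
#'
#' Reads a PNG (or TIFF) file into the package's 0-255 RGB array convention.
#' Grayscale files are replicated across channels; alpha is dropped.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return A raster image.
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = EBImage::imageData(EBImage::readImage(path)),
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  if (ext %in% c("tif", "tiff")) {
    # EBImage arrays are x,y ordered; transpose back to row = y
    x <- if (length(dim(x)) == 2L) t(x) else aperm(x, c(2L, 1L, 3L))
  }
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  as_raster(round_away(x * 255))
}

#' Write a raster image to a PNG file
#'
#' @param image A raster image.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_raster <- function(image, path) {
  image <- as_raster(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Resize a raster image
#'
#' Bilinear resampling to the requested height and width (used to bring
#' preprocessed fundus crops down to the classifier's input size).
#'
#' @param image A raster image.
#' @param height,width Target dimensions in pixels.
#' @return A raster image of the requested size.
#' @export
raster_resize <- function(image, height, width) {
  image <- as_raster(image)
  if (height == dim(image)[1] && width == dim(image)[2]) return(image)
  eb <- EBImage::Image(aperm(image, c(2L, 1L, 3L)) / 255, colormode = "Color")
  out <- EBImage::resize(eb, w = width, h = height)
  quantize255(aperm(EBImage::imageData(out), c(2L, 1L, 3L)) * 255)
}

# run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
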