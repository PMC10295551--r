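#' Preprocessing configuration for fundus photographs
#'
#' Collects the tunable parameters of the preprocessing chain: Otsu
#' thresholding range, morphological-opening kernel, non-local-means windows
#' and filter strength, and the CLAHE clip limit / tile grid applied to the
#' luminance channel.
#'
#' @param otsu_min,otsu_max Intensity range the grayscale image is clamped to
#'   before histogram thresholding (defaults 0 and 255, i.e. no clamping).
#' @param opening_kernel Integer `(rows, cols)` size of the rectangular
#'   structuring element for morphological opening. Default `c(10, 10)`.
#' @param nlm_template_window Odd patch size for non-local means (default 7).
#' @param nlm_search_window Odd search-window size (default 21).
#' @param nlm_strength Filter strength `h`; larger values smooth more.
#'   Default 3.
#' @param clahe_clip_limit Contrast-limiting clip factor (default 0.5).
#' @param clahe_tile_grid Integer `(rows, cols)` CLAHE tile grid, default
#'   `c(8, 8)`.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(otsu_min = 0, otsu_max = 255,
                              opening_kernel = c(10, 10),
                              nlm_template_window = 7, nlm_search_window = 21,
                              nlm_strength = 3,
                              clahe_clip_limit = 0.5, clahe_tile_grid = c(8, 8)) {
  stopifnot(otsu_min >= 0, otsu_max <= 255, otsu_min < otsu_max,
            length(opening_kernel) == 2, all(opening_kernel >= 1),
            length(clahe_tile_grid) == 2, all(clahe_tile_grid >= 1),
            clahe_clip_limit > 0, nlm_strength > 0)
  if (nlm_template_window %% 2 != 1 || nlm_template_window < 1)
    stop("nlm_template_window must be odd and positive", call. = FALSE)
  if (nlm_search_window %% 2 != 1 || nlm_search_window < 1)
    stop("nlm_search_window must be odd and positive", call. = FALSE)
  structure(list(
    otsu_min = otsu_min, otsu_max = otsu_max,
    opening_kernel = as.integer(opening_kernel),
    nlm_template_window = as.integer(nlm_template_window),
    nlm_search_window = as.integer(nlm_search_window),
    nlm_strength = nlm_strength,
    clahe_clip_limit = clahe_clip_limit,
    clahe_tile_grid = as.integer(clahe_tile_grid)
  ), class = "preprocess_config")
}

#' Otsu threshold and foreground mask
#'
#' Converts the image to its luminance plane, clamps it to
#' `[otsu_min, otsu_max]`, and finds the global threshold maximizing the
#' between-class intensity variance of the 8-bit histogram. The mask is 255
#' where the gray value strictly exceeds the threshold and 0 elsewhere; on a
#' fundus photograph this separates the bright retina disc from the black
#' camera background.
#'
#' @param image A raster image (RGB, 0-255).
#' @param cfg A [preprocess_config()].
#' @return A list with `threshold` (integer in 0..254) and `mask`
#'   (H x W matrix of 0/255).
#' @export
otsu_mask <- function(image, cfg = preprocess_config()) {
  gray <- pmin(pmax(raster_gray(image), cfg$otsu_min), cfg$otsu_max)
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: image has a single intensity level, no two classes exist",
         call. = FALSE)
  p <- counts / sum(counts)
  omega <- cumsum(p)               # class-0 mass for threshold t = 0..255
  mu <- cumsum(p * (0:255))        # class-0 first moment
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254 (class 0: <= t)
  w0 <- omega[1:255]
  sigma_b <- (mu_t * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  threshold <- which.max(sigma_b) - 1L   # first maximizer
  mask <- ifelse(gray > threshold, 255, 0)
  dim(mask) <- dim(gray)
  list(threshold = threshold, mask = mask)
}

#' Bounding box of the largest foreground component
#'
#' Labels the connected foreground components of a binary mask and returns
#' the tight bounding box of the one with the largest pixel area (ties broken
#' by first appearance in row-major scan order). Coordinates follow the
#' 0-based, half-open convention `[row0, row1) x [col0, col1)`.
#'
#' @param mask An H x W matrix with values 0/255 (non-zero = foreground).
#' @return Integer vector `c(row0, col0, row1, col1)` of class `bbox`.
#' @export
largest_contour_bbox <- function(mask) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) stop("no foreground pixels in mask", call. = FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(mask > 0))
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # row-major scan order: rows outermost
    H <- nrow(mask); W <- ncol(mask)
    rows <- row(lab); cols <- col(lab)
    first <- vapply(best, function(l) {
      sel <- lab == l
      min((rows[sel] - 1L) * W + cols[sel])
    }, numeric(1))
    best <- best[which.min(first)]
  }
  sel <- lab == best
  r <- range(row(lab)[sel]); c <- range(col(lab)[sel])
  structure(c(row0 = r[1] - 1L, col0 = c[1] - 1L, row1 = r[2], col1 = c[2]),
            class = "bbox")
}

#' Crop an image to a bounding box
#'
#' @param image A raster image.
#' @param box A `bbox` as returned by [largest_contour_bbox()] (0-based,
#'   half-open).
#' @return The cropped raster image of size `(row1-row0) x (col1-col0)`.
#' @export
crop_to_roi <- function(image, box) {
  image <- as_raster(image)
  b <- as.integer(box)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (length(b) != 4L || b[1] < 0 || b[2] < 0 || b[3] > H || b[4] > W ||
      b[1] >= b[3] || b[2] >= b[4])
    stop("bounding box out of image bounds", call. = FALSE)
  image[(b[1] + 1L):b[3], (b[2] + 1L):b[4], , drop = FALSE]
}

# separable running min/max over a rectangular window; offsets [lo, hi]
# relative to each pixel, window clipped at borders (pad = +/- Inf)
run_extreme <- function(m, lo, hi, fun, pad) {
  out <- matrix(pad, nrow(m), ncol(m))
  H <- nrow(m)
  for (a in lo:hi) {
    src <- (1:H) + a
    ok <- src >= 1 & src <= H
    out[ok, ] <- fun(out[ok, , drop = FALSE], m[src[ok], , drop = FALSE])
  }
  out
}

box_filter_dim <- function(m, lo_r, hi_r, lo_c, hi_c, fun, pad) {
  m <- run_extreme(m, lo_r, hi_r, fun, pad)
  t(run_extreme(t(m), lo_c, hi_c, fun, pad))
}

#' Morphological opening of a colour image
#'
#' Erosion followed by dilation with a flat rectangular structuring element,
#' applied independently to each channel. The dilation uses the reflected
#' structuring element (the adjoint pair), so the operation is a true
#' morphological opening: idempotent and never exceeding the input. Removes
#' bright structures smaller than the kernel, such as specular spurs left by
#' the camera.
#'
#' @param image A raster image.
#' @param cfg A [preprocess_config()]; `cfg$opening_kernel` gives the
#'   `(rows, cols)` kernel size, default `c(10, 10)`.
#' @return A raster image of identical size.
#' @export
morphological_open <- function(image, cfg = preprocess_config()) {
  image <- as_raster(image)
  k <- cfg$opening_kernel
  if (k[1] > dim(image)[1] || k[2] > dim(image)[2])
    stop("opening kernel larger than image", call. = FALSE)
  # erosion window offsets [-l, r]; dilation uses the reflection [-r, l]
  l_r <- (k[1] - 1L) %/% 2L; r_r <- k[1] - 1L - l_r
  l_c <- (k[2] - 1L) %/% 2L; r_c <- k[2] - 1L - l_c
  out <- image
  for (ch in 1:3) {
    er <- box_filter_dim(image[, , ch], -l_r, r_r, -l_c, r_c, pmin, Inf)
    out[, , ch] <- box_filter_dim(er, -r_r, l_r, -r_c, l_c, pmax, -Inf)
  }
  out
}

#' Non-local means denoising
#'
#' Replaces each pixel by a patch-similarity-weighted average of the pixels
#' in a surrounding search window: weights are a decreasing (Gaussian)
#' function of the mean squared difference between the two pixels' patches,
#' normalized so they sum to one. Patch and search windows are clipped at
#' image borders. A constant image is a fixed point (all patch distances are
#' zero, weights uniform).
#'
#' @param image A raster image.
#' @param cfg A [preprocess_config()]; uses `nlm_template_window` (patch
#'   size, default 7), `nlm_search_window` (default 21) and `nlm_strength`
#'   (filter strength h, default 3).
#' @return A denoised raster image of identical size.
#' @export
nlm_denoise <- function(image, cfg = preprocess_config()) {
  image <- as_raster(image)
  if (cfg$nlm_template_window %% 2 != 1 || cfg$nlm_search_window %% 2 != 1)
    stop("non-local means windows must be odd", call. = FALSE)
  out <- nlm_denoise_cpp(as.numeric(image), dim(image)[1], dim(image)[2],
                         cfg$nlm_template_window, cfg$nlm_search_window,
                         cfg$nlm_strength)
  quantize255(array(out, dim = dim(image)))
}

#' Contrast-limited adaptive histogram equalization of one plane
#'
#' Tile-based CLAHE with a 256-bin histogram per tile: each tile's
#' histogram is clipped at `limit` times the mean bin count (never below
#' one count), the clipped excess is redistributed uniformly, the tile's
#' mapping is the rescaled cumulative histogram, and every pixel is
#' bilinearly interpolated between the mappings of its four surrounding
#' tile centres. The plane is replicate-padded so the tile grid divides it
#' exactly, and cropped back afterwards.
#'
#' @param y01 Numeric matrix with values in \[0, 1\].
#' @param grid Integer `(rows, cols)` tile grid.
#' @param limit Clip-limit factor (> 0).
#' @return The equalized matrix, values in \[0, 1\].
#' @export
clahe_plane <- function(y01, grid = c(8, 8), limit = 0.5) {
  bins <- 256L
  H <- nrow(y01); W <- ncol(y01)
  gr <- as.integer(grid[1]); gc <- as.integer(grid[2])
  th <- as.integer(ceiling(H / gr)); tw <- as.integer(ceiling(W / gc))
  Hp <- th * gr; Wp <- tw * gc
  yp <- y01[c(seq_len(H), rep(H, Hp - H)), c(seq_len(W), rep(W, Wp - W)),
            drop = FALSE]
  q <- matrix(pmin(floor(yp * bins), bins - 1L), Hp, Wp)
  area <- th * tw
  clip <- max(1, floor(limit * area / bins))
  luts <- array(0, c(bins, gr, gc))
  for (i in seq_len(gr)) {
    for (j in seq_len(gc)) {
      h <- tabulate(q[((i - 1L) * th + 1L):(i * th),
                      ((j - 1L) * tw + 1L):(j * tw)] + 1L, bins)
      cl <- pmin(h, clip)
      excess <- area - sum(cl)
      cl <- cl + excess %/% bins
      res <- excess %% bins
      if (res > 0) {
        # spread the residual evenly over the histogram
        idx <- seq(1L, by = max(1L, bins %/% res), length.out = res)
        cl[idx] <- cl[idx] + 1L
      }
      luts[, i, j] <- round(cumsum(cl) * (bins - 1) / area) / (bins - 1)
    }
  }
  # tile-space coordinates of pixel centres; edges clamp to the outer tiles
  rpos <- (seq_len(Hp) - 0.5) / th + 0.5
  i0 <- pmin(pmax(floor(rpos), 1), gr); i1 <- pmin(i0 + 1, gr)
  wr <- pmin(pmax(rpos - i0, 0), 1)
  cpos <- (seq_len(Wp) - 0.5) / tw + 0.5
  j0 <- pmin(pmax(floor(cpos), 1), gc); j1 <- pmin(j0 + 1, gc)
  wc <- pmin(pmax(cpos - j0, 0), 1)
  qi <- as.vector(q) + 1L
  I0 <- rep(i0, times = Wp); I1 <- rep(i1, times = Wp); WR <- rep(wr, times = Wp)
  J0 <- rep(j0, each = Hp); J1 <- rep(j1, each = Hp); WC <- rep(wc, each = Hp)
  out <- (1 - WR) * (1 - WC) * luts[cbind(qi, I0, J0)] +
    WR * (1 - WC) * luts[cbind(qi, I1, J0)] +
    (1 - WR) * WC * luts[cbind(qi, I0, J1)] +
    WR * WC * luts[cbind(qi, I1, J1)]
  matrix(out, Hp, Wp)[seq_len(H), seq_len(W)]
}

#' Contrast-limited adaptive histogram equalization on the luminance channel
#'
#' Converts RGB to analog YUV (BT.601), applies [clahe_plane()] to the Y
#' plane only (clip limit and tile grid from the configuration), and
#' converts back to RGB. Chrominance (U, V) passes through untouched, so
#' colour shifts are bounded by the integer rounding of the final
#' conversion.
#'
#' @param image A raster image.
#' @param cfg A [preprocess_config()].
#' @return A contrast-enhanced raster image of identical size.
#' @export
clahe_luminance <- function(image, cfg = preprocess_config()) {
  image <- as_raster(image)
  yuv <- rgb_to_yuv(image)
  y01 <- pmin(pmax(yuv[, , 1] / 255, 0), 1)
  yuv[, , 1] <- clahe_plane(y01, cfg$clahe_tile_grid, cfg$clahe_clip_limit) * 255
  yuv_to_rgb(yuv)
}

#' Full fundus preprocessing chain
#'
#' Composes the artifact-removal, denoising and enhancement stages in order:
#' Otsu mask, largest-component bounding box, ROI crop, morphological
#' opening, non-local means denoising, CLAHE on the luminance channel.
#' Errors raised by a stage are re-signalled with the stage name attached.
#'
#' @param image A raster image with some non-black content.
#' @param cfg A [preprocess_config()].
#' @return The preprocessed RGB raster image (dimensions equal the ROI
#'   bounding box).
#' @export
preprocess_image <- function(image, cfg = preprocess_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  om <- stage("otsu_mask", otsu_mask(image, cfg))
  box <- stage("largest_contour_bbox", largest_contour_bbox(om$mask))
  roi <- stage("crop_to_roi", crop_to_roi(image, box))
  opened <- stage("morphological_open", morphological_open(roi, cfg))
  den <- stage("nlm_denoise", nlm_denoise(opened, cfg))
  stage("clahe_luminance", clahe_luminance(den, cfg))
}

#' Batch preprocessing driven by a manifest
#'
#' Applies [preprocess_image()] to every entry of a dataset manifest,
#' reading PNGs from `image_dir` and writing processed PNGs (mirroring the
#' input layout) plus a new manifest CSV to `out_dir`.
#'
#' @param manifest A [dr_manifest()] or a path to a manifest CSV with
#'   columns `path,label`.
#' @param image_dir Directory containing the input images.
#' @param out_dir Output directory (created if missing).
#' @param cfg A [preprocess_config()].
#' @return The new manifest (invisibly), with `image_ref` pointing into
#'   `out_dir`.
#' @export
preprocess_batch <- function(manifest, image_dir, out_dir,
                             cfg = preprocess_config()) {
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(man))) {
    img <- read_raster(file.path(image_dir, man$image_ref[i]))
    out <- preprocess_image(img, cfg)
    dest <- file.path(out_dir, man$image_ref[i])
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    write_raster(out, dest)
  }
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  invisible(man)
}
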