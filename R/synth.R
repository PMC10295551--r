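#' Synthetic fundus generator configuration
#'
#' Parameters of the seeded generator of fundus-like test images: a bright
#' reddish retina disc with radial falloff on a black camera frame, an optic
#' disc highlight, random-walk vessel curves, and grade-correlated lesion
#' counts — dark dots (microaneurysm/haemorrhage stand-ins) and bright
#' yellowish blobs (exudate stand-ins) whose expected counts are Poisson
#' rates increasing with grade. The generator's contract is pipeline
#' exercisability and a monotone class signal, not clinical realism.
#'
#' @param canvas Square canvas size in pixels (default 128, so the
#'   preprocessing windows operate meaningfully before downscaling).
#' @param disc_radius_range Disc radius as a fraction of the canvas
#'   (default `c(0.32, 0.42)`).
#' @param margin Minimum black border in pixels kept around the disc
#'   (default 8).
#' @param vessels Integer range `c(min, max)` of vessel walks (default
#'   `c(3, 5)`).
#' @param lesion_rate Expected dark-dot count per grade 0..4; must be 0 at
#'   grade 0 and strictly increasing (default `c(0, 5, 12, 22, 35)`).
#' @param exudate_rate Expected bright-blob count per grade (default
#'   `c(0, 2, 5, 9, 14)`). Blobs are drawn larger than the morphological
#'   opening kernel so the class signal survives the preprocessing chain.
#' @param noise_sigma Gaussian pixel-noise standard deviation in intensity
#'   levels (default 3).
#' @param seed Base seed used by [generate_fundus_dataset()].
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(canvas = 128, disc_radius_range = c(0.34, 0.42),
                         margin = 8, vessels = c(3, 5),
                         lesion_rate = c(0, 5, 12, 22, 35),
                         exudate_rate = c(0, 2, 5, 9, 14),
                         noise_sigma = 3, seed = 1) {
  stopifnot(canvas >= 32, length(lesion_rate) == 5, length(exudate_rate) == 5,
            length(disc_radius_range) == 2, diff(disc_radius_range) >= 0)
  if (lesion_rate[1] != 0) stop("lesion_rate must be 0 at grade 0", call. = FALSE)
  if (any(diff(lesion_rate) <= 0))
    stop("lesion_rate must be strictly increasing over grades", call. = FALSE)
  structure(list(canvas = as.integer(canvas),
                 disc_radius_range = disc_radius_range,
                 margin = as.integer(margin), vessels = as.integer(vessels),
                 lesion_rate = lesion_rate, exudate_rate = exudate_rate,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "synth_config")
}

# paint a filled disc of given radius into channel matrices (in place style)
paint_blob <- function(planes, cy, cx, r, col, mode = c("set", "scale", "add")) {
  mode <- match.arg(mode)
  H <- nrow(planes[[1]]); W <- ncol(planes[[1]])
  ys <- max(1, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(W, ceiling(cx + r))
  if (!length(ys) || !length(xs)) return(planes)
  sub <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2) <= r^2
  for (ch in 1:3) {
    m <- planes[[ch]][ys, xs, drop = FALSE]
    m[sub] <- switch(mode, set = col[ch], scale = m[sub] * col[ch],
                     add = m[sub] + col[ch])
    planes[[ch]][ys, xs] <- m
  }
  planes
}

#' Generate one synthetic fundus image
#'
#' Deterministic given `(seed, grade)`: the same pair always yields a
#' bit-identical image. Lesion and exudate counts are Poisson draws with
#' the per-grade rates from the configuration. Ground-truth metadata
#' (disc centre, radius, planted lesion count) is attached as attributes.
#'
#' @param grade Severity grade in 0..4.
#' @param cfg A [synth_config()].
#' @param seed Integer seed for this image.
#' @return A raster image of size `canvas x canvas` with attributes
#'   `center`, `radius`, `n_lesions`, `n_exudates`.
#' @export
generate_fundus <- function(grade, cfg = synth_config(), seed = cfg$seed) {
  if (length(grade) != 1L || is.na(grade) || grade < 0 || grade > 4)
    stop("grade must be a single value in 0..4", call. = FALSE)
  grade <- as.integer(grade)
  n <- cfg$canvas
  with_seed(seed * 5L + grade, {
    r_max <- n / 2 - cfg$margin
    radius <- min(stats::runif(1, cfg$disc_radius_range[1], cfg$disc_radius_range[2]) * n,
                  r_max)
    cy <- n / 2 + stats::runif(1, -3, 3)
    cx <- n / 2 + stats::runif(1, -3, 3)
    dist2 <- outer((1:n) - cy, (1:n) - cx, function(a, b) a^2 + b^2)
    inside <- dist2 <= radius^2
    falloff <- pmax(0, 1 - dist2 / radius^2)

    planes <- list(inside * (120 + 100 * sqrt(falloff)),
                   inside * (45 + 60 * falloff),
                   inside * (18 + 25 * falloff))

    # optic-disc highlight: bright spot offset from centre
    ang <- stats::runif(1, 0, 2 * pi)
    od <- c(cy + 0.45 * radius * sin(ang), cx + 0.45 * radius * cos(ang))
    planes <- paint_blob(planes, od[1], od[2], 0.16 * radius,
                         c(70, 70, 45), mode = "add")

    # vessels: dark random walks out of the optic disc
    nv <- sample(cfg$vessels[1]:cfg$vessels[2], 1)
    for (v in seq_len(nv)) {
      pos <- od
      dir <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(as.integer(2.2 * radius))) {
        dir <- dir + stats::rnorm(1, 0, 0.28)
        pos <- pos + c(sin(dir), cos(dir))
        if (sum((pos - c(cy, cx))^2) > (0.95 * radius)^2) break
        planes <- paint_blob(planes, pos[1], pos[2], 1.1,
                             c(0.45, 0.4, 0.4), mode = "scale")
      }
    }

    # grade-correlated lesions: dark dots and bright blobs inside the disc
    # lesion scale follows the canvas so the signal survives downscaling;
    # exudate blobs exceed the 10-px opening kernel, which erases smaller
    # bright structures
    scale_px <- n / 128
    n_les <- stats::rpois(1, cfg$lesion_rate[grade + 1L])
    for (i in seq_len(n_les)) {
      rr <- stats::runif(1, 0, 0.8 * radius)
      aa <- stats::runif(1, 0, 2 * pi)
      planes <- paint_blob(planes, cy + rr * sin(aa), cx + rr * cos(aa),
                           stats::runif(1, 3.2, 4.5) * scale_px,
                           c(0.25, 0.25, 0.25), mode = "scale")
    }
    n_exu <- stats::rpois(1, cfg$exudate_rate[grade + 1L])
    for (i in seq_len(n_exu)) {
      rr <- stats::runif(1, 0, 0.75 * radius)
      aa <- stats::runif(1, 0, 2 * pi)
      planes <- paint_blob(planes, cy + rr * sin(aa), cx + rr * cos(aa),
                           stats::runif(1, 6, 8.5) * scale_px,
                           c(90, 85, 20), mode = "add")
    }

    img <- array(0, dim = c(n, n, 3L))
    for (ch in 1:3) {
      m <- planes[[ch]]
      if (cfg$noise_sigma > 0)
        m <- m + inside * stats::rnorm(n * n, 0, cfg$noise_sigma)
      img[, , ch] <- m
    }
    img <- quantize255(img)
    attr(img, "center") <- c(cy, cx)
    attr(img, "radius") <- radius
    attr(img, "n_lesions") <- n_les
    attr(img, "n_exudates") <- n_exu
    img
  })
}

#' Generate a synthetic fundus dataset
#'
#' Produces `n_per_grade` images per grade (or an unbalanced per-grade count
#' vector, useful for exercising the under-sampling stage) together with a
#' [dr_manifest()]. Deterministic given `cfg$seed`.
#'
#' @param n_per_grade A single count, or a length-5 vector of per-grade
#'   counts.
#' @param cfg A [synth_config()].
#' @param dir Optional directory: when given, images are written as PNGs
#'   named by their manifest reference.
#' @return A list with `images` (named list of raster images; keys match
#'   `manifest$image_ref`) and `manifest`.
#' @export
generate_fundus_dataset <- function(n_per_grade, cfg = synth_config(), dir = NULL) {
  counts <- if (length(n_per_grade) == 1L) rep(as.integer(n_per_grade), 5L)
            else as.integer(n_per_grade)
  stopifnot(length(counts) == 5L, all(counts >= 0))
  seeds <- with_seed(cfg$seed, sample.int(.Machine$integer.max %/% 8L, sum(counts)))
  refs <- character(0); grades <- integer(0)
  images <- vector("list", sum(counts))
  k <- 0L
  for (g in 0:4) {
    for (i in seq_len(counts[g + 1L])) {
      k <- k + 1L
      ref <- sprintf("g%d_%04d.png", g, i)
      images[[k]] <- generate_fundus(g, cfg, seed = seeds[k])
      refs <- c(refs, ref); grades <- c(grades, g)
    }
  }
  names(images) <- refs
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ref in refs) write_raster(images[[ref]], file.path(dir, ref))
  }
  list(images = images, manifest = dr_manifest(refs, grades))
}
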