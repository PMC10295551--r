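#' Dataset manifest
#'
#' A manifest is the unit the balancing, splitting and counting stages
#' operate on: one row per image with its severity grade (0 = no DR through
#' 4 = proliferative DR) and split assignment.
#'
#' @param image_ref Character vector of unique image references (paths or
#'   fixture ids).
#' @param grade Integer vector of grades in 0..4.
#' @param split Character vector in `train`, `val`, `test`, `unassigned`
#'   (recycled; default `"unassigned"`).
#' @return A `data.frame` of class `dr_manifest` with columns `image_ref`,
#'   `grade`, `split`.
#' @export
dr_manifest <- function(image_ref, grade, split = "unassigned") {
  image_ref <- as.character(image_ref)
  grade <- as.integer(grade)
  if (length(image_ref) != length(grade))
    stop("image_ref and grade lengths differ", call. = FALSE)
  if (anyNA(grade) || any(grade < 0L | grade > 4L))
    stop("grades must lie in 0..4", call. = FALSE)
  if (anyDuplicated(image_ref))
    stop("manifest entries must be unique by image_ref", call. = FALSE)
  split <- rep_len(as.character(split), length(image_ref))
  if (!all(split %in% c("train", "val", "test", "unassigned")))
    stop("split must be train, val, test or unassigned", call. = FALSE)
  structure(data.frame(image_ref = image_ref, grade = grade, split = split,
                       stringsAsFactors = FALSE),
            class = c("dr_manifest", "data.frame"))
}

#' Per-grade image counts of a manifest
#'
#' @param manifest A [dr_manifest()].
#' @return A named integer vector over grades "0".."4".
#' @export
class_counts <- function(manifest) {
  counts <- tabulate(manifest$grade + 1L, nbins = 5L)
  names(counts) <- as.character(0:4)
  counts
}

#' Read / write a manifest CSV
#'
#' CSV columns are `path,label[,split]`, the interchange format used by the
#' batch tools.
#'
#' @param path CSV file path.
#' @return For `read_manifest`, a [dr_manifest()].
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  split <- if ("split" %in% names(df)) df$split else "unassigned"
  dr_manifest(df$path, df$label, split)
}

#' @param manifest A [dr_manifest()].
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    data.frame(path = manifest$image_ref, label = manifest$grade,
               split = manifest$split),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Balancing configuration
#'
#' Controls the random under-sampling stage. In `auto_mean_of_three_smallest`
#' mode the cap is the integer-truncated mean of the three smallest class
#' counts; `explicit` mode (the default) uses `explicit_cap` directly, which
#' defaults to 2384, the threshold used to balance the merged five-source
#' fundus collection.
#'
#' @param cap_mode `"explicit"` or `"auto_mean_of_three_smallest"`.
#' @param explicit_cap Positive cap used in explicit mode (default 2384).
#' @param rng_seed Integer seed for the uniform random selection.
#' @return An object of class `balance_config`.
#' @export
balance_config <- function(cap_mode = c("explicit", "auto_mean_of_three_smallest"),
                           explicit_cap = 2384, rng_seed = 17) {
  cap_mode <- match.arg(cap_mode)
  stopifnot(explicit_cap > 0)
  structure(list(cap_mode = cap_mode, explicit_cap = as.integer(explicit_cap),
                 rng_seed = as.integer(rng_seed)),
            class = "balance_config")
}

#' Under-sampling cap from per-class counts
#'
#' In auto mode, the integer-truncated arithmetic mean of the three smallest
#' of the five class counts; in explicit mode, `cfg$explicit_cap` unchanged.
#'
#' @param counts Named count vector over exactly five classes, all positive.
#' @param cfg A [balance_config()].
#' @return The integer cap.
#' @export
compute_cap <- function(counts, cfg = balance_config()) {
  if (length(counts) != 5L || any(counts <= 0))
    stop("exactly five classes with positive counts are required", call. = FALSE)
  if (cfg$cap_mode == "explicit") return(cfg$explicit_cap)
  as.integer(floor(mean(sort(as.numeric(counts))[1:3])))
}

#' Random under-sampling of the two majority grades
#'
#' The two grades with the most images (the majority classes of the merged
#' fundus collection) are reduced to exactly the cap by uniform random
#' selection without replacement (seeded, reproducible), provided they
#' exceed it; every other grade is untouched even when above the cap —
#' the subsequent augmentation stage, not further under-sampling, narrows
#' the remaining imbalance. Retained entries keep their original manifest
#' order.
#'
#' @param manifest A [dr_manifest()].
#' @param cfg A [balance_config()].
#' @return The under-sampled manifest.
#' @export
undersample <- function(manifest, cfg = balance_config()) {
  counts <- class_counts(manifest)
  cap <- compute_cap(counts, cfg)
  majority <- as.integer(names(sort(counts, decreasing = TRUE)[1:2]))
  keep <- logical(nrow(manifest))
  with_seed(cfg$rng_seed, {
    for (g in 0:4) {
      idx <- which(manifest$grade == g)
      if (g %in% majority && length(idx) > cap) idx <- sort(sample(idx, cap))
      keep[idx] <- TRUE
    }
  })
  out <- manifest[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The twelve augmentation operations
#'
#' Builds the default list of the twelve augmentation transforms applied to
#' every balanced image: two zooms (factors 1.2 and 1.5), vertical flip,
#' combined horizontal+vertical flip, rotations by +90 and -90 degrees, and
#' six photometric adjustments (brightness, sharpness, contrast, colour
#' saturation, seeded colour jitter, gamma correction). The photometric
#' magnitudes are mild visibility-enhancing defaults and are configurable.
#'
#' @param brightness,contrast,color Multiplicative enhancement factors
#'   (defaults 1.2).
#' @param sharpness Sharpness factor (default 1.5); 1 leaves the image
#'   unchanged.
#' @param gamma Gamma exponent (default 0.8).
#' @param jitter_range Half-width of the uniform per-channel jitter offsets
#'   in intensity levels (default 10).
#' @param jitter_seed Seed for the jitter draw (default 1).
#' @return A named list of 12 augmentation op descriptors.
#' @export
augmentation_ops <- function(brightness = 1.2, contrast = 1.2, sharpness = 1.5,
                             color = 1.2, gamma = 0.8,
                             jitter_range = 10, jitter_seed = 1) {
  ops <- list(
    list(name = "zoom_1_2", magnitude = 1.2),
    list(name = "zoom_1_5", magnitude = 1.5),
    list(name = "flip_vertical"),
    list(name = "flip_horizontal_vertical"),
    list(name = "rotate_p90"),
    list(name = "rotate_m90"),
    list(name = "brightness", magnitude = brightness),
    list(name = "sharpness", magnitude = sharpness),
    list(name = "contrast", magnitude = contrast),
    list(name = "color", magnitude = color),
    list(name = "color_jitter", magnitude = jitter_range, seed = jitter_seed),
    list(name = "gamma", magnitude = gamma)
  )
  names(ops) <- vapply(ops, `[[`, "", "name")
  ops
}

# PIL-style 3x3 smoothing kernel used by the sharpness enhancer
smooth3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  # replicate-padded neighbours
  up <- m[c(1, 1:(H - 1)), , drop = FALSE]
  dn <- m[c(2:H, H), , drop = FALSE]
  lf <- m[, c(1, 1:(W - 1)), drop = FALSE]
  rt <- m[, c(2:W, W), drop = FALSE]
  ul <- up[, c(1, 1:(W - 1)), drop = FALSE]
  ur <- up[, c(2:W, W), drop = FALSE]
  dl <- dn[, c(1, 1:(W - 1)), drop = FALSE]
  dr <- dn[, c(2:W, W), drop = FALSE]
  (5 * m + up + dn + lf + rt + ul + ur + dl + dr) / 13
}

zoom_image <- function(image, factor) {
  if (factor == 1) return(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  nh <- max(1L, as.integer(round(H * factor)))
  nw <- max(1L, as.integer(round(W * factor)))
  z <- raster_resize(image, nh, nw)
  if (factor > 1) {
    r0 <- (nh - H) %/% 2L; c0 <- (nw - W) %/% 2L
    z[(r0 + 1L):(r0 + H), (c0 + 1L):(c0 + W), , drop = FALSE]
  } else {
    out <- array(0, dim = dim(image))
    r0 <- (H - nh) %/% 2L; c0 <- (W - nw) %/% 2L
    out[(r0 + 1L):(r0 + nh), (c0 + 1L):(c0 + nw), ] <- z
    out
  }
}

rotate90 <- function(image, clockwise) {
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- array(0, dim = c(W, H, 3L))
  for (ch in 1:3) {
    m <- image[, , ch]
    out[, , ch] <- if (clockwise) t(m[H:1, , drop = FALSE]) else
      t(m)[W:1, , drop = FALSE]
  }
  out
}

apply_augmentation <- function(image, op) {
  image <- as_raster(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- switch(op$name,
    zoom_1_2 = , zoom_1_5 = zoom_image(image, op$magnitude),
    flip_vertical = image[H:1, , , drop = FALSE],
    flip_horizontal_vertical = image[H:1, W:1, , drop = FALSE],
    rotate_p90 = {
      r <- rotate90(image, clockwise = FALSE)
      if (H != W) raster_resize(r, H, W) else r
    },
    rotate_m90 = {
      r <- rotate90(image, clockwise = TRUE)
      if (H != W) raster_resize(r, H, W) else r
    },
    brightness = quantize255(image * op$magnitude),
    sharpness = {
      if (op$magnitude == 1) image else {
        out <- image
        for (ch in 1:3) {
          m <- image[, , ch]
          out[, , ch] <- m + (op$magnitude - 1) * (m - smooth3(m))
        }
        quantize255(out)
      }
    },
    contrast = {
      m <- mean(raster_gray(image))
      quantize255(m + op$magnitude * (image - m))
    },
    color = {
      gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
      out <- image
      for (ch in 1:3) out[, , ch] <- gray + op$magnitude * (image[, , ch] - gray)
      quantize255(out)
    },
    color_jitter = {
      offs <- with_seed(op$seed %||% 1L,
                        stats::runif(3, -op$magnitude, op$magnitude))
      out <- image
      for (ch in 1:3) out[, , ch] <- image[, , ch] + offs[ch]
      quantize255(out)
    },
    gamma = {
      if (op$magnitude == 1) image else
        quantize255(255 * (image / 255)^op$magnitude)
    },
    stop("unknown augmentation op: ", op$name, call. = FALSE)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a list of augmentation operations to one image
#'
#' Returns one transformed image per op, all with the input's dimensions
#' (zooms are centre-cropped back; rotations of non-square inputs are
#' resized back).
#'
#' @param image A raster image.
#' @param ops A list of op descriptors, default [augmentation_ops()].
#' @return A named list of raster images, one per op.
#' @export
augment_variants <- function(image, ops = augmentation_ops()) {
  lapply(ops, function(op) apply_augmentation(image, op))
}

#' Thirteen-fold manifest expansion by augmentation
#'
#' Every manifest entry is retained and contributes one variant per
#' augmentation op (12 by default), multiplying each per-class count by
#' exactly 13. Variant references are derived deterministically as
#' `<source>__<op name>`.
#'
#' @param manifest A [dr_manifest()] (typically the balanced one).
#' @param ops Augmentation op list, default [augmentation_ops()].
#' @return The expanded manifest.
#' @export
expand_manifest <- function(manifest, ops = augmentation_ops()) {
  op_names <- vapply(ops, `[[`, "", "name")
  refs <- c(manifest$image_ref,
            as.vector(t(outer(manifest$image_ref, op_names, paste, sep = "__"))))
  grades <- c(manifest$grade, rep(manifest$grade, each = length(ops)))
  splits <- c(manifest$split, rep(manifest$split, each = length(ops)))
  if (anyDuplicated(refs))
    stop("derived augmentation references collide with existing entries",
         call. = FALSE)
  dr_manifest(refs, grades, splits)
}

#' Expand an in-memory image set alongside its manifest
#'
#' Companion to [expand_manifest()]: given a named list of images keyed by
#' `image_ref`, computes every augmented variant under the derived
#' reference names.
#'
#' @param images Named list of raster images.
#' @param ops Augmentation op list, default [augmentation_ops()].
#' @return A named list containing the originals plus all variants.
#' @export
expand_images <- function(images, ops = augmentation_ops()) {
  out <- images
  for (ref in names(images)) {
    vars <- augment_variants(images[[ref]], ops)
    names(vars) <- paste(ref, vapply(ops, `[[`, "", "name"), sep = "__")
    out <- c(out, vars)
  }
  out
}
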