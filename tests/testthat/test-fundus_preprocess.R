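test_that("Otsu thresholding separates two-level images and rejects degenerate ones", {
  two <- array(rep(c(0, 0, 255, 255), 3), c(2, 2, 3))
  om <- otsu_mask(two)
  expect_equal(om$mask, matrix(c(0, 0, 255, 255), 2, 2))
  g <- raster_gray(two)
  expect_true(all(g[om$mask == 0] <= om$threshold))
  expect_true(all(g[om$mask == 255] > om$threshold))

  # 40 pixels at 10, 60 at 200: threshold equals the exhaustive maximizer
  img <- array(rep(c(rep(10, 40), rep(200, 60)), 3), c(10, 10, 3))
  expect_equal(otsu_mask(img)$threshold, otsu_bruteforce(raster_gray(img)))

  expect_error(otsu_mask(array(0, c(4, 4, 3))), "degenerate")
  expect_error(otsu_mask(array(131, c(4, 4, 3))), "degenerate")
})

test_that("Otsu threshold matches the brute-force oracle on random histograms", {
  set.seed(42)
  for (i in 1:100) {
    # mixtures of a few levels exercise ties and sparse histograms
    levels <- sample(0:255, sample(2:8, 1))
    g <- matrix(sample(levels, 144, replace = TRUE), 12, 12)
    if (length(unique(as.vector(g))) < 2) next
    img <- array(rep(g, 3), c(12, 12, 3))
    expect_identical(otsu_mask(img)$threshold, otsu_bruteforce(g))
  }
})

test_that("largest_contour_bbox returns the tight box of the biggest component", {
  m <- matrix(0, 10, 12)
  m[3:6, 4:8] <- 255                      # rows 2-5, cols 3-7 zero-based
  expect_equal(unclass(largest_contour_bbox(m)),
               c(row0 = 2, col0 = 3, row1 = 6, col1 = 8))

  # two components, areas 12 and 30: the larger one wins
  m2 <- matrix(0, 20, 20)
  m2[2:4, 2:5] <- 255                     # 3 x 4 = 12
  m2[10:14, 8:13] <- 255                  # 5 x 6 = 30
  expect_equal(unclass(largest_contour_bbox(m2)),
               c(row0 = 9, col0 = 7, row1 = 14, col1 = 13))

  expect_error(largest_contour_bbox(matrix(0, 5, 5)), "foreground")
})

test_that("crop_to_roi respects the half-open convention and bounds", {
  img <- random_image(10, 10, seed = 3)
  full <- structure(c(0L, 0L, 10L, 10L), class = "bbox")
  expect_equal(crop_to_roi(img, full), img)
  box <- structure(c(2L, 3L, 6L, 8L), class = "bbox")
  expect_equal(dim(crop_to_roi(img, box))[1:2], c(4L, 5L))
  bad <- structure(c(2L, 3L, 11L, 8L), class = "bbox")
  expect_error(crop_to_roi(img, bad), "bounds")
})

test_that("Otsu + contour + crop recovers a centred disc to within 2 px", {
  img <- disc_image(100, 30)
  box <- largest_contour_bbox(otsu_mask(img)$mask)
  out <- crop_to_roi(img, box)
  expect_true(all(abs(dim(out)[1:2] - 61) <= 2))
})

test_that("morphological opening is idempotent, anti-extensive and spur-removing", {
  flat <- array(99, c(20, 20, 3))
  expect_equal(morphological_open(flat), flat)

  spur <- array(0, c(30, 30, 3)); spur[15, 15, ] <- 255
  expect_true(all(morphological_open(spur) == 0))

  for (s in 1:5) {
    img <- random_image(25, 31, seed = s)
    o1 <- morphological_open(img)
    expect_true(all(o1 <= img))                      # anti-extensive
    expect_equal(morphological_open(o1), o1)         # idempotent
  }

  expect_error(morphological_open(random_image(8, 8, seed = 1)), "kernel")
})

test_that("non-local means keeps constants, damps noise and clips windows", {
  flat <- array(77, c(20, 20, 3))
  expect_identical(nlm_denoise(flat), flat)

  pert <- array(100, c(24, 24, 3)); pert[12, 12, ] <- 110
  out <- nlm_denoise(pert)
  expect_lt(var(as.vector(out)), var(as.vector(pert)))

  tiny <- random_image(10, 10, seed = 2)            # smaller than the search window
  expect_equal(dim(nlm_denoise(tiny)), dim(tiny))

  expect_error(nlm_denoise(flat, preprocess_config(nlm_template_window = 7,
                                                   nlm_search_window = 21)),
               NA)
  expect_error(preprocess_config(nlm_template_window = 6), "odd")
  expect_error(preprocess_config(nlm_search_window = 20), "odd")
})

test_that("CLAHE equalizes luminance only and fixes flat planes", {
  # constant mid-gray: output constant, value preserved up to rounding
  flat <- array(128, c(256, 256, 3))
  out <- clahe_luminance(flat)
  expect_equal(length(unique(as.vector(out))), 1L)
  expect_lte(max(abs(out - flat)), 2)

  # low-contrast fundus: luminance spread must not shrink
  im <- generate_fundus(0, synth_config(), seed = 3)
  low <- pmin(pmax(round(im * 0.3 + 90), 0), 255)
  ystd <- function(z) stats::sd(rgb_to_yuv(z)[, , 1])
  expect_gte(ystd(clahe_luminance(low)), ystd(low))

  # chroma passes through: U and V shift bounded by conversion rounding
  a <- rgb_to_yuv(low); b <- rgb_to_yuv(clahe_luminance(low))
  expect_lte(max(abs(a[, , 2] - b[, , 2])), 2)
  expect_lte(max(abs(a[, , 3] - b[, , 3])), 2)

  # colour-space round trip without equalization
  img <- random_image(30, 30, seed = 6)
  expect_lte(max(abs(yuv_to_rgb(rgb_to_yuv(img)) - img)), 2)
})

test_that("the composed preprocessing chain crops away the black frame", {
  # disc with 20-px black margins on every side
  img <- disc_image(100, 30, value = 180)
  set.seed(1)
  img <- pmin(pmax(img + array(rnorm(length(img), 0, 2), dim = dim(img)), 0), 255)
  img <- round(img)
  out <- preprocess_image(img)

  g <- raster_gray(out)
  lead_run <- function(black) { r <- rle(black); if (r$values[1]) r$lengths[1] else 0L }
  rows_black <- rowSums(g) == 0; cols_black <- colSums(g) == 0
  expect_lte(max(lead_run(rows_black), lead_run(rev(rows_black)),
                 lead_run(cols_black), lead_run(rev(cols_black))), 2)

  # a disc that already fills the frame keeps the image size
  full <- disc_image(40, 26, value = 180)
  out2 <- preprocess_image(full)
  expect_true(all(abs(dim(out2)[1:2] - 40) <= 2))

  # output never exceeds input dimensions
  expect_true(all(dim(out)[1:2] <= c(100, 100)))

  expect_error(preprocess_image(array(0, c(50, 50, 3))), "otsu_mask")
})
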