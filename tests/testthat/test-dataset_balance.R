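merged_manifest <- function() {
  n <- c(34830, 3718, 11209, 1441, 1987)
  dr_manifest(sprintf("img%05d", seq_len(sum(n))), rep(0:4, n))
}

test_that("compute_cap truncates the mean of the three smallest classes", {
  counts <- c(`0` = 34830, `1` = 3718, `2` = 11209, `3` = 1441, `4` = 1987)
  auto <- balance_config(cap_mode = "auto_mean_of_three_smallest")
  expect_identical(compute_cap(counts, auto), 2382L)   # floor((3718+1441+1987)/3)
  expect_identical(compute_cap(rep(100, 5), auto), 100L)
  expect_identical(compute_cap(counts, balance_config(explicit_cap = 2384)), 2384L)
  expect_error(compute_cap(counts[1:4], auto), "five classes")
})

test_that("under-sampling reduces the two majority grades to the cap", {
  man <- merged_manifest()
  us <- undersample(man, balance_config(explicit_cap = 2384, rng_seed = 17))
  expect_equal(unname(class_counts(us)), c(2384, 3718, 2384, 1441, 1987))
  expect_equal(nrow(us), 11914)

  # all classes below the cap: untouched
  small <- dr_manifest(sprintf("s%03d", 1:50), rep(0:4, each = 10))
  expect_identical(undersample(small, balance_config(explicit_cap = 2384)), small)

  # determinism and the no-increase / no-touch-below-cap contract
  us2 <- undersample(man, balance_config(explicit_cap = 2384, rng_seed = 17))
  expect_identical(us$image_ref, us2$image_ref)
  us3 <- undersample(man, balance_config(explicit_cap = 2384, rng_seed = 99))
  expect_false(identical(us$image_ref, us3$image_ref))
  expect_true(all(class_counts(us3) <= class_counts(man)))
  expect_equal(class_counts(us3)[c("3", "4")], class_counts(man)[c("3", "4")])
})

test_that("the twelve augmentations preserve shape and honour involutions", {
  ops <- augmentation_ops()
  expect_length(ops, 12L)
  img <- random_image(24, 24, seed = 7)
  vars <- augment_variants(img, ops)
  expect_length(vars, 12L)
  for (v in vars) expect_equal(dim(v), dim(img))

  # involutions are bit-exact on square inputs
  fv <- function(x) augment_variants(x, ops["flip_vertical"])[[1]]
  fhv <- function(x) augment_variants(x, ops["flip_horizontal_vertical"])[[1]]
  rp <- function(x) augment_variants(x, ops["rotate_p90"])[[1]]
  rm <- function(x) augment_variants(x, ops["rotate_m90"])[[1]]
  expect_identical(fv(fv(img)), img)
  expect_identical(fhv(fhv(img)), img)
  expect_identical(rp(rp(rp(rp(img)))), img)
  expect_identical(rm(rp(img)), img)

  # identity magnitudes reproduce the input
  id_ops <- list(list(name = "gamma", magnitude = 1),
                 list(name = "zoom_1_2", magnitude = 1),
                 list(name = "brightness", magnitude = 1),
                 list(name = "sharpness", magnitude = 1))
  for (op in id_ops)
    expect_identical(augment_variants(img, list(op))[[1]], img)

  # non-square rotations come back at the input size
  rect <- random_image(20, 30, seed = 8)
  expect_equal(dim(augment_variants(rect, ops["rotate_p90"])[[1]]), dim(rect))

  expect_error(augment_variants(img, list(list(name = "sepia"))), "unknown")
})

test_that("augmentation magnitudes transform photometry as configured", {
  img <- random_image(16, 16, seed = 9)
  ops <- augmentation_ops()
  br <- augment_variants(img, ops["brightness"])[[1]]
  interior <- img > 20 & img < 200
  expect_true(mean(br[interior] >= img[interior]) > 0.99)
  gm <- augment_variants(img, ops["gamma"])[[1]]       # gamma 0.8 brightens
  expect_gte(mean(gm), mean(img))
  # jitter is deterministic under its seed
  j1 <- augment_variants(img, ops["color_jitter"])[[1]]
  j2 <- augment_variants(img, ops["color_jitter"])[[1]]
  expect_identical(j1, j2)
})

test_that("manifest expansion multiplies every grade count by 13", {
  balanced <- dr_manifest(
    sprintf("b%05d", 1:11914),
    rep(0:4, c(2384, 3718, 2384, 1441, 1987)))
  ex <- expand_manifest(balanced)
  expect_equal(unname(class_counts(ex)),
               c(30992, 48334, 30992, 18733, 25831))
  expect_equal(nrow(ex), 154882)

  m <- dr_manifest(sprintf("x%03d", 1:100), rep(2L, 100))
  expect_equal(nrow(expand_manifest(m)), 1300L)
  expect_equal(unname(class_counts(expand_manifest(m))["4"]), 0L)

  # derived references collide with a crafted existing entry
  clash <- dr_manifest(c("a", "a__gamma"), c(0L, 1L))
  expect_error(expand_manifest(clash), "collide")
})

test_that("expansion of in-memory images matches the expanded manifest", {
  imgs <- list(one = random_image(12, 12, seed = 1),
               two = random_image(12, 12, seed = 2))
  man <- dr_manifest(names(imgs), c(0L, 3L))
  ex_man <- expand_manifest(man)
  ex_imgs <- expand_images(imgs)
  expect_setequal(names(ex_imgs), ex_man$image_ref)
  expect_identical(ex_imgs$one, imgs$one)
  expect_equal(dim(ex_imgs$`one__zoom_1_5`), dim(imgs$one))
})

test_that("manifest CSV round trip preserves entries", {
  man <- dr_manifest(c("a.png", "b.png", "c.png"), c(0L, 2L, 4L),
                     c("train", "val", "test"))
  path <- tempfile(fileext = ".csv")
  write_manifest(man, path)
  expect_identical(read_manifest(path), man)
})
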