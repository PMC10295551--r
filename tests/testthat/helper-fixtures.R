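# shared fixture builders; everything is generated in code at test time

# flat disc of the given radius centred in an otherwise black frame
disc_image <- function(size = 100, radius = 30, value = 200,
                       center = c((size + 1) / 2, (size + 1) / 2)) {
  d2 <- outer(seq_len(size) - center[1], seq_len(size) - center[2],
              function(a, b) a^2 + b^2)
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) img[, , ch] <- ifelse(d2 <= radius^2, value, 0)
  img
}

random_image <- function(h = 32, w = h, seed = 1) {
  set.seed(seed)
  array(as.numeric(sample(0:255, h * w * 3, replace = TRUE)), c(h, w, 3))
}

# exhaustive between-class-variance maximizer over all 256 thresholds,
# independent of the package's cumulative-moment implementation
otsu_bruteforce <- function(gray) {
  counts <- tabulate(as.integer(gray) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  best_t <- -1L; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- sum(((t + 1):255) * p[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# small raw (unpreprocessed) training fixture, cached across tests
.fixture_env <- new.env(parent = emptyenv())

small_train_fixture <- function(n_per_grade = 20) {
  key <- paste0("raw_", n_per_grade)
  if (is.null(.fixture_env[[key]])) {
    ds <- generate_fundus_dataset(n_per_grade, synth_config(seed = 5))
    imgs <- lapply(ds$images, function(im) raster_resize(im, 16, 16))
    .fixture_env[[key]] <- list(images = imgs, manifest = ds$manifest,
                                y = ds$manifest$grade)
  }
  .fixture_env[[key]]
}

# the desk-scale study set: 100 images per grade, preprocessed and resized
# to the classifier input size; cached because it is used by several checks
study_fixture <- function() {
  if (is.null(.fixture_env$study)) {
    ds <- generate_fundus_dataset(100, synth_config(seed = 11))
    imgs <- lapply(ds$images, function(im)
      raster_resize(preprocess_image(im), 16, 16))
    .fixture_env$study <- list(images = imgs, manifest = ds$manifest,
                               y = ds$manifest$grade)
  }
  .fixture_env$study
}
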