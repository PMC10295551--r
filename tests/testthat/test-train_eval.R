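test_that("the stratified split honours 70/20/10 with largest-remainder rounding", {
  man <- dr_manifest(sprintf("e%04d", 1:5000), rep(0:4, each = 1000))
  sp <- split_manifest(man, train_control(rng_seed = 4))
  for (g in 0:4) {
    counts <- table(sp$split[sp$grade == g])
    expect_equal(unname(counts[c("train", "val", "test")]),
                 c(700L, 200L, 100L), ignore_attr = TRUE)
  }

  # 10 entries: 7/2/1 by largest remainder
  m10 <- dr_manifest(sprintf("t%02d", 1:10), rep(2L, 10))
  sp10 <- split_manifest(m10, train_control(rng_seed = 1))
  expect_equal(unname(table(sp10$split)[c("train", "val", "test")]),
               c(7L, 2L, 1L), ignore_attr = TRUE)

  # identical seeds give identical assignments; split is a partition
  sp2 <- split_manifest(man, train_control(rng_seed = 4))
  expect_identical(sp$split, sp2$split)
  expect_true(all(sp$split %in% c("train", "val", "test")))

  # random class sizes stay within one entry of the exact fractions
  set.seed(9)
  sizes <- sample(5:97, 5)
  mr <- dr_manifest(sprintf("r%04d", seq_len(sum(sizes))), rep(0:4, sizes))
  spr <- split_manifest(mr, train_control(rng_seed = 2))
  for (g in 0:4) {
    n <- sizes[g + 1]
    counts <- table(factor(spr$split[spr$grade == g],
                           levels = c("train", "val", "test")))
    expect_true(all(abs(counts - n * c(0.7, 0.2, 0.1)) < 1))
  }

  tinycl <- dr_manifest(c("a", "b", "c", "d"), c(0L, 0L, 0L, 1L))
  expect_warning(sp3 <- split_manifest(tinycl, train_control()), "fewer than 3")
  expect_true(all(sp3$split[sp3$grade == 1] == "train"))
})

test_that("a zero learning rate leaves the weights bit-identical", {
  fx <- small_train_fixture(6)
  model <- cct_config(seed = 21)
  ctl <- train_control(epochs = 1, batch_size = 16, learning_rate = 0,
                       weight_decay = 0, rng_seed = 7)
  fit <- dr_cct(fx$images, fx$y, model, ctl)
  expect_identical(unlist(fit$weights), unlist(unclass(cct_init(model))))

  # and the training accuracy stays at the untrained model's level
  p0 <- max.col(cct_forward(drcctnet:::prep_model_input(fx$images, model),
                            cct_init(model), model), ties.method = "first") - 1L
  expect_lte(abs(mean(predict(fit, fx$images) == fx$y) - mean(p0 == fx$y)),
             0.05)
})

test_that("training reduces the loss over the first epochs (median of 3 seeds)", {
  fx <- small_train_fixture(20)
  drops <- vapply(1:3, function(s) {
    fit <- dr_cct(fx$images, fx$y, cct_config(),
                  train_control(epochs = 6, batch_size = 32, rng_seed = s))
    fit$history$loss[1] - min(fit$history$loss[5:6])
  }, numeric(1))
  expect_gt(stats::median(drops), 0)
})

test_that("training is deterministic under identical seeds", {
  fx <- small_train_fixture(6)
  ctl <- train_control(epochs = 2, batch_size = 16, rng_seed = 3)
  f1 <- dr_cct(fx$images, fx$y, cct_config(), ctl)
  f2 <- dr_cct(fx$images, fx$y, cct_config(), ctl)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(unlist(f1$weights), unlist(f2$weights))
})

test_that("train_cct reports a test confusion matrix with correct row sums", {
  fx <- small_train_fixture(20)
  res <- train_cct(fx$manifest, fx$images, cct_config(),
                   train_control(epochs = 2, batch_size = 32, rng_seed = 5))
  expect_s3_class(res$fit, "dr_cct")
  test_counts <- table(factor(res$manifest$grade[res$manifest$split == "test"],
                              levels = 0:4))
  expect_equal(unname(rowSums(res$confusion)), as.integer(test_counts))
  expect_true(all(unclass(res$metrics) >= -1 & unclass(res$metrics) <= 1))
})

test_that("model methods behave: print, predict, coef, plot", {
  fx <- small_train_fixture(6)
  fit <- dr_cct(fx$images, fx$y, cct_config(),
                train_control(epochs = 1, batch_size = 16, rng_seed = 2))
  expect_output(print(fit), "trainable parameters")
  probs <- predict(fit, fx$images, type = "prob")
  expect_equal(rowSums(probs), rep(1, length(fx$y)), tolerance = 1e-6)
  cls <- predict(fit, fx$images)
  expect_true(all(cls %in% 0:4))
  expect_s3_class(coef(fit), "cct_weights")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("the reduction protocol subsamples, retrains and reports spreads", {
  fx <- small_train_fixture(20)
  ctl <- train_control(epochs = 2, batch_size = 32, rng_seed = 5)
  tab <- reduction_protocol(fx$manifest, fx$images, cct_config(), ctl,
                            fractions = c(1, 0.5), repeats = 2)
  expect_equal(tab$fraction, c(1, 0.5))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  expect_true(all(tab$spread >= 0))
  expect_equal(tab$n_train[2], floor(0.5 * tab$n_train[1]))

  # deterministic given the same control
  tab2 <- reduction_protocol(fx$manifest, fx$images, cct_config(), ctl,
                             fractions = c(1, 0.5), repeats = 2)
  expect_identical(tab, tab2)

  expect_error(reduction_protocol(fx$manifest, fx$images,
                                  fractions = c(0, 0.5)), "fractions")
})
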