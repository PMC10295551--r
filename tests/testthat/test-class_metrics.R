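random_cm <- function(seed, n = 5L) {
  set.seed(seed)
  matrix(sample(0:40, n * n, replace = TRUE), n, n)
}

test_that("confusion_matrix tabulates actual rows against predicted columns", {
  cm <- confusion_matrix(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_true(all(cm == diag(5)))

  cm2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1))
  expect_equal(cm2["0", "0"], 1L)
  expect_equal(cm2["0", "1"], 1L)
  expect_equal(cm2["1", "1"], 1L)
  expect_equal(sum(cm2), 3L)

  expect_error(confusion_matrix(integer(0), integer(0)), "empty")
  expect_error(confusion_matrix(c(0, 5), c(0, 0)), "labels")
  expect_error(confusion_matrix(c(0, 1), c(0)), "lengths")
})

test_that("one_vs_rest decomposes counts and conserves the total", {
  d <- one_vs_rest(diag(5) * 10)
  expect_true(all(d$FP == 0) && all(d$FN == 0))

  m <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE)  # rows actual
  d2 <- one_vs_rest(m)
  expect_equal(d2$TP[1], 50); expect_equal(d2$FN[1], 10)
  expect_equal(d2$FP[1], 5);  expect_equal(d2$TN[1], 35)
  expect_true(all(d2$TP + d2$TN + d2$FP + d2$FN == 100))
})

test_that("metric_report reproduces hand-computed values", {
  perfect <- metric_report(diag(5) * 20)
  expect_equal(unname(perfect[c("acc", "recall", "specificity", "precision",
                                "f1", "npv", "mcc")]), rep(1, 7))
  expect_equal(unname(perfect[c("fpr", "fnr", "fdr")]), rep(0, 3))

  m <- matrix(c(50, 10, 5, 35), 2, 2, byrow = TRUE)
  per <- attr(metric_report(m), "per_class")
  expect_equal(per[1, "recall"], 50 / 60, tolerance = 1e-12)
  expect_equal(per[1, "precision"], 50 / 55, tolerance = 1e-12)
  expect_equal(per[1, "mcc"], (50 * 35 - 5 * 10) / sqrt(55 * 60 * 40 * 45),
               tolerance = 1e-12)

  expect_error(metric_report(matrix(0, 5, 5)), "all-zero")
})

test_that("complement identities hold exactly on random confusion matrices", {
  for (s in 1:100) {
    cm <- random_cm(s)
    if (sum(cm) == 0) next
    per <- attr(metric_report(cm), "per_class")
    ok <- per[, "recall"] + per[, "fnr"]
    d <- one_vs_rest(cm)
    defined <- d$TP + d$FN > 0
    expect_equal(unname(ok[defined]), rep(1, sum(defined)))
    expect_equal(unname((per[, "specificity"] + per[, "fpr"])[d$TN + d$FP > 0]),
                 rep(1, sum(d$TN + d$FP > 0)))
    expect_equal(unname((per[, "precision"] + per[, "fdr"])[d$TP + d$FP > 0]),
                 rep(1, sum(d$TP + d$FP > 0)))
    expect_true(all(per[, "mcc"] >= -1 & per[, "mcc"] <= 1))
  }
})

test_that("the macro report is the mean of per-class reports and is order-invariant", {
  set.seed(3)
  y <- sample(0:4, 400, replace = TRUE)
  p <- ifelse(runif(400) < 0.6, y, sample(0:4, 400, replace = TRUE))
  rep1 <- metric_report(confusion_matrix(y, p))
  expect_equal(unclass(rep1), colMeans(attr(rep1, "per_class")),
               ignore_attr = TRUE)

  ord <- sample(400)
  rep2 <- metric_report(confusion_matrix(y[ord], p[ord]))
  expect_equal(unclass(rep1), unclass(rep2), ignore_attr = TRUE)

  # micro averaging pools counts first
  mic <- metric_report(confusion_matrix(y, p), average = "micro")
  expect_equal(unname(mic["recall"]), sum(y == p) / 400, tolerance = 1e-12)
})

test_that("zero-denominator metrics are defined as zero and flagged", {
  cm <- matrix(0, 5, 5); cm[1, 1] <- 10   # only class 0 present or predicted
  rep <- metric_report(cm)
  expect_true(all(is.finite(unclass(rep))))
  expect_true(length(attr(rep, "zero_denominator")) > 0)
})
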