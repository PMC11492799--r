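test_that("confusion metrics match hand-computed values", {
  m <- metrics_from_counts(1, 1, 0, 0)
  expect_equal(unname(m[c("sn", "sp", "acc", "mcc", "pre", "f1")]),
               rep(1, 6))
  m2 <- metrics_from_counts(50, 40, 10, 0)
  expect_equal(unname(m2[["sn"]]), 1)
  expect_equal(unname(m2[["sp"]]), 0.8)
  expect_equal(unname(m2[["acc"]]), 0.9)
  expect_equal(unname(m2[["pre"]]), 50 / 60, tolerance = 1e-12)
  expect_equal(unname(m2[["f1"]]), 2 * (50 / 60) / (50 / 60 + 1), tolerance = 1e-12)
  expect_equal(unname(m2[["mcc"]]),
               (50 * 40) / sqrt(60 * 50 * 50 * 40), tolerance = 1e-12)
})

test_that("swapping class polarity exchanges sn/sp and preserves acc and |mcc|", {
  m <- metrics_from_counts(30, 50, 7, 13)
  ms <- metrics_from_counts(50, 30, 13, 7)
  expect_equal(m[["sn"]], ms[["sp"]])
  expect_equal(m[["sp"]], ms[["sn"]])
  expect_equal(m[["acc"]], ms[["acc"]])
  expect_equal(abs(m[["mcc"]]), abs(ms[["mcc"]]))
})

test_that("undefined denominators are flagged, never silently zeroed", {
  m <- metrics_from_counts(0, 10, 0, 0)
  expect_true(is.na(m[["sn"]]))
  expect_true("sn" %in% attr(m, "undefined"))
  expect_true("mcc" %in% attr(m, "undefined"))
  expect_equal(unname(m[["mcc"]]), 0)
  expect_error(metrics_from_counts(0, 0, 0, 0), "zero")
})

test_that("metrics agree with a brute-force tally from label/prediction pairs", {
  set.seed(30)
  labels <- rbinom(200, 1, 0.4)
  scores <- runif(200)
  cc <- confusion_counts(labels, scores)
  pred <- as.integer(scores >= 0.5)
  expect_equal(unname(cc["tp"]), sum(pred & labels))
  expect_equal(unname(cc["fn"]), sum(!pred & labels))
  m <- metric_set(labels, scores)
  expect_equal(unname(m[["acc"]]), mean(pred == labels))
})

test_that("rank AUC handles separation, ties, and matches the trapezoid oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(20:80, 1)
    labels <- c(rep(1, 5), rbinom(n - 5, 1, 0.5))
    scores <- round(runif(n), 2)  # rounded to force ties
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), trapezoid_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  labels <- rbinom(100, 1, 0.5)
  scores <- rnorm(100)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(plogis(3 * scores + 1), labels), a)
})

test_that("stratified folds partition the data with balanced sizes", {
  set.seed(33)
  y <- rbinom(137, 1, 0.4)
  f <- stratified_folds(y, k = 10, seed = 5)
  expect_setequal(unique(f), 1:10)
  sizes <- table(f)
  expect_lte(max(sizes) - min(sizes), 1)
  # both classes in every fold
  expect_true(all(table(f, y) > 0))
  # determinism
  expect_identical(f, stratified_folds(y, k = 10, seed = 5))
  expect_false(identical(f, stratified_folds(y, k = 10, seed = 6)))
  expect_error(stratified_folds(rep(c(0, 1), c(130, 7)), k = 10, seed = 1),
               "stratify")
})

test_that("cross-validation covers each sample exactly once and is seed-stable", {
  set.seed(34)
  x <- matrix(rnorm(300), 100)
  y <- rbinom(100, 1, 0.5)
  trainer <- function(xx, yy) glm.fit(cbind(1, xx), yy,
                                      family = binomial())
  predictor <- function(fit, nx) plogis(drop(cbind(1, nx) %*% fit$coefficients))
  cv1 <- kfold_cv(x, y, trainer, predictor, k = 5, seed = 9)
  cv2 <- kfold_cv(x, y, trainer, predictor, k = 5, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_equal(cv1$oof_scores, cv2$oof_scores)
  expect_equal(nrow(cv1$per_fold), 5L)
  expect_length(cv1$pooled, 7L)
})
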