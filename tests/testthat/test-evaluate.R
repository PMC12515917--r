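test_that("the 7:3 split reproduces the cohort counts and is stratified", {
  ds <- tibble::tibble(
    id = 1:326,
    binary_label = rep(c("normal", "abnormal"), c(224, 102))
  )
  sp <- split_dataset(ds, c(0.7, 0.3), seed = 1)
  expect_equal(nrow(sp$train), 228)
  expect_equal(nrow(sp$test), 98)
  expect_equal(sort(c(sp$train$id, sp$test$id)), 1:326)
  # per-stratum largest remainder: 224 * 0.7 = 156.8 -> 157, 102 * 0.7 -> 71
  expect_equal(sum(sp$train$binary_label == "normal"), 157)
  expect_equal(sum(sp$train$binary_label == "abnormal"), 71)

  sp2 <- split_dataset(ds, c(0.7, 0.3), seed = 1)
  expect_identical(sp$train$id, sp2$train$id)

  all_train <- split_dataset(ds, c(1, 0), seed = 2)
  expect_equal(nrow(all_train$train), 326)
  expect_equal(nrow(all_train$test), 0)
})

test_that("metric arithmetic follows the confusion-matrix definitions", {
  labels <- rep(c("normal", "abnormal"), c(4, 6))
  preds <- c("normal", "normal", "normal", "abnormal",
             "normal", "normal", rep("abnormal", 4))
  # TP=3, FN=1, FP=2, TN=4
  m <- compute_metrics(labels, preds)
  expect_equal(unname(m$confusion[1, ]), c(3, 1))
  expect_equal(unname(m$confusion[2, ]), c(2, 4))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision_normal, 0.6)
  expect_equal(m$recall_normal, 0.75)
  expect_equal(m$precision_abnormal, 0.8)
  expect_equal(m$recall_abnormal, 4 / 6)
  # precision = recall = 0.9 gives F1 = 0.9 (harmonic mean of equals)
  expect_equal(2 * 0.9 * 0.9 / (0.9 + 0.9), 0.9)
  expect_error(compute_metrics(character(), character()), "empty")
})

test_that("metrics agree with a brute-force recount on random vectors", {
  set.seed(11)
  for (i in 1:300) {
    n <- sample(5:40, 1)
    labels <- sample(c("normal", "abnormal"), n, replace = TRUE)
    preds <- sample(c("normal", "abnormal"), n, replace = TRUE)
    m <- compute_metrics(labels, preds)
    o <- brute_metrics(labels, preds)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(unname(m$confusion[1, 1]), o$tp)
    expect_equal(unname(m$confusion[2, 2]), o$tn)
    expect_equal(m$precision_normal, o$precision_normal)
    expect_equal(m$recall_abnormal, o$recall_abnormal)
  }
})

test_that("AUC equals the pairwise-comparison probability", {
  set.seed(12)
  for (i in 1:60) {
    n <- sample(8:40, 1)
    labels <- c("normal", "abnormal",
                sample(c("normal", "abnormal"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    a <- roc_auc(labels, scores)$auc
    expect_lt(abs(a - pairwise_auc(labels, scores)), 1e-9)
  }
})

test_that("ROC endpoints, monotonicity, and landmark AUCs hold", {
  labels <- rep(c("normal", "abnormal"), each = 20)
  sep <- c(rnorm(20, 3), rnorm(20, -3))
  ra <- roc_auc(labels, sep)
  expect_equal(ra$auc, 1)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[1], 0)
  expect_equal(tail(ra$roc$fpr, 1), 1)
  expect_equal(tail(ra$roc$tpr, 1), 1)
  expect_true(all(diff(ra$roc$fpr) >= 0))
  expect_true(all(diff(ra$roc$tpr) >= 0))

  set.seed(13)
  big <- sample(c("normal", "abnormal"), 4000, replace = TRUE)
  rnd <- roc_auc(big, rnorm(4000))$auc
  expect_lt(abs(rnd - 0.5), 0.05)

  # invariant under strictly monotone transforms of the scores
  sc <- rnorm(40)
  labs <- rep(c("normal", "abnormal"), 20)
  a1 <- roc_auc(labs, sc)$auc
  expect_equal(roc_auc(labs, exp(sc))$auc, a1)
  expect_equal(roc_auc(labs, 5 * sc - 3)$auc, a1)
  expect_error(roc_auc(rep("normal", 5), rnorm(5)), "both classes")
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  labels <- sample(c("normal", "abnormal"), 200, replace = TRUE)
  scores <- rnorm(200) + (labels == "normal")
  ours <- roc_auc(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(labels, c("abnormal", "normal")),
    predictor = scores, quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("generalization decay rate arithmetic and flag", {
  g <- gdr(0.9, 0.72)
  expect_equal(g$gdr_percent, 20)
  expect_true(g$adaptation_needed)
  g0 <- gdr(0.9, 0.9)
  expect_equal(g0$gdr_percent, 0)
  expect_false(g0$adaptation_needed)
  g11 <- gdr(0.9, 0.80)
  expect_equal(g11$gdr_percent, 100 / 9, tolerance = 1e-9)
  expect_false(g11$adaptation_needed)
  expect_error(gdr(0, 0.5), "positive")
})

test_that("tidy and glance summarize an eval report", {
  labels <- rep(c("normal", "abnormal"), c(4, 6))
  preds <- c(rep("normal", 3), rep("abnormal", 7))
  scores <- seq(1, 0, length.out = 10)
  m <- compute_metrics(labels, preds, scores)
  td <- tidy(m)
  expect_true(all(c("metric", "value") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n, 10)
  expect_equal(gl$tp + gl$fn + gl$fp + gl$tn, 10)
  expect_s3_class(autoplot(m), "ggplot")
})
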