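test_that("all-correct predictions give the perfect-score table", {
  truth <- rep(0:9, each = 10)
  rep <- classification_report(truth, truth)
  expect_equal(rep$table$tp, rep(10L, 10))
  expect_equal(rep$table$fp, rep(0L, 10))
  expect_equal(rep$table$fn, rep(0L, 10))
  expect_equal(rep$table$precision, rep(100, 10))
  expect_equal(rep$table$recall, rep(100, 10))
  expect_equal(rep$table$f1, rep(100, 10))
  expect_equal(rep$total_accuracy, 100)
})

test_that("swapped adjacent phases yield the expected counts and 90% scores", {
  # 100 per phase with 10 swaps in each direction for 3<->4 and 6<->7
  truth <- rep(0:9, each = 100)
  est <- truth
  swap <- function(est, a, b) {
    ia <- which(truth == a)[1:10]
    ib <- which(truth == b)[1:10]
    est[ia] <- b
    est[ib] <- a
    est
  }
  est <- swap(est, 3, 4)
  est <- swap(est, 6, 7)
  counts <- confusion_counts(truth, est)
  for (p in c(3, 4, 6, 7)) {
    expect_equal(counts$tp[counts$phase == p], 90)
    expect_equal(counts$fp[counts$phase == p], 10)
    expect_equal(counts$fn[counts$phase == p], 10)
  }
  scored <- precision_recall_f1(counts)
  # TP=90, FP=10, FN=10 computes to 90% by the formulas
  expect_equal(scored$f1[scored$phase %in% c(3, 4, 6, 7)], rep(90, 4))
  expect_equal(scored$f1[!scored$phase %in% c(3, 4, 6, 7)], rep(100, 6))
})

test_that("confusion counts partition the evaluated samples", {
  withr::local_seed(14)
  for (i in 1:5) {
    n <- sample(20:200, 1)
    truth <- sample(0:9, n, replace = TRUE)
    est <- sample(0:9, n, replace = TRUE)
    counts <- confusion_counts(truth, est)
    expect_equal(sum(counts$tp) + sum(counts$fn), n)
    expect_equal(sum(counts$fp), sum(counts$fn))
  }
  expect_error(confusion_counts(c(0, 11), c(0, 1)), "0..9")
})

test_that("per-phase scores agree with an independent macro one-vs-rest oracle", {
  skip_if_not_installed("caret")
  withr::local_seed(15)
  truth <- sample(0:9, 400, replace = TRUE)
  est <- ifelse(runif(400) < 0.7, truth, sample(0:9, 400, replace = TRUE))
  ours <- precision_recall_f1(confusion_counts(truth, est))
  cm <- caret::confusionMatrix(
    factor(est, levels = 0:9), factor(truth, levels = 0:9),
    mode = "prec_recall"
  )
  expect_equal(ours$precision / 100, unname(cm$byClass[, "Precision"]),
               tolerance = 1e-12)
  expect_equal(ours$recall / 100, unname(cm$byClass[, "Recall"]),
               tolerance = 1e-12)
  expect_equal(ours$f1 / 100, unname(cm$byClass[, "F1"]), tolerance = 1e-12)
})

test_that("total accuracy is the mean of exactly ten values, order-free", {
  expect_equal(total_accuracy(rep(100, 10)), 100)
  v <- c(100, 100, 100, 81.1, 81.1, 100, 81.1, 81.1, 100, 100)
  expect_equal(total_accuracy(v), 92.44)
  expect_equal(total_accuracy(sample(v)), total_accuracy(v))
  expect_equal(total_accuracy(rep(73.2, 10)), 73.2)
  expect_error(total_accuracy(rep(100, 9)), "10")
})

test_that("degenerate one-vs-rest cells score zero with a warning", {
  counts <- tibble::tibble(phase = 0:9, tp = c(0L, rep(10L, 9)),
                           fp = 0L, fn = c(5L, rep(0L, 9)))
  expect_warning(scored <- precision_recall_f1(counts), "no true positives")
  expect_equal(scored$f1[1], 0)
})

test_that("regression metrics reproduce hand-computed values", {
  # perfect fit
  perfect <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)

  # predicting the mean: Var - MSE = 0 by the definition of variance
  y <- c(0.2, 0.4, 0.9, 0.5)
  expect_equal(regression_metrics(y, rep(mean(y), 4))$r2, 0)

  # hand arithmetic
  m <- regression_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
  expect_equal(m$mse, 0.02 / 3)
  expect_equal(m$mae, 0.2 / 3)
  expect_equal(m$r2, 0.96)

  expect_error(regression_metrics(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("both R-squared forms coincide on random data", {
  withr::local_seed(16)
  for (i in 1:5) {
    y <- rnorm(50)
    yhat <- y + rnorm(50, sd = 0.3)
    m <- regression_metrics(y, yhat)
    v <- mean((y - mean(y))^2)
    expect_equal(m$r2, 1 - m$mse / v, tolerance = 1e-12)
  }
})

test_that("the regression report exposes percent and millimetre scales", {
  sc <- fit_minmax(cbind(disp_mm = c(0, 20)))
  truth_mm <- c(2, 8, 14)
  pred_mm <- c(2.2, 7.8, 14.4)
  rep <- regression_report(
    truth_norm = truth_mm / 20, pred_norm = pred_mm / 20,
    truth_mm = truth_mm, pred_mm = pred_mm
  )
  expect_equal(rep$mse_pct, 100 * mean((truth_mm - pred_mm)^2) / 400)
  expect_equal(rep$mm$mae, mean(abs(truth_mm - pred_mm)))
  # R-squared is invariant under the affine rescaling
  expect_equal(rep$normalized$r2, rep$mm$r2, tolerance = 1e-12)
  expect_equal(nrow(tidy(rep)), 2)
})
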