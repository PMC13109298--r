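test_that("IoU matches hand-counted overlaps and rejects empty input", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(mask_iou(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(mask_iou(a, b), 0)
  # 10x10 square against itself shifted 5 px: 50 / 150
  s <- matrix(FALSE, 20, 20); s[1:10, 6:15] <- TRUE
  expect_equal(mask_iou(a, s), 50 / 150)
  expect_error(mask_iou(b & FALSE, b & FALSE), "empty")
})

test_that("confusion metrics follow the specificity/sensitivity/Dice formulas", {
  expect_equal(confusion_metrics(10, 90, 0, 0),
               tibble::tibble(specificity = 100, sensitivity = 100, dice = 1))
  m <- confusion_metrics(0, 90, 0, 10)  # all-negative prediction
  expect_equal(unlist(m), c(specificity = 100, sensitivity = 0, dice = 0))
  m2 <- confusion_metrics(8, 88, 2, 2)
  expect_equal(m2$specificity, 88 / 90 * 100, tolerance = 1e-12)
  expect_equal(round(m2$specificity, 2), 97.78)
  expect_equal(m2$sensitivity, 80)
  expect_equal(m2$dice, 0.8)
  # zero denominators give NA, not 0
  expect_true(is.na(confusion_metrics(0, 5, 0, 0)$sensitivity))
  expect_true(is.na(confusion_metrics(5, 0, 0, 0)$specificity))
})

test_that("regression metrics follow the R2/RMSE/NRMSE/MAPE formulas", {
  y <- c(10, 20, 30)
  expect_equal(unlist(regression_metrics(y, y)),
               c(r2 = 1, rmse = 0, nrmse = 0, mape = 0))
  m <- regression_metrics(y, c(20, 20, 20))
  expect_equal(m$r2, 0)
  expect_equal(m$rmse, sqrt(200 / 3), tolerance = 1e-12)
  expect_equal(round(m$rmse, 3), 8.165)
  expect_equal(round(m$nrmse, 2), 40.82)
  expect_equal(round(m$mape, 2), 44.44)
  expect_true(is.na(regression_metrics(c(5, 5, 5), c(1, 2, 3))$r2))
  expect_true(is.na(regression_metrics(c(0, 1, 2), c(1, 1, 1))$mape))
})

test_that("classification metrics follow the accuracy/recall formulas", {
  expect_equal(unlist(classification_metrics(10, 10, 0, 0)),
               c(accuracy = 100, recall0 = 100, recall1 = 100))
  m <- classification_metrics(8, 7, 2, 3)
  expect_equal(unlist(m), c(accuracy = 75, recall0 = 80, recall1 = 70))
  expect_true(is.na(classification_metrics(5, 0, 1, 0)$recall1))
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("metrics agree with brute-force recomputation on random instances", {
  set.seed(42)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); tn <- sample(0:50, 1)
    fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + tn + fp + fn == 0) next
    m <- confusion_metrics(tp, tn, fp, fn)
    if (tn + fp > 0) expect_equal(m$specificity, 100 * tn / (tn + fp))
    if (tp + fn > 0) expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    c2 <- classification_metrics(tp, tn, fp, fn)
    expect_equal(c2$accuracy, 100 * (tp + tn) / (tp + tn + fp + fn))
  }
  # regression metrics against naive loops
  for (i in 1:200) {
    n <- sample(2:20, 1)
    y <- stats::runif(n, 1, 50); yh <- y + stats::rnorm(n)
    if (max(y) == min(y)) next
    m <- regression_metrics(y, yh)
    sse <- 0; for (j in seq_len(n)) sse <- sse + (y[j] - yh[j])^2
    expect_equal(m$rmse, sqrt(sse / n), tolerance = 1e-10)
    expect_equal(m$r2, 1 - sse / sum((y - mean(y))^2), tolerance = 1e-10)
    expect_equal(m$nrmse, sqrt(sse / n) / (max(y) - min(y)) * 100,
                 tolerance = 1e-10)
    expect_equal(m$mape, 100 * mean(abs((y - yh) / y)), tolerance = 1e-10)
  }
})

test_that("Dice and IoU satisfy the closed-form identity on random masks", {
  set.seed(7)
  for (i in 1:200) {
    a <- matrix(stats::runif(100) < 0.4, 10, 10)
    b <- matrix(stats::runif(100) < 0.4, 10, 10)
    if (!any(a | b)) next
    iou <- mask_iou(a, b)
    cc <- fieldpheno:::confusion_counts(a, b)
    dice <- confusion_metrics(cc$tp, cc$tn, cc$fp, cc$fn)$dice
    if (is.na(dice)) dice <- 0  # both masks empty of positives
    expect_equal(dice, 2 * iou / (1 + iou), tolerance = 1e-12)
  }
})
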