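test_that("canopy height averages the two half statistics", {
  nd <- matrix(0, 40, 40)
  nd[5, 5] <- 0.30    # top half maximum
  nd[30, 5] <- 0.20   # bottom half maximum
  p <- make_test_patch(1L, nd, center_y = 20L)
  out <- extract_canopy_height(p, "max")
  expect_equal(out$ch_cm, 25.0)
  expect_equal(out$plot_id, 1L)
  expect_false(out$flagged)

  # all-zero nDSM -> 0 cm
  expect_equal(extract_canopy_height(make_test_patch(2L, matrix(0, 10, 10)))$ch_cm, 0)

  # single-row plots use the full patch
  ps <- make_test_patch(3L, nd, center_y = 20L, single_row = TRUE)
  expect_equal(extract_canopy_height(ps)$ch_cm, 30)
})

test_that("percentile statistics ignore isolated spikes", {
  vals <- c(rep(0.1, 99), 1.0)
  nd <- matrix(vals, 10, 10)
  p <- make_test_patch(1L, nd, single_row = TRUE)
  out <- extract_canopy_height(p, "p95")
  # 95th percentile of 99 x 0.1 and 1 x 1.0 is 0.1 (type-7 quantile oracle:
  # sorted interpolation at rank 1 + 0.95 * 99 = 95.05)
  expect_equal(out$ch_cm, 10)
  expect_equal(extract_canopy_height(p, "max")$ch_cm, 100)
})

test_that("canopy-height statistics are monotone: max >= p99 >= p97 >= p95", {
  set.seed(11)
  for (i in 1:20) {
    nd <- matrix(stats::runif(400, 0, 0.4), 20, 20)
    p <- make_test_patch(i, nd, center_y = 10L)
    ch <- vapply(c("max", "p99", "p97", "p95"),
                 function(s) extract_canopy_height(p, s)$ch_cm, 0)
    expect_true(all(diff(ch) <= 1e-9))
  }
})

test_that("an all-missing half falls back to the other half with a flag", {
  nd <- matrix(NA_real_, 20, 20)
  nd[15:20, ] <- 0.22
  p <- make_test_patch(1L, nd, center_y = 10L)
  out <- extract_canopy_height(p)
  expect_true(out$flagged)
  expect_equal(out$ch_cm, 22)
})

test_that("nDSM fusion adds centimeters to G with clipping", {
  rgb <- array(0, c(2, 2, 3))
  rgb[, , 1] <- 10; rgb[, , 2] <- 100; rgb[, , 3] <- 30
  nd0 <- matrix(0, 2, 2)
  expect_identical(fuse_ndsm_rgb(rgb, nd0), rgb)  # idempotent at ndsm = 0
  nd <- matrix(0.5, 2, 2)
  fused <- fuse_ndsm_rgb(rgb, nd)
  expect_true(all(fused[, , 2] == 150))
  rgb2 <- rgb; rgb2[, , 2] <- 200
  fused2 <- fuse_ndsm_rgb(rgb2, matrix(1.0, 2, 2))
  expect_true(all(fused2[, , 2] == 255))  # clipped
  # R and B never change
  expect_identical(fused2[, , 1], rgb2[, , 1])
  expect_identical(fused2[, , 3], rgb2[, , 3])
})

test_that("fusion matches the formula on randomized patches", {
  set.seed(21)
  for (i in 1:50) {
    rgb <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
    nd <- matrix(stats::rnorm(16, 0.5, 1.2), 4, 4)
    fused <- fuse_ndsm_rgb(rgb, nd)
    want <- matrix(pmin(255, pmax(0, round(rgb[, , 2] + 100 * nd))), 4, 4)
    expect_equal(fused[, , 2], want)
    expect_equal(fused[, , c(1, 3)], rgb[, , c(1, 3)], ignore_attr = TRUE)
  }
})

test_that("datasets split 80:20 stratified and augment fourfold", {
  sep <- separable_patches(50, seed = 2)  # 100 patches, 50/50 classes
  ds <- build_dataset(sep$patches, sep$labels, "gh", modality = "rgb",
                      seed = 3)
  expect_equal(max(ds$train$base_idx), 80L)
  expect_length(ds$test$y, 20L)
  expect_length(ds$train$images, 320L)  # original + 3 flip variants
  expect_equal(unname(c(table(ds$train$y[seq_len(80)]))), c(40L, 40L))
  expect_setequal(unique(ds$train$variant),
                  c("orig", "flip_h", "flip_v", "mirror"))
  # same seed -> identical split membership
  ds2 <- build_dataset(sep$patches, sep$labels, "gh", modality = "rgb",
                       seed = 3)
  expect_identical(ds$test$y, ds2$test$y)
  expect_identical(ds$train$y, ds2$train$y)
  # single class -> error
  one <- sep$labels; one$gh <- "bunch"
  expect_error(build_dataset(sep$patches, one, "gh"), "2 classes")
})

test_that("the grid search covers all combinations with fold scores", {
  sep <- separable_patches(12, seed = 4, side = 56L)
  spec <- train_spec(model_name = "alexnet", modality = "ndsm",
                     runs = 2L, seed = 7L)
  fit <- train_trait_classifier(sep$patches, sep$labels, "gh", spec)
  expect_equal(nrow(fit$cv_table), 18L)  # 2 batches x 3 epochs x 3 lrs
  expect_true(all(is.finite(fit$cv_table$mean_f1)))
  expect_true(all(fit$cv_table$mean_f1 >= 0 & fit$cv_table$mean_f1 <= 1))
  expect_equal(nrow(fit$runs), 2L)
  g <- glance(fit)
  expect_true(g$accuracy_mean >= 0 && g$accuracy_mean <= 100)
  expect_equal(g$n_runs, 2L)
  expect_s3_class(tidy(fit), "tbl_df")
})

test_that("height-separable classes are learned from the ndsm modality", {
  sep <- separable_patches(40, seed = 5)
  spec <- train_spec(model_name = "alexnet", modality = "ndsm",
                     batch = 16L, epochs = c(10L, 20L),
                     lr = c(1e-4, 1e-3), runs = 3L, seed = 11L)
  fit <- train_trait_classifier(sep$patches, sep$labels, "gh", spec)
  expect_gte(mean(fit$runs$accuracy), 95)
})

test_that("classifier evaluation mirrors the classification equations", {
  sep <- separable_patches(20, seed = 6, side = 56L)
  spec <- train_spec(model_name = "alexnet", modality = "ndsm",
                     batch = 16L, epochs = 10L, lr = 1e-3,
                     runs = 1L, seed = 13L)
  fit <- train_trait_classifier(sep$patches, sep$labels, "gh", spec)
  m <- evaluate_trait_classifier(fit)
  expect_true(all(c("accuracy", "recall0", "recall1") %in% names(m)))
  # one-class test set: absent class reports NA recall, not 0
  keep <- which(fit$test$y == fit$classes[1])
  m1 <- evaluate_trait_classifier(
    fit, list(images = fit$test$images[keep], y = fit$test$y[keep]))
  expect_true(is.na(m1$recall1))
  expect_error(evaluate_trait_classifier(
    fit, list(images = list(), y = character(0))), "empty")
})
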