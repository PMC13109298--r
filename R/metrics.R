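#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`, the standard overlap measure for
#' segmentation masks and rasterized bounding rectangles. Undefined (error)
#' when both masks are empty.
#'
#' @param mask_a,mask_b logical (or 0/1) matrices of identical shape.
#' @return IoU in `[0, 1]`.
#' @export
mask_iou <- function(mask_a, mask_b) {
  stopifnot(all(dim(mask_a) == dim(mask_b)))
  a <- mask_a > 0; b <- mask_b > 0
  u <- sum(a | b)
  if (u == 0L) stop("IoU undefined: both masks empty", call. = FALSE)
  sum(a & b) / u
}

#' Pixel-wise segmentation metrics from confusion counts
#'
#' Specificity `TN / (TN + FP) * 100`, sensitivity `TP / (TP + FN) * 100`
#' (both percent), and the Dice coefficient `2 TP / (2 TP + FP + FN)`
#' (a fraction in `[0, 1]`). A metric with a zero denominator is reported
#' as `NA`, never as 0, so that aggregates stay honest.
#'
#' @param tp,tn,fp,fn non-negative pixel counts.
#' @return a one-row tibble with columns `specificity`, `sensitivity`,
#'   `dice`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  if (tp + tn + fp + fn == 0) stop("no pixels to score", call. = FALSE)
  spec <- if (tn + fp > 0) tn / (tn + fp) * 100 else NA_real_
  sens <- if (tp + fn > 0) tp / (tp + fn) * 100 else NA_real_
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  tibble::tibble(specificity = spec, sensitivity = sens, dice = dice)
}

# Confusion counts of a predicted binary mask against a truth mask.
confusion_counts <- function(pred, truth) {
  p <- pred > 0; t <- truth > 0
  list(tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Regression agreement metrics
#'
#' Coefficient of determination, RMSE (units of `y`), NRMSE normalized by
#' the observed range of `y` (percent), and MAPE (percent) between observed
#' and estimated values. R-squared is `NA` when `y` is constant; MAPE is
#' `NA` when any observed value is zero.
#'
#' @param y observed values.
#' @param y_hat estimated values, same length.
#' @return a one-row tibble with columns `r2`, `rmse`, `nrmse`, `mape`.
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  n <- length(y)
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  rmse <- sqrt(sse / n)
  rng <- max(y) - min(y)
  nrmse <- if (rng > 0) rmse / rng * 100 else NA_real_
  mape <- if (all(y != 0)) mean(abs((y - y_hat) / y)) * 100 else NA_real_
  tibble::tibble(r2 = r2, rmse = rmse, nrmse = nrmse, mape = mape)
}

#' Binary classification metrics
#'
#' Accuracy `(T0 + T1) / N * 100` and per-class recall
#' `T_c / (T_c + F_c) * 100`, where `T_c` counts samples of class `c`
#' classified correctly and `F_c` those of class `c` classified as the
#' other class. The recall of a class absent from the evaluation set is
#' `NA`, not 0.
#'
#' @param t0,t1 correctly classified counts for class 0 and class 1.
#' @param f0,f1 misclassified counts for class 0 and class 1.
#' @return a one-row tibble with columns `accuracy`, `recall0`, `recall1`
#'   (all percent).
#' @export
classification_metrics <- function(t0, t1, f0, f1) {
  n <- t0 + t1 + f0 + f1
  if (n == 0) stop("empty evaluation set", call. = FALSE)
  tibble::tibble(
    accuracy = (t0 + t1) / n * 100,
    recall0 = if (t0 + f0 > 0) t0 / (t0 + f0) * 100 else NA_real_,
    recall1 = if (t1 + f1 > 0) t1 / (t1 + f1) * 100 else NA_real_
  )
}

#' Rasterize a convex polygon to a binary mask
#'
#' Half-plane test against every edge (works for convex rings in either
#' winding order); used to compare detected bounding rectangles against
#' ground-truth rectangles pixel-wise.
#'
#' @param poly_px n x 2 matrix of polygon corners in 0-based pixel
#'   coordinates.
#' @param dim_out output dimensions `c(H, W)`.
#' @return a logical H x W matrix.
#' @export
rasterize_polygon <- function(poly_px, dim_out) {
  h <- dim_out[1]; w <- dim_out[2]
  xs <- rep(0:(w - 1), each = h); ys <- rep(0:(h - 1), times = w)
  n <- nrow(poly_px)
  pos <- rep(TRUE, length(xs)); neg <- rep(TRUE, length(xs))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly_px[j, 1] - poly_px[i, 1]; ey <- poly_px[j, 2] - poly_px[i, 2]
    cr <- ex * (ys - poly_px[i, 2]) - ey * (xs - poly_px[i, 1])
    pos <- pos & cr >= 0; neg <- neg & cr <= 0
  }
  matrix(pos | neg, h, w)
}
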