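#' Extract canopy height from a plot patch
#'
#' The nDSM patch is split horizontally at the computed plot center; the
#' chosen statistic (maximum by default, or an upper percentile) is taken
#' independently for each half — one crop row per half — and the plot's
#' canopy height is the mean of the two half statistics, in centimeters.
#' Single-row plots take the statistic over the whole patch (the plot
#' center is the centroid of the only row, so the split would bisect it).
#' An all-missing half falls back to the other half with a flag.
#'
#' @param patch a `plot_patch` from [plot_patches()].
#' @param stat `"max"`, `"p95"`, `"p97"` or `"p99"`.
#' @return a one-row tibble: `plot_id`, `ch_cm`, `ch_stat`, `flagged`.
#' @export
extract_canopy_height <- function(patch, stat = c("max", "p95", "p97", "p99")) {
  stat <- match.arg(stat)
  fn <- switch(stat,
    max = function(v) max(v),
    p95 = function(v) stats::quantile(v, 0.95, names = FALSE, type = 7),
    p97 = function(v) stats::quantile(v, 0.97, names = FALSE, type = 7),
    p99 = function(v) stats::quantile(v, 0.99, names = FALSE, type = 7))
  nd <- patch$ndsm
  flagged <- FALSE
  if (isTRUE(patch$single_row)) {
    v <- nd[!is.na(nd)]
    ch_m <- if (length(v)) fn(v) else NA_real_
  } else {
    cy <- max(1L, min(nrow(nd) - 1L, patch$center_y))
    top <- nd[seq_len(cy), , drop = FALSE]
    bot <- nd[(cy + 1L):nrow(nd), , drop = FALSE]
    vt <- top[!is.na(top)]; vb <- bot[!is.na(bot)]
    if (!length(vt) && !length(vb)) {
      ch_m <- NA_real_
    } else if (!length(vt) || !length(vb)) {
      flagged <- TRUE
      ch_m <- fn(c(vt, vb))
    } else {
      ch_m <- (fn(vt) + fn(vb)) / 2
    }
  }
  tibble::tibble(plot_id = patch$plot_id, ch_cm = 100 * ch_m,
                 ch_stat = stat, flagged = flagged)
}

#' Extract the canopy-height trait table for all plots
#'
#' @param patches list of `plot_patch` objects.
#' @param stat statistic passed to [extract_canopy_height()].
#' @return a tibble with one row per plot (`plot_id`, `ch_cm`, `ch_stat`,
#'   `flagged`).
#' @export
extract_traits <- function(patches, stat = "max") {
  dplyr::bind_rows(lapply(patches, extract_canopy_height, stat = stat))
}

#' Fuse the nDSM into the green channel of an RGB patch
#'
#' nDSM values (meters) are scaled by 100 into centimeters and added to
#' the G channel; sums are clipped to `[0, 255]`. R and B are unchanged,
#' so the fused image keeps the three-channel format expected by
#' image-classification backbones.
#'
#' @param rgb H x W x 3 array (0--255).
#' @param ndsm H x W matrix in meters (`NA` treated as 0).
#' @return the fused H x W x 3 array.
#' @export
fuse_ndsm_rgb <- function(rgb, ndsm) {
  stopifnot(all(dim(rgb)[1:2] == dim(ndsm)))
  nd <- ndsm
  nd[is.na(nd)] <- 0
  out <- rgb
  out[, , 2] <- pmin(255, pmax(0, round(rgb[, , 2] + 100 * nd)))
  out
}

# turn a patch into the 3-channel input for the requested modality
modality_image <- function(patch, modality) {
  switch(modality,
    rgb = patch$rgb,
    ndsm = {
      nd <- patch$ndsm
      nd[is.na(nd)] <- 0
      ch <- pmin(255, pmax(0, 100 * nd))
      array(rep(ch, 3), c(dim(nd), 3))
    },
    combined = fuse_ndsm_rgb(patch$rgb, patch$ndsm),
    stop("unknown modality: ", modality, call. = FALSE))
}

flip_h <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_v <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
mirror_t <- function(img) aperm(img, c(2, 1, 3))

#' Build stratified train/test datasets from labelled patches
#'
#' Splits plots into train and test with per-class stratification (seeded,
#' deterministic), converts each patch to the requested modality, and
#' augments the training set with horizontal flips, vertical flips and
#' mirroring (transpose) — four images per training plot.
#'
#' @param patches list of `plot_patch` objects.
#' @param labels tibble with `plot_id` and the class column named by
#'   `trait`.
#' @param trait name of the label column (e.g. `"gh"` or `"mp"`).
#' @param modality `"rgb"`, `"ndsm"` or `"combined"`.
#' @param split training fraction.
#' @param seed RNG seed for the split.
#' @param augment apply the three flip transforms to the training set.
#' @return list with `train` (`images`, `y`, `base_idx`, `variant`),
#'   `test` (`images`, `y`) and `classes`.
#' @export
build_dataset <- function(patches, labels, trait, modality = "rgb",
                          split = 0.8, seed = 1, augment = TRUE) {
  ids <- vapply(patches, function(p) p$plot_id, 0)
  lab <- labels[[trait]][match(ids, labels$plot_id)]
  if (anyNA(lab)) stop("missing labels for some plots", call. = FALSE)
  classes <- sort(unique(lab))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  tr_idx <- with_local_seed(seed, {
    unlist(lapply(classes, function(cl) {
      ii <- which(lab == cl)
      sample(ii, round(split * length(ii)))
    }))
  })
  te_idx <- setdiff(seq_along(patches), tr_idx)
  if (!all(classes %in% lab[tr_idx]) || !all(classes %in% lab[te_idx]))
    stop("a class is absent from the train or test split; insufficient data",
         call. = FALSE)
  imgs <- lapply(patches, modality_image, modality = modality)
  tr_imgs <- imgs[tr_idx]; tr_y <- lab[tr_idx]
  variant <- rep("orig", length(tr_idx)); base_idx <- seq_along(tr_idx)
  if (augment) {
    aug <- list(flip_h = flip_h, flip_v = flip_v, mirror = mirror_t)
    for (nm in names(aug)) {
      tr_imgs <- c(tr_imgs, lapply(imgs[tr_idx], aug[[nm]]))
      tr_y <- c(tr_y, lab[tr_idx])
      variant <- c(variant, rep(nm, length(tr_idx)))
      base_idx <- c(base_idx, seq_along(tr_idx))
    }
  }
  list(train = list(images = tr_imgs, y = tr_y, base_idx = base_idx,
                    variant = variant),
       test = list(images = imgs[te_idx], y = lab[te_idx]),
       classes = classes)
}

# ---- frozen convolutional feature bank -----------------------------------

#' Frozen convolutional feature bank
#'
#' A fixed (untrained) random-projection convolutional embedding: images
#' are resampled to 28 x 28, passed through a seeded bank of 3 x 3 x 3
#' filters with ReLU, and pooled (global mean, global max and a 4 x 4 grid
#' of means per filter, plus raw channel statistics). The backbone is
#' frozen; only the fully connected classification head on top of these
#' features is trained. `model_name` selects the bank size.
#'
#' @param model_name `"alexnet"` (8 filters), `"resnet18"` (16) or
#'   `"efficientnet_b0"` (24); the names label capacity tiers.
#' @return a `feature_bank` object.
#' @export
cnn_feature_bank <- function(model_name = c("alexnet", "resnet18",
                                            "efficientnet_b0")) {
  model_name <- match.arg(model_name)
  k <- switch(model_name, alexnet = 8L, resnet18 = 16L, efficientnet_b0 = 24L)
  seed <- sum(utf8ToInt(model_name))
  filt <- with_local_seed(seed, array(stats::rnorm(3 * 3 * 3 * k, sd = 0.5),
                                      c(3, 3, 3, k)))
  structure(list(model_name = model_name, k = k, filters = filt, side = 28L),
            class = "feature_bank")
}

# features for one image (H x W x 3, 0-255)
cnn_features <- function(img, bank) {
  s <- bank$side
  small <- array(0, c(s, s, 3))
  d <- dim(img)
  xs <- (rep(0:(s - 1), each = s) + 0.5) * d[2] / s - 0.5
  ys <- (rep(0:(s - 1), times = s) + 0.5) * d[1] / s - 0.5
  for (b in 1:3)
    small[, , b] <- matrix(bilinear_sample(img[, , b], xs, ys, 0), s, s) / 255
  base <- as.numeric(apply(small, 3, function(m) c(mean(m), stats::sd(m), max(m))))
  n <- s - 2L
  feats <- numeric(0)
  grid_cut <- function(m) {
    bx <- ceiling(seq_len(n) / (n / 4))
    as.numeric(tapply(as.numeric(m), list(rep(bx, times = n), rep(bx, each = n)), mean))
  }
  for (f in seq_len(bank$k)) {
    acc <- matrix(0, n, n)
    for (dy in 0:2) for (dx in 0:2) for (ch in 1:3)
      acc <- acc + bank$filters[dy + 1, dx + 1, ch, f] *
        small[(1 + dy):(n + dy), (1 + dx):(n + dx), ch]
    acc <- pmax(acc, 0)
    feats <- c(feats, mean(acc), max(acc), grid_cut(acc))
  }
  c(base, feats)
}

featurize <- function(images, bank) {
  t(vapply(images, cnn_features, numeric(9 + bank$k * 18), bank = bank))
}

# ---- trainable softmax head ----------------------------------------------

one_cycle_lr <- function(step, total, lr_max, final_frac = 0.001,
                         warmup = 0.1) {
  wsteps <- max(1, round(warmup * total))
  if (step <= wsteps) return(lr_max * step / wsteps)
  t <- (step - wsteps) / max(1, total - wsteps)
  lr_min <- final_frac * lr_max
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t))
}

# AdamW-trained softmax (multinomial logistic) head with input dropout and
# a one-cycle cosine learning-rate schedule decaying to 0.001 x initial.
train_softmax_head <- function(X, y, classes, epochs, batch, lr,
                               dropout = 0.5, weight_decay = 0.01,
                               seed = 1) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  n <- nrow(Xs); d <- ncol(Xs); C <- length(classes)
  Y <- matrix(0, n, C); Y[cbind(seq_len(n), match(y, classes))] <- 1
  with_local_seed(seed, {
    W <- matrix(stats::rnorm(d * C, sd = 0.01), d, C); b <- rep(0, C)
    mW <- vW <- matrix(0, d, C); mb <- vb <- rep(0, C)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    steps_per_epoch <- ceiling(n / batch)
    total <- epochs * steps_per_epoch
    step <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (s in seq(1, n, by = batch)) {
        ii <- ord[s:min(n, s + batch - 1)]
        step <- step + 1L
        Xb <- Xs[ii, , drop = FALSE]
        if (dropout > 0) {
          keep <- matrix(stats::runif(length(Xb)) >= dropout, nrow(Xb))
          Xb <- Xb * keep / (1 - dropout)
        }
        logits <- sweep(Xb %*% W, 2, b, `+`)
        logits <- logits - apply(logits, 1, max)
        P <- exp(logits); P <- P / rowSums(P)
        G <- (P - Y[ii, , drop = FALSE]) / length(ii)
        gW <- crossprod(Xb, G); gb <- colSums(G)
        lr_t <- one_cycle_lr(step, total, lr)
        mW <- b1 * mW + (1 - b1) * gW; vW <- b2 * vW + (1 - b2) * gW^2
        mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
        mhW <- mW / (1 - b1^step); vhW <- vW / (1 - b2^step)
        mhb <- mb / (1 - b1^step); vhb <- vb / (1 - b2^step)
        W <- W - lr_t * (mhW / (sqrt(vhW) + eps) + weight_decay * W)
        b <- b - lr_t * mhb / (sqrt(vhb) + eps)
      }
    }
    structure(list(W = W, b = b, mu = mu, sd = sdv, classes = classes),
              class = "softmax_head")
  })
}

predict_head <- function(head, X) {
  Xs <- sweep(sweep(X, 2, head$mu), 2, head$sd, `/`)
  logits <- sweep(Xs %*% head$W, 2, head$b, `+`)
  head$classes[max.col(logits, ties.method = "first")]
}

macro_f1 <- function(truth, pred, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

#' Training specification for trait classifiers
#'
#' The hyperparameter grid and protocol: batch sizes 16 and 32, 10/15/20
#' epochs, learning rates 1e-5/1e-4/1e-3 (18 combinations), dropout 0.5,
#' weight decay 0.01, 5-fold cross-validation on the training split scored
#' by macro F1, and the best combination retrained and tested `runs`
#' times.
#'
#' @param model_name backbone tier, see [cnn_feature_bank()].
#' @param modality `"rgb"`, `"ndsm"` or `"combined"`.
#' @param batch,epochs,lr grid values.
#' @param dropout,weight_decay regularization.
#' @param folds CV folds.
#' @param runs repeated train/test runs of the selected combination.
#' @param split train fraction.
#' @param seed master seed; fans out to split, folds, and per-run
#'   initialization.
#' @return a `train_spec` list.
#' @export
train_spec <- function(model_name = "alexnet", modality = "combined",
                       batch = c(16L, 32L), epochs = c(10L, 15L, 20L),
                       lr = c(1e-5, 1e-4, 1e-3), dropout = 0.5,
                       weight_decay = 0.01, folds = 5L, runs = 10L,
                       split = 0.8, seed = 1L) {
  stopifnot(all(batch %in% c(16L, 32L)), all(epochs %in% c(10L, 15L, 20L)),
            all(lr %in% c(1e-5, 1e-4, 1e-3)), split > 0, split < 1)
  structure(as.list(environment()), class = "train_spec")
}

#' Train a trait classifier
#'
#' Fine-tunes the fully connected head on top of the frozen feature bank:
#' grid search over the spec's hyperparameter combinations by stratified
#' k-fold cross-validation on the training split (validation folds are
#' scored on unaugmented images, training folds use the augmented set),
#' selection by mean macro F1, then `runs` repeated train/test evaluations
#' of the winning combination with different initializations.
#'
#' @param patches list of `plot_patch` objects.
#' @param labels tibble with `plot_id` and the trait column.
#' @param trait label column name (`"gh"` or `"mp"`).
#' @param spec a [train_spec()].
#' @return a `trait_classifier` with elements `head` (best run's model),
#'   `cv_table`, `runs`, `best`, `bank`, `spec`, `classes`, `test_metrics`.
#' @export
train_trait_classifier <- function(patches, labels, trait,
                                   spec = train_spec()) {
  ds <- build_dataset(patches, labels, trait, modality = spec$modality,
                      split = spec$split, seed = spec$seed)
  bank <- cnn_feature_bank(spec$model_name)
  Xtr <- featurize(ds$train$images, bank)
  Xte <- featurize(ds$test$images, bank)
  ytr <- ds$train$y
  base <- ds$train$base_idx
  n_base <- max(base)
  y_base <- ytr[seq_len(n_base)]
  folds <- with_local_seed(spec$seed + 1L, {
    f <- integer(n_base)
    for (cl in ds$classes) {
      ii <- sample(which(y_base == cl))
      f[ii] <- rep_len(seq_len(spec$folds), length(ii))
    }
    f
  })
  grid <- expand.grid(batch = spec$batch, epochs = spec$epochs, lr = spec$lr)
  cv <- lapply(seq_len(nrow(grid)), function(gi) {
    scores <- vapply(seq_len(spec$folds), function(k) {
      val <- which(folds == k)
      tr_rows <- which(!(base %in% val))
      head <- train_softmax_head(
        Xtr[tr_rows, , drop = FALSE], ytr[tr_rows], ds$classes,
        epochs = grid$epochs[gi], batch = grid$batch[gi], lr = grid$lr[gi],
        dropout = spec$dropout, weight_decay = spec$weight_decay,
        seed = spec$seed + 100L * gi + k)
      pred <- predict_head(head, Xtr[val, , drop = FALSE])
      macro_f1(y_base[val], pred, ds$classes)
    }, 0)
    cbind(grid[gi, ], mean_f1 = mean(scores), sd_f1 = stats::sd(scores))
  })
  cv_table <- tibble::as_tibble(dplyr::bind_rows(cv))
  best <- cv_table[which.max(cv_table$mean_f1), ]
  runs <- vector("list", spec$runs)
  heads <- vector("list", spec$runs)
  for (r in seq_len(spec$runs)) {
    run_seed <- spec$seed + 1000L + r
    heads[[r]] <- train_softmax_head(
      Xtr, ytr, ds$classes, epochs = best$epochs, batch = best$batch,
      lr = best$lr, dropout = spec$dropout,
      weight_decay = spec$weight_decay, seed = run_seed)
    pred <- predict_head(heads[[r]], Xte)
    m <- eval_counts(ds$test$y, pred, ds$classes)
    runs[[r]] <- dplyr::bind_cols(tibble::tibble(run = r, seed = run_seed), m)
  }
  runs <- dplyr::bind_rows(runs)
  best_run <- which.max(runs$accuracy)
  structure(list(head = heads[[best_run]], cv_table = cv_table,
                 runs = runs, best = best, bank = bank, spec = spec,
                 classes = ds$classes, trait = trait,
                 test = ds$test), class = "trait_classifier")
}

eval_counts <- function(truth, pred, classes) {
  t0 <- sum(truth == classes[1] & pred == classes[1])
  f0 <- sum(truth == classes[1] & pred != classes[1])
  t1 <- sum(truth == classes[2] & pred == classes[2])
  f1 <- sum(truth == classes[2] & pred != classes[2])
  classification_metrics(t0, t1, f0, f1)
}

#' @export
predict.trait_classifier <- function(object, patches, ...) {
  imgs <- lapply(patches, modality_image, modality = object$spec$modality)
  predict_head(object$head, featurize(imgs, object$bank))
}

#' Evaluate a trait classifier on a labelled test set
#'
#' Accuracy and per-class recall (percent). Class 0 is the first class in
#' the model's class order; a class absent from the test set gets `NA`
#' recall.
#'
#' @param fit a `trait_classifier`.
#' @param testset list with `images` (modality images) and `y` (labels);
#'   defaults to the held-out test split stored in the fit.
#' @return a one-row tibble: `accuracy`, `recall0`, `recall1`.
#' @export
evaluate_trait_classifier <- function(fit, testset = fit$test) {
  if (length(testset$y) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict_head(fit$head, featurize(testset$images, fit$bank))
  eval_counts(testset$y, pred, fit$classes)
}

#' @export
tidy.trait_classifier <- function(x, ...) x$runs

#' @export
glance.trait_classifier <- function(x, ...) {
  tibble::tibble(trait = x$trait, model = x$spec$model_name,
                 modality = x$spec$modality,
                 batch = x$best$batch, epochs = x$best$epochs,
                 lr = x$best$lr,
                 accuracy_mean = mean(x$runs$accuracy),
                 accuracy_sd = stats::sd(x$runs$accuracy),
                 n_runs = nrow(x$runs))
}

#' @export
print.trait_classifier <- function(x, ...) {
  cat(sprintf("<trait_classifier %s | %s/%s | acc %.1f%% (sd %.1f) over %d runs>\n",
              x$trait, x$spec$model_name, x$spec$modality,
              mean(x$runs$accuracy), stats::sd(x$runs$accuracy),
              nrow(x$runs)))
  invisible(x)
}

# broom-style generics (defined here so no broom dependency is needed)
#' Turn a fitted object into a tidy tibble
#' @param x object to tidy.
#' @param ... unused.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model summary
#' @param x fitted object.
#' @param ... unused.
#' @export
glance <- function(x, ...) UseMethod("glance")
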