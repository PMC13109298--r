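vegetation_index_values <- function(vals) {
  stopifnot(length(dim(vals)) == 3L)
  d <- dim(vals)[1:2]
  R <- vals[, , 1]; G <- vals[, , 2]; B <- vals[, , 3]
  S <- R + G + B
  score <- ifelse(S > 0, (3 * G - 2.4 * R - B) / S, 0)
  dim(score) <- d
  list(score = score, mask = score > 0)
}

#' Excess Green minus Excess Red vegetation index
#'
#' Computes ExG - ExR on chromatic coordinates: with
#' `r = R/(R+G+B)` (and likewise `g`, `b`), `ExG = 2g - r - b` and
#' `ExR = 1.4r - g`, so the score is `3g - 2.4r - b`. Pixels with
#' `R + G + B = 0` score 0 (non-vegetation). Positive scores flag
#' vegetation.
#'
#' @param rgb an RGB [raster_grid()] or H x W x 3 array (0--255).
#' @return a `veg_map`: list with `score` (float matrix) and `mask`
#'   (`score > 0`).
#' @export
vegetation_index <- function(rgb) {
  vals <- if (inherits(rgb, "raster_grid")) rgb$values else rgb
  out <- vegetation_index_values(vals)
  class(out) <- "veg_map"
  out
}

moving_average <- function(v, width) {
  width <- max(1L, as.integer(round(width)))
  if (width <= 1L) return(v)
  k <- rep(1 / width, width)
  as.numeric(stats::filter(v, k, sides = 2, circular = FALSE)) -> sm
  sm[is.na(sm)] <- v[is.na(sm)]
  sm
}

#' Detect crop ranges from the vegetation column profile
#'
#' Sums vegetation pixels down each column; maximal runs where the smoothed
#' profile falls below `valley_frac` of its maximum are treated as bare
#' alleys, and the midpoints of interior valleys become the boundaries
#' between adjacent crop ranges. Valleys touching the image edges clamp
#' their boundary to the edge.
#'
#' @param veg a `veg_map` from [vegetation_index()].
#' @param valley_frac valley threshold as a fraction of the profile maximum.
#' @param smooth_px moving-average window for the profile (px).
#' @return a tibble with columns `x_start`, `x_end` (half-open pixel
#'   intervals, 0-based), one row per detected range; empty when the
#'   profile is all zero.
#' @export
detect_ranges <- function(veg, valley_frac = 0.1, smooth_px = 1) {
  prof <- colSums(veg$mask)
  if (max(prof) == 0) return(tibble::tibble(x_start = integer(), x_end = integer()))
  sm <- moving_average(prof, smooth_px)
  low <- sm < valley_frac * max(sm)
  w <- length(prof)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bounds <- 0
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    if (starts[i] == 1L || ends[i] == w) next  # edge valley: clamp to edge
    bounds <- c(bounds, (starts[i] - 1L + ends[i] - 1L) / 2)
  }
  bounds <- c(bounds, w)
  iv <- tibble::tibble(x_start = bounds[-length(bounds)], x_end = bounds[-1])
  # keep only intervals that actually contain vegetation
  has_veg <- vapply(seq_len(nrow(iv)), function(i) {
    cols <- seq.int(floor(iv$x_start[i]) + 1L, ceiling(iv$x_end[i]))
    any(prof[cols[cols >= 1 & cols <= w]] > 0)
  }, TRUE)
  iv[has_veg, ]
}

# greedy peak picking: local maxima above `frac * max`, descending height,
# enforcing a minimum separation
find_peaks <- function(prof, frac, min_sep) {
  if (max(prof) == 0) return(numeric(0))
  thr <- frac * max(prof)
  n <- length(prof)
  cand <- which(prof >= thr)
  cand <- cand[vapply(cand, function(i) {
    l <- if (i > 1) prof[i - 1] else -Inf
    r <- if (i < n) prof[i + 1] else -Inf
    prof[i] >= l && prof[i] >= r
  }, TRUE)]
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(prof[cand], cand, decreasing = c(TRUE, FALSE), method = "radix")]
  acc <- numeric(0)
  for (i in cand)
    if (!length(acc) || min(abs(acc - i)) >= min_sep) acc <- c(acc, i)
  sort(acc) - 1  # 0-based pixel rows
}

#' Detect crop rows within one range
#'
#' Sums vegetation pixels along each row restricted to the range's column
#' interval; local maxima of the smoothed profile above `peak_frac` of its
#' maximum, separated by at least half the expected row spacing, are the
#' crop rows.
#'
#' @param veg a `veg_map`.
#' @param interval one row of [detect_ranges()]'s output (or a list with
#'   `x_start`, `x_end`).
#' @param row_spacing_px expected row spacing in pixels.
#' @param peak_frac peak threshold as a fraction of the profile maximum.
#' @return numeric vector of row y positions (0-based), sorted; may be
#'   empty.
#' @export
detect_rows <- function(veg, interval, row_spacing_px, peak_frac = 0.3) {
  cols <- seq.int(max(1L, floor(interval$x_start) + 1L),
                  min(ncol(veg$mask), ceiling(interval$x_end)))
  prof <- rowSums(veg$mask[, cols, drop = FALSE])
  if (max(prof) == 0) return(numeric(0))
  sm <- moving_average(prof, 0.25 * row_spacing_px)
  find_peaks(sm, peak_frac, 0.5 * row_spacing_px)
}

#' Detect the full range-row layout and provisional plot centroids
#'
#' Runs [detect_ranges()] and [detect_rows()] and places one provisional
#' centroid per (range, row): y at the detected row, x at the center of
#' mass of the vegetation pixels in a band around the row inside the range
#' interval.
#'
#' @param veg a `veg_map`.
#' @param row_spacing_px expected row spacing in pixels.
#' @param valley_frac,peak_frac profile thresholds.
#' @return a `row_layout`: list with `ranges` (tibble) and `centroids`
#'   (tibble `x`, `y`, `range_idx`, `row_idx`).
#' @export
detect_layout <- function(veg, row_spacing_px, valley_frac = 0.1,
                          peak_frac = 0.3) {
  ranges <- detect_ranges(veg, valley_frac, smooth_px = 0.25 * row_spacing_px)
  cents <- list()
  for (i in seq_len(nrow(ranges))) {
    ys <- detect_rows(veg, ranges[i, ], row_spacing_px, peak_frac)
    if (!length(ys)) next
    cols <- seq.int(max(1L, floor(ranges$x_start[i]) + 1L),
                    min(ncol(veg$mask), ceiling(ranges$x_end[i])))
    for (j in seq_along(ys)) {
      band <- seq.int(max(1L, round(ys[j] - 0.25 * row_spacing_px) + 1L),
                      min(nrow(veg$mask), round(ys[j] + 0.25 * row_spacing_px) + 1L))
      sub <- veg$mask[band, cols, drop = FALSE]
      px <- which(sub, arr.ind = TRUE)
      cx <- if (nrow(px)) mean(cols[px[, 2]]) - 1 else mean(cols) - 1
      cy <- if (nrow(px)) mean(band[px[, 1]]) - 1 else ys[j]
      cents[[length(cents) + 1L]] <- tibble::tibble(
        x = cx, y = cy, range_idx = i, row_idx = j)
    }
  }
  structure(list(ranges = ranges,
                 centroids = dplyr::bind_rows(cents)),
            class = "row_layout")
}

#' Build point prompts for one target centroid
#'
#' The target centroid is the foreground point; the `k` nearest other
#' centroids (typically the rows above/below and the adjacent ranges) are
#' background points.
#'
#' @param layout a `row_layout` from [detect_layout()].
#' @param target_idx row index into `layout$centroids`.
#' @param k number of background points.
#' @return list with `fg` (1 x 2 matrix) and `bg` (up to k x 2 matrix).
#' @export
make_prompts <- function(layout, target_idx, k = 4) {
  cents <- layout$centroids
  stopifnot(target_idx >= 1, target_idx <= nrow(cents))
  tgt <- c(cents$x[target_idx], cents$y[target_idx])
  others <- cents[-target_idx, , drop = FALSE]
  if (nrow(others) == 0L)
    return(list(fg = matrix(tgt, 1, dimnames = list(NULL, c("x", "y"))),
                bg = matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))))
  d <- sqrt((others$x - tgt[1])^2 + (others$y - tgt[2])^2)
  near <- order(d)[seq_len(min(k, nrow(others)))]
  list(fg = matrix(tgt, 1, dimnames = list(NULL, c("x", "y"))),
       bg = as.matrix(others[near, c("x", "y")]))
}

#' Segment all rows with point prompts
#'
#' For every provisional centroid, queries the backend with its prompts,
#' clips the returned mask to the centroid's range interval and writes it
#' into a label raster under a unique positive label. Pixels claimed by
#' more than one centroid go to the nearest centroid; centroids whose
#' query returns an empty mask are flagged missing.
#'
#' @param image RGB [raster_grid()] or array.
#' @param layout a `row_layout`.
#' @param backend a [seg_backend()].
#' @param k background points per prompt.
#' @return list with `labels` (integer matrix; 0 = background) and
#'   `centroids` (the layout centroids plus `label` and `missing`).
#' @export
segment_rows <- function(image, layout, backend = seg_backend(), k = 4) {
  cents <- layout$centroids
  if (is.null(cents) || nrow(cents) == 0L) stop("empty layout", call. = FALSE)
  vals <- if (inherits(image, "raster_grid")) image$values else image
  comp <- if (backend$backend == "classical") vegetation_components(vals) else NULL
  out <- matrix(0L, dim(vals)[1], dim(vals)[2])
  owner_x <- numeric(0); owner_y <- numeric(0)  # centroid per label
  cents$label <- 0L
  cents$missing <- FALSE
  for (i in seq_len(nrow(cents))) {
    pr <- make_prompts(layout, i, k)
    m <- suppressWarnings(
      prompt_mask(vals, pr$fg, pr$bg, backend = backend, labels = comp))
    iv <- layout$ranges[cents$range_idx[i], ]
    keep_cols <- seq.int(max(1L, floor(iv$x_start) + 1L),
                         min(ncol(m), ceiling(iv$x_end)))
    clip <- matrix(FALSE, nrow(m), ncol(m))
    clip[, keep_cols] <- m[, keep_cols]
    if (!any(clip)) {
      cents$missing[i] <- TRUE
      next
    }
    lab <- max(out) + 1L
    conflict <- clip & out > 0L
    free <- clip & out == 0L
    out[free] <- lab
    if (any(conflict)) {
      idx <- which(conflict, arr.ind = TRUE)
      d_new <- (idx[, 2] - 1 - cents$x[i])^2 + (idx[, 1] - 1 - cents$y[i])^2
      old <- out[conflict]
      d_old <- (idx[, 2] - 1 - owner_x[old])^2 + (idx[, 1] - 1 - owner_y[old])^2
      take <- d_new < d_old
      out[conflict][take] <- lab
    }
    owner_x[lab] <- cents$x[i]; owner_y[lab] <- cents$y[i]
    cents$label[i] <- lab
  }
  list(labels = out, centroids = cents)
}
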