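#' Detect raised-bed boundary lines from the nDSM
#'
#' Tractor tracks between raised beds sit below the bed-top terrain model,
#' so they show up as negative values in the nDSM. Pixels below
#' `-depth_threshold_m` vote in a Hough accumulator restricted to
#' near-horizontal lines (`|theta| <= angle_window_deg`); accumulator peaks
#' above `min_support` are merged when closer than half a bed width and
#' returned as bed boundary lines sorted by their y position at the image
#' center.
#'
#' @param ndsm the nDSM [raster_grid()].
#' @param bed_width_px expected bed pitch in pixels (sets the merge
#'   distance).
#' @param depth_threshold_m depth below the terrain model that counts as a
#'   track pixel.
#' @param angle_window_deg half-width of the angular search window around
#'   horizontal.
#' @param angle_step_deg angular resolution of the accumulator.
#' @param min_support_frac minimum voting pixels for a line, as a fraction
#'   of the raster width.
#' @return a tibble with columns `y` (0-based row at the image center
#'   column) and `support`, sorted by `y`.
#' @export
detect_bed_lines <- function(ndsm, bed_width_px,
                             depth_threshold_m = 0.01,
                             angle_window_deg = 2,
                             angle_step_deg = 0.25,
                             min_support_frac = 0.25) {
  v <- ndsm$values
  neg <- v < -depth_threshold_m & v != ndsm$nodata
  if (!any(neg))
    stop("no negative-elevation pixels below the threshold; ",
         "lower `depth_threshold_m` or supply the known bed pitch",
         call. = FALSE)
  px <- which(neg, arr.ind = TRUE)
  x <- px[, 2] - 1; y <- px[, 1] - 1
  w <- ncol(v)
  min_support <- min_support_frac * w
  x_c <- (w - 1) / 2
  angles <- seq(-angle_window_deg, angle_window_deg, by = angle_step_deg)
  hits <- list()
  for (a in angles) {
    th <- a * pi / 180
    rho <- round(y * cos(th) - x * sin(th))
    tab <- table(rho)
    good <- tab[tab >= min_support]
    if (!length(good)) next
    rr <- as.numeric(names(good))
    hits[[length(hits) + 1L]] <- tibble::tibble(
      y = (rr + x_c * sin(th)) / cos(th),
      support = as.numeric(good))
  }
  if (!length(hits))
    stop("no bed boundary lines found; ",
         "adjust `depth_threshold_m`/`min_support_frac` or use the known bed pitch",
         call. = FALSE)
  cand <- dplyr::bind_rows(hits)
  cand <- cand[order(cand$y), ]
  merge_dist <- 0.5 * bed_width_px
  grp <- cumsum(c(1, diff(cand$y) > merge_dist))
  merged <- dplyr::summarise(
    dplyr::group_by(cand, .grp = grp),
    y = stats::weighted.mean(.data$y, .data$support),
    support = max(.data$support),
    .groups = "drop")
  dplyr::arrange(merged[, c("y", "support")], .data$y)
}

#' Delineate two-row plots from ranges, bed lines and row masks
#'
#' Bed boundary lines and crop-range limits tile the field into candidate
#' plot cells. Every cell containing at least one row mask becomes a plot:
#' its center is the center of mass of all mask pixels in the cell, its
#' bounding box is `box_px` x `box_px` centered there (shifted inward at
#' raster edges so crops stay within real data), and it is flagged
#' single-row when exactly one row mask is present. Plot IDs are assigned
#' bed-major, then range left-to-right.
#'
#' @param ranges tibble of range intervals from [detect_ranges()].
#' @param bed_lines tibble from [detect_bed_lines()] (needs >= 2 lines).
#' @param row_labels integer label raster from [segment_rows()].
#' @param box_px bounding-box side length (px).
#' @return a tibble of plot records: `plot_id`, `range_idx`, `bed_idx`,
#'   `center_x`, `center_y`, `bbox_x0`, `bbox_y0`, `bbox_w`, `bbox_h`,
#'   `single_row`, `n_rows`, `labels` (list of row-mask labels).
#' @export
delineate_plots <- function(ranges, bed_lines, row_labels, box_px = 224L) {
  if (nrow(bed_lines) < 2L) stop("need at least 2 bed lines", call. = FALSE)
  if (nrow(ranges) < 1L) stop("need at least 1 range", call. = FALSE)
  h <- nrow(row_labels); w <- ncol(row_labels)
  px <- which(row_labels > 0L, arr.ind = TRUE)
  if (!nrow(px)) return(empty_plot_records())
  x <- px[, 2] - 1; y <- px[, 1] - 1
  lab <- row_labels[px]
  bed_breaks <- sort(bed_lines$y)
  bed_idx <- findInterval(y, bed_breaks)  # 0 = above first line
  rng_idx <- integer(length(x))
  for (i in seq_len(nrow(ranges)))
    rng_idx[x >= ranges$x_start[i] & x < ranges$x_end[i]] <- i
  ok <- bed_idx >= 1L & bed_idx < length(bed_breaks) & rng_idx >= 1L
  if (!any(ok)) return(empty_plot_records())
  x <- x[ok]; y <- y[ok]; lab <- lab[ok]
  bed_idx <- bed_idx[ok]; rng_idx <- rng_idx[ok]
  cell <- paste(bed_idx, rng_idx)
  recs <- lapply(split(seq_along(x), cell), function(ii) {
    tibble::tibble(
      bed_idx = bed_idx[ii[1]], range_idx = rng_idx[ii[1]],
      center_x = mean(x[ii]), center_y = mean(y[ii]),
      n_rows = length(unique(lab[ii])),
      labels = list(sort(unique(lab[ii]))))
  })
  out <- dplyr::bind_rows(recs)
  out <- dplyr::arrange(out, .data$bed_idx, .data$range_idx)
  out$plot_id <- seq_len(nrow(out))
  out$single_row <- out$n_rows == 1L
  half <- box_px %/% 2L
  out$bbox_x0 <- pmax(0L, pmin(w - box_px, as.integer(round(out$center_x)) - half))
  out$bbox_y0 <- pmax(0L, pmin(h - box_px, as.integer(round(out$center_y)) - half))
  out$bbox_w <- as.integer(box_px)
  out$bbox_h <- as.integer(box_px)
  out[, c("plot_id", "range_idx", "bed_idx", "center_x", "center_y",
          "bbox_x0", "bbox_y0", "bbox_w", "bbox_h", "single_row",
          "n_rows", "labels")]
}

empty_plot_records <- function() {
  tibble::tibble(plot_id = integer(), range_idx = integer(),
                 bed_idx = integer(), center_x = numeric(),
                 center_y = numeric(), bbox_x0 = integer(),
                 bbox_y0 = integer(), bbox_w = integer(), bbox_h = integer(),
                 single_row = logical(), n_rows = integer(), labels = list())
}

#' Extract per-plot image patches
#'
#' Crops the RGB orthomosaic, the nDSM and the row-label raster to each
#' plot's bounding box. nDSM nodata cells become `NA` in the patch.
#'
#' @param plots plot records from [delineate_plots()].
#' @param ortho RGB [raster_grid()].
#' @param ndsm nDSM [raster_grid()].
#' @param row_labels integer label raster (optional; used for the mask
#'   channel and the single-row occupancy split).
#' @return a list of `plot_patch` objects: `rgb` (box x box x 3), `ndsm`
#'   (box x box, meters, `NA` = nodata), `mask` (logical), `center_y`
#'   (split row within the patch, 0-based), `plot_id`, `single_row`.
#' @export
plot_patches <- function(plots, ortho, ndsm, row_labels = NULL) {
  lapply(seq_len(nrow(plots)), function(i) {
    x0 <- plots$bbox_x0[i]; y0 <- plots$bbox_y0[i]
    w <- plots$bbox_w[i]; h <- plots$bbox_h[i]
    nd <- crop_raster_values(ndsm$values, x0, y0, w, h)
    nd[nd == ndsm$nodata] <- NA_real_
    mask <- if (!is.null(row_labels)) {
      sub <- crop_raster_values(row_labels, x0, y0, w, h)
      if (length(plots$labels[[i]])) sub %in% plots$labels[[i]] &
        matrix(TRUE, h, w) else sub > 0
    } else NULL
    if (!is.null(mask)) mask <- matrix(mask, h, w)
    structure(list(
      rgb = crop_raster_values(ortho$values, x0, y0, w, h),
      ndsm = nd,
      mask = mask,
      center_y = round(plots$center_y[i]) - y0,
      plot_id = plots$plot_id[i],
      single_row = plots$single_row[i]), class = "plot_patch")
  })
}
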