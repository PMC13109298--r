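make_ndsm <- function(h, w, stripe_rows = NULL, depth = 0.05) {
  v <- matrix(0.02, h, w)
  for (y in stripe_rows) v[(y - 1):(y + 3), ] <- -depth
  raster_grid(v, gsd_cm = 1)
}

test_that("Hough detection finds horizontal track stripes", {
  nd <- make_ndsm(300, 400, stripe_rows = c(100, 200))
  lines <- detect_bed_lines(nd, bed_width_px = 90)
  expect_equal(nrow(lines), 2L)
  expect_equal(lines$y[1], 100.5, tolerance = 1.5)
  expect_equal(lines$y[2], 200.5, tolerance = 1.5)
  expect_true(all(lines$support > 0))
})

test_that("an all-positive nDSM raises an informative error", {
  nd <- raster_grid(matrix(0.05, 50, 50), gsd_cm = 1)
  expect_error(detect_bed_lines(nd, bed_width_px = 20), "threshold")
})

test_that("slightly tilted stripes stay inside the angular window", {
  h <- 200; w <- 400
  v <- matrix(0.02, h, w)
  for (x in 0:(w - 1)) {
    yc <- round(100 + tan(1 * pi / 180) * (x - w / 2))
    v[(yc - 1):(yc + 1) + 1, x + 1] <- -0.05
  }
  nd <- raster_grid(v, gsd_cm = 1)
  lines <- detect_bed_lines(nd, bed_width_px = 90)
  expect_equal(nrow(lines), 1L)
  expect_equal(lines$y, 100, tolerance = 2)
})

test_that("plots are delineated cell-by-cell with bed-major IDs", {
  labels <- matrix(0L, 300, 400)
  # 2 ranges x 2 bed cells; two row masks per cell except one single-row
  put <- function(lab, x0, y0) {
    labels[(y0 + 1):(y0 + 10), (x0 + 1):(x0 + 40)] <<- lab
  }
  put(1L, 30, 60); put(2L, 30, 110)    # range 1, bed 1
  put(3L, 230, 60); put(4L, 230, 110)  # range 2, bed 1
  put(5L, 30, 160)                     # range 1, bed 2 (single row)
  put(6L, 230, 160); put(7L, 230, 210)
  ranges <- tibble::tibble(x_start = c(0, 200), x_end = c(200, 400))
  bed_lines <- tibble::tibble(y = c(40, 140, 240), support = 100)
  plots <- delineate_plots(ranges, bed_lines, labels, box_px = 100L)
  expect_equal(nrow(plots), 4L)
  expect_equal(plots$plot_id, 1:4)
  # bed-major then range order
  expect_equal(plots$bed_idx, c(1L, 1L, 2L, 2L))
  expect_equal(plots$range_idx, c(1L, 2L, 1L, 2L))
  expect_equal(plots$single_row, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(plots$n_rows, c(2L, 2L, 1L, 2L))
  # centers are the cell's mask centers of mass
  expect_equal(plots$center_x[1], mean(c(30:69)), tolerance = 1e-9)
  expect_equal(plots$center_y[1], mean(c(60:69, 110:119)), tolerance = 1e-9)
  # boxes are clamped fully inside the raster and keep their size
  expect_true(all(plots$bbox_x0 >= 0 & plots$bbox_x0 + plots$bbox_w <= 400))
  expect_true(all(plots$bbox_y0 >= 0 & plots$bbox_y0 + plots$bbox_h <= 300))
  expect_true(all(plots$bbox_w == 100L))

  expect_error(delineate_plots(ranges, bed_lines[1, ], labels), "2 bed lines")
  expect_error(delineate_plots(ranges[0, ], bed_lines, labels), "1 range")
})

test_that("boxes near the raster edge shift inward, staying full size", {
  labels <- matrix(0L, 300, 300)
  labels[100:120, 21:60] <- 1L  # center ~50 px from the left edge
  ranges <- tibble::tibble(x_start = 0, x_end = 300)
  bed_lines <- tibble::tibble(y = c(80, 180), support = 10)
  plots <- delineate_plots(ranges, bed_lines, labels, box_px = 224L)
  expect_equal(plots$bbox_x0, 0L)
  expect_equal(plots$bbox_w, 224L)
})

test_that("patches crop all modalities to the plot box", {
  f <- tiny_field(n_ranges = 2, n_beds = 2, seed = 10)
  veg <- vegetation_index(f$ortho)
  lay <- detect_layout(veg, 0.91 * 100 / f$ortho$gsd_cm)
  seg <- segment_rows(f$ortho, lay)
  bed_px <- 1.82 * 100 / f$ortho$gsd_cm
  s <- sample_terrain_points(seg$labels, f$dsm, offset_px = 25,
                             veg_mask = veg$mask)
  dtm <- build_dtm(s, dim(f$dsm$values), gsd_cm = f$dsm$gsd_cm)
  ndsm <- compute_ndsm(f$dsm, dtm)
  lines <- detect_bed_lines(ndsm, bed_width_px = bed_px)
  plots <- delineate_plots(lay$ranges, lines, seg$labels)
  expect_equal(nrow(plots), 4L)
  patches <- plot_patches(plots, f$ortho, ndsm, seg$labels)
  for (p in patches) {
    expect_equal(dim(p$rgb), c(224L, 224L, 3L))
    expect_equal(dim(p$ndsm), c(224L, 224L))
    expect_true(p$center_y >= 0 && p$center_y < 224)
  }
})
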