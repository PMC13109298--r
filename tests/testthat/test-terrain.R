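test_that("two terrain samples are taken per mask, away from vegetation", {
  labels <- matrix(0L, 60, 120)
  labels[20:30, 30:50] <- 1L
  labels[20:30, 80:100] <- 2L
  dsm <- raster_grid(matrix(50, 60, 120), gsd_cm = 1)
  s <- sample_terrain_points(labels, dsm, offset_px = 10)
  expect_equal(nrow(s), 4L)
  expect_equal(unname(c(table(s$plot_id))), c(2L, 2L))
  s1 <- s[s$plot_id == 1, ]
  expect_equal(sort(s1$x), c(29 - 10, 49 + 10))
  expect_equal(unique(s1$y), 24)  # centroid row of rows 20:30 (0-based)
  expect_false(any(s$clamped))
  # every sample lies outside every mask
  expect_true(all(labels[cbind(s$y + 1, s$x + 1)] == 0L))
})

test_that("masks flush with the raster edge keep one flagged sample", {
  labels <- matrix(0L, 30, 40)
  labels[10:20, 1:39] <- 1L  # nearly full-width mask
  dsm <- raster_grid(matrix(50, 30, 40), gsd_cm = 1)
  s <- sample_terrain_points(labels, dsm, offset_px = 10)
  expect_true(any(s$clamped))
})

test_that("samples read the true terrain on a noise-free field", {
  f <- tiny_field(seed = 12, slope = c(0.004, 0.002))
  s <- sample_terrain_points(f$truth$mask, f$dsm, offset_px = 25,
                             veg_mask = f$truth$mask > 0)
  g <- f$dsm$gsd_cm / 100
  true_z <- f$truth$closure(s$x * g, s$y * g)
  expect_true(all(abs(s$elev_m - true_z) < 1e-6))
})

test_that("the Delaunay DTM reproduces affine terrain exactly", {
  set.seed(3)
  x <- stats::runif(40, 0, 99); y <- stats::runif(40, 0, 79)
  z <- 1 + 0.01 * x + 0.02 * y
  s <- tibble::tibble(x = x, y = y, elev_m = z)
  dtm <- build_dtm(s, c(80, 100))
  # interior of the hull: linear interpolation reproduces the plane
  hull <- grDevices::chull(x, y)
  inside <- rasterize_polygon(cbind(x, y)[hull, ], c(80, 100))
  xs <- rep(0:99, each = 80); ys <- rep(0:79, times = 100)
  plane <- matrix(1 + 0.01 * xs + 0.02 * ys, 80, 100)
  expect_lt(max(abs(dtm$values[inside] - plane[inside])), 1e-6)
})

test_that("constant samples give a constant DTM", {
  s <- tibble::tibble(x = c(2, 30, 15), y = c(2, 4, 25), elev_m = 7)
  dtm <- build_dtm(s, c(30, 40))
  expect_equal(dtm$values, matrix(7, 30, 40))
})

test_that("pixels outside the hull take the nearest sample's elevation", {
  s <- tibble::tibble(x = c(10, 30, 20), y = c(10, 10, 30),
                      elev_m = c(1, 2, 3))
  dtm <- build_dtm(s, c(40, 40))
  # brute-force nearest-neighbour oracle at a few outside pixels
  for (p in list(c(0, 0), c(39, 0), c(0, 39), c(39, 39), c(20, 0))) {
    d2 <- (s$x - p[1])^2 + (s$y - p[2])^2
    expect_equal(dtm$values[p[2] + 1, p[1] + 1], s$elev_m[which.min(d2)])
  }
})

test_that("degenerate sample sets are rejected", {
  expect_error(build_dtm(tibble::tibble(x = 1:2, y = 1:2, elev_m = 1),
                         c(10, 10)), "3")
  expect_error(build_dtm(tibble::tibble(x = 1:5, y = 2 * (1:5), elev_m = 1),
                         c(20, 20)), "collinear")
})

test_that("nDSM subtracts the DTM and propagates nodata", {
  dsm <- raster_grid(matrix(50, 10, 10), gsd_cm = 1)
  dtm <- raster_grid(matrix(50, 10, 10), gsd_cm = 1)
  expect_equal(compute_ndsm(dsm, dtm)$values, matrix(0, 10, 10))
  dsm2 <- raster_grid(matrix(50.25, 10, 10), gsd_cm = 1)
  expect_equal(compute_ndsm(dsm2, dtm)$values, matrix(0.25, 10, 10))
  dsm3 <- dsm
  dsm3$values[3, 3] <- dsm3$nodata
  nd <- compute_ndsm(dsm3, dtm)
  expect_equal(nd$values[3, 3], nd$nodata)
  expect_error(compute_ndsm(dsm, raster_grid(matrix(0, 5, 5), 1)), "differ")
})

test_that("the nDSM vanishes at the terrain samples (interpolation
           passes through its data points)", {
  f <- tiny_field(seed = 13, slope = c(0.006, -0.004))
  veg <- f$truth$mask > 0
  s <- sample_terrain_points(f$truth$mask, f$dsm, offset_px = 40,
                             veg_mask = veg)
  dtm <- build_dtm(s, dim(f$dsm$values), gsd_cm = f$dsm$gsd_cm)
  ndsm <- compute_ndsm(f$dsm, dtm)
  at_samples <- ndsm$values[cbind(s$y + 1, s$x + 1)]
  expect_lt(max(abs(at_samples)), 1e-6)
})

test_that("terrain tilt contributes less than 0.5 cm to plot canopy height", {
  # +/- 10 cm of affine tilt across the field, zero DSM noise: the height
  # statistic sits at the canopy peak on the sampled row line, so the
  # local DTM bounds the terrain contribution to CH error
  # 10 cm drop across the 9.5 m field raster
  f <- generate_field(field_config(n_ranges = 3, n_beds = 4, gsd_cm = 1,
                                   seed = 14, slope = c(0.10 / 9.5, 0),
                                   missing_plot_rate = 0,
                                   single_row_rate = 0))
  res <- suppressWarnings(run_pipeline(f$ortho, f$dsm))
  m <- match_truth(res, f$truth)
  expect_equal(nrow(m), nrow(f$truth$plots))
  expect_lt(max(abs(m$ch_cm_est - m$ch_cm_true)), 0.5)
})
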