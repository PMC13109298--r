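test_that("ExG-ExR follows the chromatic-coordinate formula", {
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- c(0, 255, 0)      # pure green
  img[1, 2, ] <- c(128, 128, 128)  # gray
  img[1, 3, ] <- c(0, 0, 0)        # black
  v <- vegetation_index(img)
  expect_equal(v$score[1, 1], 3)            # ExG = 2, ExR = -1
  expect_equal(v$score[1, 2], -0.4 / 3, tolerance = 1e-12)  # = -0.1333
  expect_equal(v$score[1, 3], 0)
  expect_identical(unname(v$mask[1, ]), c(TRUE, FALSE, FALSE))
})

test_that("range boundaries fall at valley midpoints", {
  img <- soil_image(60, 500)
  img <- add_green_blob(img, 100, 10, 100, 40)  # columns [100, 200)
  img <- add_green_blob(img, 300, 10, 100, 40)  # columns [300, 400)
  iv <- detect_ranges(vegetation_index(img))
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$x_end[1], 250, tolerance = 1)
  expect_equal(iv$x_start[2], iv$x_end[1])

  # full-width vegetation: a single interval spanning the image
  full <- add_green_blob(soil_image(30, 200), 0, 5, 200, 20)
  iv2 <- detect_ranges(vegetation_index(full))
  expect_equal(nrow(iv2), 1L)
  expect_equal(c(iv2$x_start, iv2$x_end), c(0, 200))

  # empty mask: no ranges
  expect_equal(nrow(detect_ranges(vegetation_index(soil_image(30, 200)))), 0L)
})

test_that("row peaks sit on the vegetation bands", {
  img <- soil_image(200, 120)
  img <- add_green_blob(img, 10, 40, 100, 21)   # band centered y = 50
  img <- add_green_blob(img, 10, 131, 100, 21)  # band centered y = 141
  veg <- vegetation_index(img)
  iv <- list(x_start = 0, x_end = 120)
  ys <- detect_rows(veg, iv, row_spacing_px = 91)
  expect_length(ys, 2L)
  expect_equal(ys[1], 50, tolerance = 2)
  expect_equal(ys[2], 141, tolerance = 2)

  single <- add_green_blob(soil_image(100, 50), 5, 40, 40, 15)
  expect_length(detect_rows(vegetation_index(single),
                            list(x_start = 0, x_end = 50), 91), 1L)
  expect_length(detect_rows(vegetation_index(soil_image(50, 50)),
                            list(x_start = 0, x_end = 50), 91), 0L)
})

test_that("prompts use the target as foreground and neighbors as background", {
  layout <- structure(list(
    ranges = tibble::tibble(x_start = 0, x_end = 100),
    centroids = tibble::tibble(x = c(50, 50, 50), y = c(30, 120, 210),
                               range_idx = 1L, row_idx = 1:3)),
    class = "row_layout")
  pr <- make_prompts(layout, 2)
  expect_equal(unname(pr$fg[1, ]), c(50, 120))
  expect_equal(sort(pr$bg[, 2]), c(30, 210))  # rows above and below

  solo <- structure(list(ranges = layout$ranges,
                         centroids = layout$centroids[1, ]),
                    class = "row_layout")
  expect_equal(nrow(make_prompts(solo, 1)$bg), 0L)

  # one prompt set per centroid
  sets <- lapply(seq_len(3), make_prompts, layout = layout)
  expect_length(sets, nrow(layout$centroids))
})

test_that("layout detection recovers the generator's range-row grid", {
  f <- tiny_field(n_ranges = 2, n_beds = 3, seed = 6)
  veg <- vegetation_index(f$ortho)
  row_px <- 0.91 * 100 / f$ortho$gsd_cm
  lay <- detect_layout(veg, row_px)
  expect_equal(nrow(lay$ranges), 2L)
  expect_equal(nrow(lay$centroids), 2L * 3L * 2L)  # ranges x beds x 2 rows
  # centroids coincide with the truth plot-row centers within 3 px
  g <- f$ortho$gsd_cm / 100
  geo <- f$truth$geometry
  cfg <- f$truth$config
  true_y <- sort(rep(geo$fy0 + (seq_len(3) - 0.5) * cfg$bed_width_m,
                     each = 2) +
                 c(-0.5, 0.5) * cfg$row_spacing_m) / g
  for (r in 1:2) {
    got <- sort(lay$centroids$y[lay$centroids$range_idx == r])
    expect_equal(got, true_y, tolerance = 3)
  }
})

test_that("segment_rows labels match truth components and stay in the field", {
  f <- tiny_field(n_ranges = 2, n_beds = 2, seed = 9)
  veg <- vegetation_index(f$ortho)
  row_px <- 0.91 * 100 / f$ortho$gsd_cm
  lay <- detect_layout(veg, row_px)
  seg <- segment_rows(f$ortho, lay)
  expect_equal(max(seg$labels), 8L)  # 2 ranges x 2 beds x 2 rows
  expect_false(any(seg$centroids$missing))
  # labels never extend beyond the vegetation mask
  expect_true(all(veg$mask[seg$labels > 0L]))
  # two plots sharing no pixels get disjoint labels: each label is one
  # truth component
  for (l in seq_len(max(seg$labels))) {
    ids <- unique(f$truth$mask[seg$labels == l])
    expect_length(ids, 1L)
  }
  expect_error(segment_rows(f$ortho, structure(
    list(ranges = lay$ranges, centroids = lay$centroids[0, ]),
    class = "row_layout")), "empty")
})
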