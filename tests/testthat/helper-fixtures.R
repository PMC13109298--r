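# shared fixtures and independent oracles

tiny_field <- function(n_ranges = 3, n_beds = 4, gsd_cm = 2, seed = 1, ...) {
  generate_field(field_config(n_ranges = n_ranges, n_beds = n_beds,
                              gsd_cm = gsd_cm, seed = seed,
                              missing_plot_rate = 0, single_row_rate = 0,
                              ...))
}

# independent connected-components oracle: BFS flood fill, 4-connectivity
bfs_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      r <- (i - 1L) %% h + 1L; c <- (i - 1L) %/% h + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] < 1L || d[1] > h || d[2] < 1L || d[2] > w) next
        j <- (d[2] - 1L) * h + d[1]
        if (mask[j] && lab[j] == 0L) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# soil/vegetation test image builders (values chosen so ExG-ExR is
# negative on soil and positive on the green blobs)
soil_image <- function(h, w) {
  array(rep(c(120, 100, 80), each = h * w), c(h, w, 3))
}

add_green_blob <- function(img, x0, y0, w, h) {
  img[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), 1] <- 60
  img[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), 2] <- 140
  img[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), 3] <- 70
  img
}

# plot_patch builder for trait tests
make_test_patch <- function(plot_id, ndsm, rgb = NULL, center_y = NULL,
                            single_row = FALSE) {
  d <- dim(ndsm)
  if (is.null(rgb)) rgb <- array(100, c(d, 3))
  if (is.null(center_y)) center_y <- d[1] %/% 2L
  structure(list(rgb = rgb, ndsm = ndsm, mask = ndsm > 0,
                 center_y = center_y, plot_id = plot_id,
                 single_row = single_row), class = "plot_patch")
}

# height-separable patch pair generator: identical RGB texture statistics,
# class difference only in the nDSM dome height
separable_patches <- function(n_per_class, h1 = 35, h2 = 18, sd = 2,
                              side = 112L, seed = 1) {
  make_one <- function(id, h_cm, s) {
    set.seed(s)
    rgb <- array(stats::runif(side * side * 3, 90, 130), c(side, side, 3))
    xs <- seq(-1, 1, length.out = side)
    dome <- pmax(0, 1 - outer(xs^2, xs^2, `+`))
    nd <- h_cm / 100 * dome + matrix(stats::rnorm(side^2, 0, 0.003), side)
    make_test_patch(id, nd, rgb = rgb)
  }
  set.seed(seed)
  hs <- c(stats::rnorm(n_per_class, h1, sd), stats::rnorm(n_per_class, h2, sd))
  patches <- lapply(seq_len(2 * n_per_class), function(i)
    make_one(i, hs[i], seed * 10000 + i))
  labels <- tibble::tibble(
    plot_id = seq_len(2 * n_per_class),
    gh = rep(c("bunch", "spreading"), each = n_per_class))
  list(patches = patches, labels = labels)
}

# truth-vs-detected plot matching by (range, bed)
match_truth <- function(res, truth) {
  est <- dplyr::inner_join(res$traits,
                           res$plots[, c("plot_id", "range_idx", "bed_idx",
                                         "single_row")],
                           by = "plot_id")
  dplyr::inner_join(est,
                    truth$plots[, c("range_idx", "bed_idx", "ch_cm",
                                    "single_row")],
                    by = c("range_idx", "bed_idx"),
                    suffix = c("_est", "_true"))
}
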