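#' Synthetic raised-bed trial configuration
#'
#' Describes the layout and trait distributions of a synthetic two-row
#' raised-bed breeding trial: beds 1.82 m wide carrying two crop rows
#' spaced 0.91 m apart, planted plot segments about 0.5 m long separated by
#' 2 m bare-soil alleys, imaged at about 1 cm/px. Canopy heights follow a
#' normal distribution (mean 24.8 cm, SD 6.37 cm) rejection-sampled into
#' the observed 16--40 cm range; growth habit (bunch vs spreading) and
#' mainstem prominence (apparent vs not apparent) are binary labels drawn
#' with the observed class frequencies.
#'
#' @param n_ranges,n_beds grid size: ranges along the beds, beds across.
#' @param bed_width_m,row_spacing_m,plot_len_m,alley_m layout lengths in
#'   meters.
#' @param gsd_cm ground sampling distance, cm/px.
#' @param ch_mean_cm,ch_sd_cm,ch_range_cm canopy-height law (clipped normal).
#' @param gh_spreading_prob,mp_apparent_prob class frequencies for growth
#'   habit and mainstem prominence.
#' @param base_elev_m,slope terrain: base elevation and affine slope
#'   `c(dz/dx, dz/dy)` in m per m.
#' @param furrow_depth_m,furrow_width_m depressed tractor-track strips
#'   between beds.
#' @param noise_sd_cm i.i.d. Gaussian noise added to the DSM, cm.
#' @param missing_plot_rate,single_row_rate independent per-plot
#'   probabilities of a fully missing plot and of a one-row plot.
#' @param margin_m bare-soil margin around the planted block.
#' @param pad_for_rotation if `TRUE`, the canvas is a square with side equal
#'   to the planted-block diagonal plus margins, so any rotation keeps the
#'   field fully in frame.
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return a `field_config` list.
#' @export
field_config <- function(n_ranges = 5, n_beds = 8,
                         bed_width_m = 1.82, row_spacing_m = 0.91,
                         plot_len_m = 0.5, alley_m = 2.0,
                         gsd_cm = 1.0,
                         ch_mean_cm = 24.8, ch_sd_cm = 6.37,
                         ch_range_cm = c(16, 40),
                         gh_spreading_prob = 0.508,
                         mp_apparent_prob = 0.657,
                         base_elev_m = 50, slope = c(0, 0),
                         furrow_depth_m = 0.05, furrow_width_m = 0.30,
                         noise_sd_cm = 0,
                         missing_plot_rate = 0.02, single_row_rate = 0.03,
                         margin_m = 2, pad_for_rotation = FALSE,
                         seed = 1) {
  cfg <- as.list(environment())
  stopifnot(n_ranges >= 1, n_beds >= 1, bed_width_m > 0, row_spacing_m > 0,
            plot_len_m > 0, alley_m > 0, gsd_cm > 0,
            ch_range_cm[1] < ch_range_cm[2],
            missing_plot_rate >= 0, missing_plot_rate <= 1,
            single_row_rate >= 0, single_row_rate <= 1)
  class(cfg) <- "field_config"
  cfg
}

# evaluate code with a local, restored RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Clipped-normal canopy heights by rejection sampling (keeps the range
# exact). Truncating shifts the moments, so the pre-truncation parameters
# are calibrated (closed-form truncated-normal moments + Nelder-Mead) so
# that the *generated* heights have the requested mean and SD.
truncnorm_moments <- function(mu, sigma, l, u) {
  a <- (l - mu) / sigma; b <- (u - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

calibrate_truncnorm <- function(mean, sd, range) {
  obj <- function(p) {
    if (p[2] <= 0) return(1e6)
    mo <- truncnorm_moments(p[1], p[2], range[1], range[2])
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, sd), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  fit$par
}

sample_canopy_heights <- function(n, mean, sd, range) {
  p <- calibrate_truncnorm(mean, sd, range)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(2 * (n - length(out)) + 8, p[1], p[2])
    out <- c(out, draw[draw >= range[1] & draw <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic raised-bed field
#'
#' Renders an RGB orthomosaic and a co-registered DSM of a raised-bed trial
#' together with complete ground truth. Beds are elevated strips separated
#' by depressed furrow tracks; each surviving plot carries two (or one, for
#' single-row plots) green canopy blobs. Bunch plots are rendered as
#' compact domed canopies, spreading plots as wider flat-topped ones;
#' mainstem-prominent plots carry a narrow central height spike reaching
#' the canopy top. The DSM is the terrain closure plus the canopy height
#' field plus optional Gaussian noise.
#'
#' Guarantees used by the test-suite: canopy pixels (and only canopy
#' pixels) have positive ExG-ExR under the rendered colors, and with zero
#' noise `dsm - closure(x, y)` equals the rendered canopy height field.
#'
#' @param config a [field_config()].
#' @return a list with elements `ortho` and `dsm` ([raster_grid()]s) and
#'   `truth`: plot-level tibble (`plots`), label mask matrix (`mask`),
#'   field rectangle corners (`field_rect`, world coords), expected
#'   orientation (`orientation_deg`), applied rotation (`angle_deg`), the
#'   terrain closure function (`closure`) and the geometry of the layout.
#' @export
generate_field <- function(config = field_config()) {
  stopifnot(inherits(config, "field_config"))
  g <- config$gsd_cm / 100  # m per px
  w_f <- config$n_ranges * config$plot_len_m +
    (config$n_ranges - 1) * config$alley_m
  h_f <- config$n_beds * config$bed_width_m
  if (w_f <= 0 || h_f <= 0) stop("field too small for one plot", call. = FALSE)
  if (config$pad_for_rotation) {
    side <- sqrt(w_f^2 + h_f^2) + 2 * config$margin_m
    w_c <- h_c <- side
  } else {
    w_c <- w_f + 2 * config$margin_m
    h_c <- h_f + 2 * config$margin_m
  }
  W <- as.integer(round(w_c / g)); H <- as.integer(round(h_c / g))
  fx0 <- (w_c - w_f) / 2; fy0 <- (h_c - h_f) / 2

  # world coordinates of pixel centers
  wx <- (0:(W - 1)) * g
  wy <- (0:(H - 1)) * g

  furrow_ys <- fy0 + (0:config$n_beds) * config$bed_width_m
  closure <- local({
    base <- config$base_elev_m; sl <- config$slope
    fd <- config$furrow_depth_m; fw <- config$furrow_width_m
    fys <- furrow_ys
    function(wx, wy) {
      z <- base + sl[1] * wx + sl[2] * wy
      in_furrow <- rep(FALSE, length(wy))
      for (fy in fys) in_furrow <- in_furrow | abs(wy - fy) <= fw / 2
      z - fd * in_furrow
    }
  })

  with_local_seed(config$seed, {
    # terrain + furrows (separable in x and y here: slope is affine, furrows
    # depend on y only)
    zx <- config$base_elev_m + config$slope[1] * wx
    zy <- config$slope[2] * wy
    in_furrow <- rep(FALSE, H)
    for (fy in furrow_ys) in_furrow <- in_furrow | abs(wy - fy) <= config$furrow_width_m / 2
    zy <- zy - config$furrow_depth_m * in_furrow
    terrain <- outer(zy, zx, `+`)  # H x W

    # plot truth table, bed-major then range order
    grid <- expand.grid(range_idx = seq_len(config$n_ranges),
                        bed_idx = seq_len(config$n_beds))
    grid <- grid[order(grid$bed_idx, grid$range_idx), ]
    n <- nrow(grid)
    keep <- stats::runif(n) >= config$missing_plot_rate
    single <- stats::runif(n) < config$single_row_rate
    which_row <- sample(1:2, n, replace = TRUE)
    ch <- sample_canopy_heights(n, config$ch_mean_cm, config$ch_sd_cm,
                                config$ch_range_cm)
    gh <- ifelse(stats::runif(n) < config$gh_spreading_prob,
                 "spreading", "bunch")
    mp <- ifelse(stats::runif(n) < config$mp_apparent_prob,
                 "apparent", "not_apparent")

    canopy <- matrix(0, H, W)
    labels <- matrix(0L, H, W)
    plots <- vector("list", n)
    pid <- 0L
    for (k in seq_len(n)) {
      if (!keep[k]) next
      pid <- pid + 1L
      ri <- grid$range_idx[k]; bi <- grid$bed_idx[k]
      px0 <- fx0 + (ri - 1) * (config$plot_len_m + config$alley_m)
      px1 <- px0 + config$plot_len_m
      py0 <- fy0 + (bi - 1) * config$bed_width_m
      py1 <- py0 + config$bed_width_m
      cx <- (px0 + px1) / 2
      row_ys <- (py0 + py1) / 2 + c(-0.5, 0.5) * config$row_spacing_m
      rows_here <- if (single[k]) which_row[k] else 1:2
      for (rr in rows_here) {
        blob <- render_canopy_blob(cx, row_ys[rr], ch[k] / 100, gh[k], mp[k],
                                   config$plot_len_m / 2, g, W, H)
        if (is.null(blob)) next
        sub <- canopy[blob$rows, blob$cols]
        upd <- blob$height > sub
        sub[upd] <- blob$height[upd]
        canopy[blob$rows, blob$cols] <- sub
        lab <- labels[blob$rows, blob$cols]
        lab[blob$height > 0 & lab == 0L] <- pid
        labels[blob$rows, blob$cols] <- lab
      }
      plots[[pid]] <- tibble::tibble(
        plot_id = pid, range_idx = ri, bed_idx = bi,
        ch_cm = ch[k], gh = gh[k], mp = mp[k],
        single_row = single[k],
        center_wx = cx, center_wy = (py0 + py1) / 2,
        poly = list(cbind(wx = c(px0, px1, px1, px0),
                          wy = c(py0, py0, py1, py1)))
      )
    }
    plots <- dplyr::bind_rows(plots[seq_len(pid)])

    dsm_vals <- terrain + canopy
    if (config$noise_sd_cm > 0)
      dsm_vals <- dsm_vals + matrix(stats::rnorm(H * W, 0, config$noise_sd_cm / 100), H, W)

    ortho_vals <- render_colors(labels > 0L, in_furrow, H, W)

    truth <- list(
      plots = plots, mask = labels,
      field_rect = cbind(wx = c(fx0, fx0 + w_f, fx0 + w_f, fx0),
                         wy = c(fy0, fy0, fy0 + h_f, fy0 + h_f)),
      orientation_deg = if (h_f >= w_f) 90 else 0,
      angle_deg = 0,
      closure = closure,
      geometry = list(w_c = w_c, h_c = h_c, w_f = w_f, h_f = h_f,
                      fx0 = fx0, fy0 = fy0, furrow_ys = furrow_ys),
      config = config
    )
    list(
      ortho = raster_grid(ortho_vals, gsd_cm = config$gsd_cm),
      dsm = raster_grid(dsm_vals, gsd_cm = config$gsd_cm),
      truth = truth
    )
  })
}

# Render one canopy blob; returns NULL if fully outside the canvas.
# Bunch: compact dome; spreading: wider flat top; apparent mainstem: narrow
# central spike reaching the canopy top (the plant's tallest point).
render_canopy_blob <- function(cx, cy, h_m, gh, mp, ax, g, W, H) {
  ay <- if (gh == "bunch") 0.16 else 0.22
  rx <- ax + 0.02; ry <- ay + 0.02
  c0 <- max(0L, floor((cx - rx) / g)); c1 <- min(W - 1L, ceiling((cx + rx) / g))
  r0 <- max(0L, floor((cy - ry) / g)); r1 <- min(H - 1L, ceiling((cy + ry) / g))
  if (c1 < c0 || r1 < r0) return(NULL)
  xs <- (c0:c1) * g - cx
  ys <- (r0:r1) * g - cy
  r2 <- outer((ys / ay)^2, (xs / ax)^2, `+`)
  prof <- if (gh == "bunch") {
    h_m * pmax(0, 1 - r2)^0.9
  } else {
    h_m * pmax(0, 1 - r2^2)^0.35
  }
  if (mp == "apparent") {
    d2 <- outer(ys^2, xs^2, `+`)
    spike <- h_m * exp(-d2 / (2 * 0.05^2))
    spike[r2 >= 1] <- 0
    prof <- pmax(0.85 * prof, spike)
  }
  prof[prof < 1e-4] <- 0
  list(rows = (r0:r1) + 1L, cols = (c0:c1) + 1L, height = prof)
}

# Soil / furrow / canopy coloring with per-pixel jitter. Colors are chosen
# so that ExG-ExR is strictly positive on canopy and strictly negative on
# soil and furrow pixels under the full jitter range.
render_colors <- function(canopy_mask, furrow_rows, H, W,
                          soil = c(120, 100, 80), green = c(60, 140, 70),
                          jitter = 8) {
  vals <- array(0, c(H, W, 3))
  furrow <- matrix(furrow_rows, H, W)
  for (b in 1:3) {
    base <- matrix(soil[b], H, W)
    base[furrow] <- soil[b] * 0.85
    base[canopy_mask] <- green[b]
    vals[, , b] <- pmin(255, pmax(0, round(
      base + matrix(stats::runif(H * W, -jitter, jitter), H, W))))
  }
  vals
}

#' Rotate a synthetic field and its ground truth
#'
#' Rotates the orthomosaic (soil-colored fill), the DSM (nodata fill) and
#' every truth polygon/mask by the same transform about the image center,
#' and updates the expected field orientation.
#'
#' @param field a list as returned by [generate_field()].
#' @param angle_deg rotation in degrees, in `[0, 180)`.
#' @return a list with the same structure as [generate_field()]'s.
#' @export
rotate_field <- function(field, angle_deg) {
  stopifnot(angle_deg >= 0, angle_deg < 180)
  if (angle_deg == 0) return(field)
  soil_fill <- c(120, 100, 80)
  ortho <- rotate_raster(field$ortho, angle_deg, fill = soil_fill)
  dsm <- rotate_raster(field$dsm, angle_deg)
  truth <- field$truth
  d <- dim(field$dsm$values)
  g <- field$dsm$gsd_cm / 100
  cx <- (d[2] - 1) / 2 * g; cy <- (d[1] - 1) / 2 * g
  th <- angle_deg * pi / 180
  rot <- function(p) {
    dx <- p[, 1] - cx; dy <- p[, 2] - cy
    cbind(wx = cos(th) * dx - sin(th) * dy + cx,
          wy = sin(th) * dx + cos(th) * dy + cy)
  }
  truth$plots$poly <- lapply(truth$plots$poly, rot)
  ctr <- rot(cbind(truth$plots$center_wx, truth$plots$center_wy))
  truth$plots$center_wx <- ctr[, 1]; truth$plots$center_wy <- ctr[, 2]
  truth$field_rect <- rot(truth$field_rect)
  truth$mask <- rotate_labels(truth$mask, angle_deg)
  truth$orientation_deg <- (truth$orientation_deg + angle_deg) %% 180
  truth$angle_deg <- (truth$angle_deg + angle_deg) %% 180
  list(ortho = ortho, dsm = dsm, truth = truth)
}

# nearest-neighbour rotation for integer label rasters
rotate_labels <- function(m, angle_deg) {
  h <- nrow(m); w <- ncol(m)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  xd <- rep(0:(w - 1), each = h) - cx
  yd <- rep(0:(h - 1), times = w) - cy
  xs <- round(cos(th) * xd + sin(th) * yd + cx)
  ys <- round(-sin(th) * xd + cos(th) * yd + cy)
  ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  out <- integer(h * w)
  out[ok] <- m[cbind(ys[ok] + 1, xs[ok] + 1)]
  matrix(out, h, w)
}
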