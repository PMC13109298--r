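#' Resize an orthomosaic for automatic mask generation
#'
#' The longest image dimension is resized to `max_long_side` pixels (aspect
#' preserved, other side rounded to the nearest integer); images already
#' within the limit are returned unchanged.
#'
#' @param ortho an RGB [raster_grid()].
#' @param max_long_side working resolution (px).
#' @return list with `image` (resized [raster_grid()]) and `scale`
#'   (factor mapping resized pixel coordinates back to full resolution).
#' @export
prepare_image <- function(ortho, max_long_side = 1024L) {
  d <- dim(ortho$values)
  long <- max(d[1:2])
  if (long <= max_long_side) return(list(image = ortho, scale = 1))
  scale <- long / max_long_side
  nh <- if (d[1] >= d[2]) max_long_side else as.integer(round(d[1] / scale))
  nw <- if (d[2] >= d[1]) max_long_side else as.integer(round(d[2] / scale))
  list(image = resize_raster(ortho, nh, nw), scale = scale)
}

# minimum-area enclosing rectangle of a point set by rotating calipers
# over the convex hull; returns corners, extents and the long-side angle
min_area_rect <- function(xy) {
  xy <- unique(xy)
  if (nrow(xy) < 3L) stop("mask with fewer than 3 pixels", call. = FALSE)
  hull <- grDevices::chull(xy[, 1], xy[, 2])
  hp <- xy[hull, , drop = FALSE]
  nh <- nrow(hp)
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hp[, 1] * u[1] + hp[, 2] * u[2]
    pv <- hp[, 1] * v[1] + hp[, 2] * v[2]
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area) {
      corners <- rbind(
        min(pu) * u + min(pv) * v, max(pu) * u + min(pv) * v,
        max(pu) * u + max(pv) * v, min(pu) * u + max(pv) * v)
      best <- list(area = area, u = u, v = v, du = du, dv = dv,
                   corners = corners)
    }
  }
  ang_u <- (atan2(best$u[2], best$u[1]) * 180 / pi) %% 180
  ang_v <- (atan2(best$v[2], best$v[1]) * 180 / pi) %% 180
  rel_tie <- abs(best$du - best$dv) <= 1e-9 * max(best$du, best$dv)
  angle <- if (rel_tie) min(ang_u, ang_v)
           else if (best$du >= best$dv) ang_u else ang_v
  best$angle <- unname(angle %% 180)
  best
}

#' Estimate the orientation of a field mask
#'
#' Angle of the long side of the minimum-area enclosing rectangle of the
#' mask pixels (equivalently, the first principal axis for a near
#' rectangular mask), reported modulo 180 degrees in image coordinates
#' (x right, y down). Both the rectangle angle and the principal-component
#' angle are computed; a warning is emitted when they disagree by more
#' than 2 degrees. A square mask resolves the tie to the smaller of the
#' two rectangle angles.
#'
#' @param mask logical or 0/1 matrix.
#' @return orientation in `[0, 180)` degrees.
#' @export
estimate_orientation <- function(mask) {
  px <- which(mask > 0, arr.ind = TRUE)
  if (nrow(px) < 3L) stop("mask with fewer than 3 pixels", call. = FALSE)
  xy <- cbind(x = px[, 2] - 1, y = px[, 1] - 1)
  rect <- min_area_rect(xy)
  pca_ang <- pca_orientation(xy)
  if (angle_diff_180(rect$angle, pca_ang) > 2)
    warning(sprintf(
      "min-rect (%.2f deg) and principal-axis (%.2f deg) orientations disagree",
      rect$angle, pca_ang))
  rect$angle
}

pca_orientation <- function(xy) {
  cc <- sweep(xy, 2, colMeans(xy))
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180
}

# circular distance between two angles modulo 180 degrees
angle_diff_180 <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}

#' Locate the experimental field in an orthomosaic
#'
#' Generates candidate masks with [auto_masks()] on the resized image,
#' keeps candidates whose bounding-box center lies within
#' `center_radius_px` (resized coordinates) of the image center — the
#' field is assumed roughly centered in frame, as standard flight plans
#' produce — and selects the survivor with the highest mean of predicted
#' IoU and stability score. The selected mask is upscaled to full
#' resolution and its minimum oriented bounding rectangle and orientation
#' are computed.
#'
#' @param ortho an RGB [raster_grid()].
#' @param backend a [seg_backend()].
#' @param center_radius_px center-filter radius in resized pixels.
#' @return a `field_region`: list with `mask` (full-resolution logical
#'   matrix), `min_rect` (4 x 2 corner matrix, full-resolution pixel
#'   coords), `orientation_deg`, `score`, `n_candidates`,
#'   `n_centered`.
#' @export
locate_field <- function(ortho, backend = seg_backend(),
                         center_radius_px = 5) {
  prep <- prepare_image(ortho, backend$max_long_side)
  cands <- auto_masks(prep$image, backend)
  d <- dim(prep$image$values)
  ctr <- c((d[2] - 1) / 2, (d[1] - 1) / 2)
  dist <- vapply(cands, function(cc)
    sqrt(sum((cc$centroid - ctr)^2)), 0)
  keep <- which(dist <= center_radius_px)
  if (!length(keep))
    stop("no candidate mask near the image center; ",
         "consider a larger `center_radius_px` (currently ",
         center_radius_px, ")", call. = FALSE)
  scores <- vapply(cands[keep], function(cc)
    (cc$predicted_iou + cc$stability) / 2, 0)
  sel <- cands[[keep[which.max(scores)]]]
  mask <- upscale_mask(sel$mask, dim(ortho$values)[1:2], prep$scale)
  px <- which(mask, arr.ind = TRUE)
  rect <- min_area_rect(cbind(x = px[, 2] - 1, y = px[, 1] - 1))
  pca_ang <- pca_orientation(cbind(px[, 2] - 1, px[, 1] - 1))
  if (angle_diff_180(rect$angle, pca_ang) > 2)
    warning("min-rect and principal-axis orientations disagree by > 2 deg")
  structure(list(mask = mask, min_rect = rect$corners,
                 orientation_deg = rect$angle,
                 score = max(scores),
                 n_candidates = length(cands), n_centered = length(keep)),
            class = "field_region")
}

upscale_mask <- function(mask, full_dim, scale) {
  if (scale == 1 && all(dim(mask) == full_dim)) return(mask)
  h <- full_dim[1]; w <- full_dim[2]
  # map full-res pixel centers into resized coordinates
  xs <- pmin(dim(mask)[2] - 1, pmax(0, round(((0:(w - 1)) + 0.5) / (w / dim(mask)[2]) - 0.5)))
  ys <- pmin(dim(mask)[1] - 1, pmax(0, round(((0:(h - 1)) + 0.5) / (h / dim(mask)[1]) - 0.5)))
  mask[ys + 1, , drop = FALSE][, xs + 1, drop = FALSE]
}

#' Rotate orthomosaic and DSM to axis alignment
#'
#' Rotates both rasters by the negative of the estimated field orientation
#' about the image center so the field's axes become image-parallel. The
#' long-axis orientation leaves a 90-degree ambiguity (it does not say
#' which axis carries the beds); when `row_spacing_px` is supplied, the
#' ambiguity is resolved by checking along which image axis the vegetation
#' profile repeats at the expected crop-row spacing, and adding 90 degrees
#' when the rows come out vertical.
#'
#' @param ortho,dsm co-registered [raster_grid()]s.
#' @param region a `field_region` from [locate_field()].
#' @param row_spacing_px expected row spacing (px) for the mod-90
#'   disambiguation; `NULL` skips it.
#' @return list with rotated `ortho`, `dsm`, the applied `angle_deg`, and
#'   `transform(points)` mapping original pixel coordinates into the
#'   rotated frame.
#' @export
rotate_to_axis <- function(ortho, dsm, region, row_spacing_px = NULL) {
  angle <- -region$orientation_deg
  if (!is.null(row_spacing_px)) {
    veg <- vegetation_index(ortho)$mask
    test <- rotate_labels(veg + 0L, angle %% 360)
    if (rows_look_vertical(test, row_spacing_px)) angle <- angle + 90
  }
  angle <- angle %% 360
  d <- dim(ortho$values)
  cx <- (d[2] - 1) / 2; cy <- (d[1] - 1) / 2
  th <- angle * pi / 180
  transform <- function(p) {
    dx <- p[, 1] - cx; dy <- p[, 2] - cy
    cbind(x = cos(th) * dx - sin(th) * dy + cx,
          y = sin(th) * dx + cos(th) * dy + cy)
  }
  list(ortho = rotate_raster(ortho, angle, fill = c(120, 100, 80)),
       dsm = rotate_raster(dsm, angle),
       angle_deg = angle, transform = transform)
}

# After rotation, do vegetation rows repeat at `row_spacing_px` along the
# *column* profile (i.e. rows are vertical)? Compares the median peak
# spacing of the two axis profiles against the expected row spacing.
rows_look_vertical <- function(mask, row_spacing_px) {
  spacing <- function(prof) {
    if (max(prof) == 0) return(Inf)
    sm <- moving_average(prof, 0.25 * row_spacing_px)
    pk <- find_peaks(sm, 0.3, 0.5 * row_spacing_px)
    if (length(pk) < 2) return(Inf)
    stats::median(diff(pk))
  }
  sp_y <- spacing(rowSums(mask))  # rows horizontal -> y profile repeats
  sp_x <- spacing(colSums(mask))
  abs(sp_x - row_spacing_px) < abs(sp_y - row_spacing_px)
}
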