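#' Raster grid objects
#'
#' A `raster_grid` is the package's in-memory raster: a numeric matrix
#' (single-band elevation, meters) or an H x W x 3 array (RGB orthomosaic,
#' values 0--255), together with the pixel size in cm/px, the world
#' coordinate of pixel (0, 0) and a nodata sentinel.
#'
#' Pixel convention: 0-based, `(x = column, y = row)`, pixel centers at
#' integer coordinates. Boxes are half-open. Rasters without georeferencing
#' are accepted; the default origin is `(0, 0)` in a local coordinate system
#' with a user-supplied ground sampling distance, matching orthomosaics
#' produced without surveyed ground control.
#'
#' @param values numeric matrix (H x W) or array (H x W x 3).
#' @param gsd_cm pixel size in cm/px (> 0).
#' @param origin numeric length-2, world coordinate (meters) of pixel (0, 0).
#' @param nodata sentinel value marking missing elevation cells.
#' @return a `raster_grid` object.
#' @export
raster_grid <- function(values, gsd_cm, origin = c(0, 0), nodata = -9999) {
  stopifnot(is.numeric(values), length(dim(values)) %in% c(2L, 3L))
  if (length(dim(values)) == 3L && dim(values)[3] != 3L)
    stop("RGB rasters must have exactly 3 bands", call. = FALSE)
  if (!is.numeric(gsd_cm) || length(gsd_cm) != 1L || gsd_cm <= 0)
    stop("gsd_cm must be a single positive number", call. = FALSE)
  if (any(dim(values)[1:2] < 1L)) stop("raster must have H, W >= 1", call. = FALSE)
  structure(
    list(values = values, gsd_cm = as.numeric(gsd_cm),
         origin = as.numeric(origin), nodata = as.numeric(nodata)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  kind <- if (length(d) == 3L) "RGB" else "single-band"
  cat(sprintf("<raster_grid %s %d x %d, gsd %.3g cm/px, origin (%.3g, %.3g)>\n",
              kind, d[1], d[2], x$gsd_cm, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

is_rgb <- function(r) length(dim(r$values)) == 3L

#' Convert pixel coordinates to world coordinates
#'
#' One conversion pair is used everywhere in the package, so converting a
#' pixel to world coordinates and back is the identity.
#'
#' @param r a `raster_grid` (or any list with `gsd_cm` and `origin`).
#' @param x,y pixel coordinates (0-based, x = column, y = row).
#' @return `pixel_to_world()`: a two-column matrix of world coordinates in
#'   meters; `world_to_pixel()`: a two-column matrix of pixel coordinates.
#' @export
pixel_to_world <- function(r, x, y) {
  g <- r$gsd_cm / 100
  cbind(wx = r$origin[1] + x * g, wy = r$origin[2] + y * g)
}

#' @rdname pixel_to_world
#' @param wx,wy world coordinates in meters.
#' @export
world_to_pixel <- function(r, wx, wy) {
  g <- r$gsd_cm / 100
  cbind(x = (wx - r$origin[1]) / g, y = (wy - r$origin[2]) / g)
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Read a raster from disk
#'
#' Reads a single-band float raster (DSM/DTM/nDSM, meters) or a 3-band byte
#' orthomosaic from a TIFF file. Georeferencing metadata (gsd, origin,
#' nodata, and the linear offset/scale used to store floating-point
#' elevations) travels in a JSON sidecar written by [write_raster()]; a bare
#' TIFF is accepted with `gsd_cm` supplied by the caller and origin (0, 0).
#'
#' @param path path to a `.tif` file.
#' @param gsd_cm fallback pixel size when no sidecar is present.
#' @return a [raster_grid()].
#' @export
read_raster <- function(path, gsd_cm = 1) {
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  img <- tryCatch(tiff::readTIFF(path),
                  error = function(e) stop("unreadable TIFF: ", path, call. = FALSE))
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  gsd <- if (!is.null(meta$gsd_cm)) meta$gsd_cm else gsd_cm
  origin <- if (!is.null(meta$origin)) meta$origin else c(0, 0)
  nodata <- if (!is.null(meta$nodata)) meta$nodata else -9999
  nd <- length(dim(img))
  if (nd == 3L) {
    if (dim(img)[3] != 3L)
      stop("band count not in {1, 3}: ", dim(img)[3], call. = FALSE)
    vals <- round(img * 255)
  } else if (nd == 2L || is.null(dim(img))) {
    vals <- if (is.null(dim(img))) matrix(img, 1) else img
    if (!is.null(meta$scale)) {
      nd_mask <- vals >= 0.999999  # reserved nodata code
      vals <- vals * meta$scale + meta$offset
      vals[nd_mask] <- nodata
    }
  } else stop("band count not in {1, 3}", call. = FALSE)
  raster_grid(vals, gsd_cm = gsd, origin = origin, nodata = nodata)
}

#' Write a raster to disk
#'
#' RGB rasters are stored as 8-bit TIFF; single-band rasters as 32-bit float
#' TIFF with values mapped linearly into `[0, 0.9]` (nodata cells encode as
#' 1.0) and the offset/scale recorded in the JSON sidecar, so elevations in
#' meters round-trip to within float32 precision of the data range.
#'
#' @param r a [raster_grid()].
#' @param path output `.tif` path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "raster_grid"))
  meta <- list(gsd_cm = r$gsd_cm, origin = r$origin, nodata = r$nodata)
  if (is_rgb(r)) {
    v <- pmin(pmax(r$values, 0), 255) / 255
    ok <- tryCatch(tiff::writeTIFF(v, path, bits.per.sample = 8L),
                   error = function(e) stop("cannot write raster: ", path, call. = FALSE))
  } else {
    v <- r$values
    nd_mask <- !is.finite(v) | v == r$nodata
    fin <- v[!nd_mask]
    lo <- if (length(fin)) min(fin) else 0
    hi <- if (length(fin)) max(fin) else 1
    scale <- if (hi > lo) (hi - lo) / 0.9 else 1
    enc <- (v - lo) / scale
    enc[nd_mask] <- 1.0
    meta$offset <- lo
    meta$scale <- scale
    ok <- tryCatch(tiff::writeTIFF(enc, path, bits.per.sample = 32L),
                   error = function(e) stop("cannot write raster: ", path, call. = FALSE))
  }
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rotate a raster about its center
#'
#' Inverse-mapped rotation with bilinear resampling, keeping the output
#' canvas the same size as the input. The forward transform maps pixel `p`
#' to `R(angle) %*% (p - c) + c` where `c` is the image center and angles
#' are degrees, measured with the image convention (x right, y down).
#'
#' @param r a [raster_grid()].
#' @param angle_deg rotation angle in degrees.
#' @param fill fill value(s) for pixels sampled outside the source
#'   (length 3 for RGB); defaults to the nodata sentinel for single-band
#'   rasters and black for RGB.
#' @return a rotated [raster_grid()] with the same dimensions.
#' @export
rotate_raster <- function(r, angle_deg, fill = NULL) {
  stopifnot(inherits(r, "raster_grid"))
  if (angle_deg %% 360 == 0) return(r)
  d <- dim(r$values)
  h <- d[1]; w <- d[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  # inverse map: source = R(-angle) (dest - c) + c
  xd <- rep(0:(w - 1), each = h) - cx
  yd <- rep(0:(h - 1), times = w) - cy
  xs <- ct * xd + st * yd + cx
  ys <- -st * xd + ct * yd + cy
  if (is_rgb(r)) {
    if (is.null(fill)) fill <- c(0, 0, 0)
    out <- array(0, d)
    for (b in 1:3)
      out[, , b] <- matrix(bilinear_sample(r$values[, , b], xs, ys, fill[b]), h, w)
  } else {
    if (is.null(fill)) fill <- r$nodata
    v <- r$values
    v[v == r$nodata] <- NA_real_
    out <- matrix(bilinear_sample(v, xs, ys, NA_real_), h, w)
    out[is.na(out)] <- fill
  }
  raster_grid(out, gsd_cm = r$gsd_cm, origin = r$origin, nodata = r$nodata)
}

# Bilinear sampling of matrix m at fractional 0-based pixel coords (xs, ys).
# Out-of-bounds and NA-adjacent samples return `fill`.
bilinear_sample <- function(m, xs, ys, fill) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  inside <- x0 >= 0 & y0 >= 0 & x0 <= w - 1 & y0 <= h - 1
  # clamp the +1 neighbour at the border (replicate edge)
  x1 <- pmax(pmin(x0 + 1, w - 1), 0); y1 <- pmax(pmin(y0 + 1, h - 1), 0)
  x0c <- pmax(pmin(x0, w - 1), 0); y0c <- pmax(pmin(y0, h - 1), 0)
  g <- function(yy, xx) m[cbind(yy + 1, xx + 1)]
  v <- (1 - fx) * (1 - fy) * g(y0c, x0c) +
       fx * (1 - fy) * g(y0c, x1) +
       (1 - fx) * fy * g(y1, x0c) +
       fx * fy * g(y1, x1)
  v[!inside | is.na(v)] <- fill
  v
}

#' Resize a raster by bilinear resampling
#'
#' @param r a [raster_grid()].
#' @param new_h,new_w output dimensions in pixels.
#' @return a resized [raster_grid()]; `gsd_cm` is rescaled accordingly.
#' @export
resize_raster <- function(r, new_h, new_w) {
  d <- dim(r$values)
  sy <- d[1] / new_h; sx <- d[2] / new_w
  xs <- (rep(0:(new_w - 1), each = new_h) + 0.5) * sx - 0.5
  ys <- (rep(0:(new_h - 1), times = new_w) + 0.5) * sy - 0.5
  if (is_rgb(r)) {
    out <- array(0, c(new_h, new_w, 3))
    for (b in 1:3)
      out[, , b] <- matrix(bilinear_sample(r$values[, , b], xs, ys, 0), new_h, new_w)
  } else {
    out <- matrix(bilinear_sample(r$values, xs, ys, r$nodata), new_h, new_w)
  }
  raster_grid(out, gsd_cm = r$gsd_cm * (d[2] / new_w), origin = r$origin,
              nodata = r$nodata)
}

# Crop a half-open pixel box [x0, x0+w) x [y0, y0+h); 0-based coords.
crop_raster_values <- function(values, x0, y0, w, h) {
  if (length(dim(values)) == 3L)
    values[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), , drop = FALSE]
  else
    values[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
}
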