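#' Write plot polygons to an ESRI shapefile
#'
#' Writes one polygon per plot record (the 224 x 224 bounding box, expressed
#' in world coordinates through the raster's affine mapping) to `path.shp`,
#' with the companion `.shx` index and `.dbf` attribute table
#' (`plot_id`, `range_idx`, `bed_idx`, `single_row`).
#'
#' @param plots a tibble of plot records as returned by [delineate_plots()]:
#'   columns `plot_id`, `range_idx`, `bed_idx`, `single_row`, `bbox_x0`,
#'   `bbox_y0`, `bbox_w`, `bbox_h` (pixel units).
#' @param gsd_cm pixel size in cm/px used for the pixel-to-world mapping.
#' @param origin world coordinate of pixel (0, 0), meters.
#' @param path output path without extension (or ending in `.shp`).
#' @return the `.shp` path, invisibly.
#' @export
write_plot_shapefile <- function(plots, gsd_cm, origin = c(0, 0), path) {
  if (NROW(plots) == 0L) stop("empty plot list", call. = FALSE)
  base <- sub("\\.shp$", "", path)
  ref <- list(gsd_cm = gsd_cm, origin = origin)
  polys <- lapply(seq_len(nrow(plots)), function(i) {
    x0 <- plots$bbox_x0[i]; y0 <- plots$bbox_y0[i]
    w <- plots$bbox_w[i]; h <- plots$bbox_h[i]
    px <- c(x0, x0 + w, x0 + w, x0, x0)
    py <- c(y0, y0, y0 + h, y0 + h, y0)
    pixel_to_world(ref, px, py)
  })
  write_shp_polygons(polys, base)
  attrs <- data.frame(plot_id = as.integer(plots$plot_id),
                      range_idx = as.integer(plots$range_idx),
                      bed_idx = as.integer(plots$bed_idx),
                      single_row = as.integer(plots$single_row))
  foreign::write.dbf(attrs, paste0(base, ".dbf"))
  invisible(paste0(base, ".shp"))
}

#' Read plot polygons from an ESRI shapefile
#'
#' Counterpart of [write_plot_shapefile()]: returns the attribute table with
#' a `geometry` list-column of closed polygon rings (two-column matrices of
#' world coordinates, meters).
#'
#' @param path path to the `.shp` file (extension optional).
#' @return a tibble with attribute columns and a `geometry` list-column.
#' @export
read_plot_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path)
  polys <- read_shp_polygons(paste0(base, ".shp"))
  dbf <- paste0(base, ".dbf")
  attrs <- if (file.exists(dbf)) foreign::read.dbf(dbf) else
    data.frame(row.names = seq_along(polys))
  out <- tibble::as_tibble(attrs)
  out$geometry <- polys
  out
}

# --- minimal ESRI shapefile (type 5, polygon) binary writer/reader ---------

write_shp_polygons <- function(polys, base) {
  recs <- lapply(polys, function(p) {
    n <- nrow(p)
    bb <- c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2]))
    list(bb = bb, n = n, pts = p,
         content_words = (4L + 32L + 8L + n * 16L) / 2L)
  })
  total_words <- 50L + sum(vapply(recs, function(r) 4L + r$content_words, 0))
  gbb <- c(min(vapply(recs, function(r) r$bb[1], 0)),
           min(vapply(recs, function(r) r$bb[2], 0)),
           max(vapply(recs, function(r) r$bb[3], 0)),
           max(vapply(recs, function(r) r$bb[4], 0)))
  hdr <- function(con, length_words) {
    writeBin(as.integer(c(9994, 0, 0, 0, 0, 0)), con, size = 4, endian = "big")
    writeBin(as.integer(length_words), con, size = 4, endian = "big")
    writeBin(as.integer(c(1000, 5)), con, size = 4, endian = "little")
    writeBin(as.numeric(c(gbb, 0, 0, 0, 0)), con, size = 8, endian = "little")
  }
  shp <- file(paste0(base, ".shp"), "wb")
  on.exit(close(shp), add = TRUE)
  hdr(shp, total_words)
  shx <- file(paste0(base, ".shx"), "wb")
  on.exit(close(shx), add = TRUE)
  hdr(shx, 50L + 4L * length(recs))
  offset <- 50L
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    writeBin(as.integer(offset), shx, size = 4, endian = "big")
    writeBin(as.integer(r$content_words), shx, size = 4, endian = "big")
    writeBin(as.integer(c(i, r$content_words)), shp, size = 4, endian = "big")
    writeBin(5L, shp, size = 4, endian = "little")
    writeBin(as.numeric(r$bb), shp, size = 8, endian = "little")
    writeBin(as.integer(c(1, r$n, 0)), shp, size = 4, endian = "little")
    writeBin(as.numeric(t(r$pts)), shp, size = 8, endian = "little")
    offset <- offset + 4L + r$content_words
  }
  invisible(base)
}

read_shp_polygons <- function(path) {
  if (!file.exists(path)) stop("cannot read shapefile: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1, size = 4, endian = "big")
  if (!identical(magic, 9994L)) stop("not a shapefile: ", path, call. = FALSE)
  readBin(con, "integer", 5, size = 4, endian = "big")
  len_words <- readBin(con, "integer", 1, size = 4, endian = "big")
  readBin(con, "integer", 2, size = 4, endian = "little")
  readBin(con, "numeric", 8, size = 8, endian = "little")
  polys <- list()
  words_read <- 50L
  while (words_read < len_words) {
    readBin(con, "integer", 1, size = 4, endian = "big")
    content <- readBin(con, "integer", 1, size = 4, endian = "big")
    type <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (type != 5L) stop("unsupported shape type: ", type, call. = FALSE)
    readBin(con, "numeric", 4, size = 8, endian = "little")
    np <- readBin(con, "integer", 2, size = 4, endian = "little")
    readBin(con, "integer", np[1], size = 4, endian = "little")
    pts <- readBin(con, "numeric", 2 * np[2], size = 8, endian = "little")
    polys[[length(polys) + 1L]] <- matrix(pts, ncol = 2, byrow = TRUE,
                                          dimnames = list(NULL, c("wx", "wy")))
    words_read <- words_read + 4L + content
  }
  polys
}
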