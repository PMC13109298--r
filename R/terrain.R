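#' Sample terrain points beside each segmentation mask
#'
#' For every positive label in the mask raster, two points are placed on
#' opposite sides of the mask — at `(bbox_x_min - offset, y_c)` and
#' `(bbox_x_max + offset, y_c)`, where `y_c` is the mask's centroid row —
#' so they land in the bare-soil alley on the raised-bed top next to the
#' plot. Points are clamped inside the raster and nudged outward (up to
#' `offset_px` further) off any vegetation pixel; a point that ends up on
#' DSM nodata is dropped with a warning, and a label whose two points
#' collapse onto one another keeps a single flagged sample.
#'
#' @param labels integer label matrix (0 = background), e.g. from
#'   [segment_rows()].
#' @param dsm the DSM [raster_grid()], co-registered with `labels`.
#' @param offset_px horizontal offset from the mask bounding box, px.
#' @param veg_mask optional logical matrix of vegetation pixels to nudge
#'   away from.
#' @param median3 if `TRUE`, read elevations as the 3 x 3 neighborhood
#'   median instead of the single pixel.
#' @return a tibble with columns `plot_id` (the mask label), `side`
#'   (`"left"`/`"right"`), `x`, `y` (0-based pixel coords), `elev_m`,
#'   `clamped`.
#' @export
sample_terrain_points <- function(labels, dsm, offset_px,
                                  veg_mask = NULL, median3 = FALSE) {
  stopifnot(all(dim(labels) == dim(dsm$values)[1:2]))
  h <- nrow(labels); w <- ncol(labels)
  px <- which(labels > 0L, arr.ind = TRUE)
  if (!nrow(px)) stop("no labelled masks to sample beside", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  rows_by <- split(seq_len(nrow(px)), labels[px])
  read_elev <- function(x, y) {
    if (!median3) return(dsm$values[y + 1, x + 1])
    ys <- pmax(1, pmin(h, (y:(y + 2))))
    xs <- pmax(1, pmin(w, (x:(x + 2))))
    v <- dsm$values[ys, xs]
    v <- v[v != dsm$nodata]
    if (!length(v)) dsm$nodata else stats::median(v)
  }
  out <- list()
  for (id in ids) {
    rc <- px[rows_by[[as.character(id)]], , drop = FALSE]
    y_c <- round(mean(rc[, 1])) - 1L
    x_min <- min(rc[, 2]) - 1L; x_max <- max(rc[, 2]) - 1L
    cand <- list(left = x_min - offset_px, right = x_max + offset_px)
    pts <- list()
    for (side in names(cand)) {
      x <- round(cand[[side]])
      clamped <- x < 0 || x > w - 1
      x <- max(0L, min(w - 1L, x))
      if (!is.null(veg_mask)) {
        step <- if (side == "left") -1L else 1L
        moved <- 0L
        while (veg_mask[y_c + 1, x + 1] && moved < offset_px) {
          xn <- x + step
          if (xn < 0 || xn > w - 1) break
          x <- xn; moved <- moved + 1L
        }
      }
      pts[[side]] <- c(x = x, y = y_c, clamped = clamped)
    }
    if (pts$left[["x"]] == pts$right[["x"]]) {
      pts$right <- NULL
      pts$left[["clamped"]] <- TRUE
    }
    for (side in names(pts)) {
      p <- pts[[side]]
      z <- read_elev(p[["x"]], p[["y"]])
      if (z == dsm$nodata) {
        warning("terrain sample on nodata dropped (label ", id, ")")
        next
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        plot_id = id, side = side, x = p[["x"]], y = p[["y"]],
        elev_m = z, clamped = as.logical(p[["clamped"]]))
    }
  }
  dplyr::bind_rows(out)
}

# ---- Bowyer-Watson Delaunay triangulation --------------------------------

# Incremental Bowyer-Watson on jittered coordinates (a tiny deterministic
# jitter breaks the exact cocircularity of grid-aligned samples without
# measurably moving the surface). Returns a matrix of vertex-index triples.
delaunay_triangulate <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) stop("need at least 3 non-collinear points", call. = FALSE)
  # reject fully collinear inputs: test every point against the longest chord
  a <- xy[1, ]
  d2a <- (xy[, 1] - a[1])^2 + (xy[, 2] - a[2])^2
  b <- xy[which.max(d2a), ]
  cross <- (b[1] - a[1]) * (xy[, 2] - a[2]) - (b[2] - a[2]) * (xy[, 1] - a[1])
  if (all(abs(cross) < 1e-7)) stop("points are collinear", call. = FALSE)
  jit <- 1e-4 * (seq_len(n) %% 7 - 3) / 3
  p <- cbind(xy[, 1] + jit, xy[, 2] + jit * c(1, -1)[seq_len(n) %% 2 + 1])
  rng <- max(max(p[, 1]) - min(p[, 1]), max(p[, 2]) - min(p[, 2]), 1)
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  big <- 1000 * rng
  p <- rbind(p, c(cx - big, cy - big), c(cx + big, cy - big), c(cx, cy + big))
  sup <- n + 1:3
  tris <- matrix(sup, 1, 3)
  cc <- matrix(circumcircle(p[sup[1], ], p[sup[2], ], p[sup[3], ]), 1, 3)
  for (i in seq_len(n)) {
    bad <- which((p[i, 1] - cc[, 1])^2 + (p[i, 2] - cc[, 2])^2 <= cc[, 3])
    if (!length(bad)) next  # degenerate; jitter makes this unreachable
    edges <- NULL
    for (t in bad) {
      v <- tris[t, ]
      edges <- rbind(edges, c(v[1], v[2]), c(v[2], v[3]), c(v[3], v[1]))
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(boundary))) {
      v <- c(boundary[e, ], i)
      tris <- rbind(tris, v)
      cc <- rbind(cc, circumcircle(p[v[1], ], p[v[2], ], p[v[3], ]))
    }
  }
  keep <- !apply(tris, 1, function(v) any(v %in% sup))
  tris <- tris[keep, , drop = FALSE]
  if (!nrow(tris)) stop("points are collinear", call. = FALSE)
  rownames(tris) <- NULL
  tris
}

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

#' Build a digital terrain model from terrain samples
#'
#' Piecewise-linear interpolation over the Delaunay triangulation of the
#' sample points (so any affine terrain is reproduced exactly and the
#' surface passes through every sample); pixels outside the convex hull
#' take the elevation of the nearest sample.
#'
#' @param samples a tibble from [sample_terrain_points()] (columns `x`,
#'   `y`, `elev_m`).
#' @param dim_out output raster dimensions `c(H, W)`.
#' @param gsd_cm pixel size of the output, cm/px.
#' @param nodata nodata sentinel for the output raster.
#' @return the DTM as a [raster_grid()].
#' @export
build_dtm <- function(samples, dim_out, gsd_cm = 1, nodata = -9999) {
  pts <- unique(data.frame(x = samples$x, y = samples$y, z = samples$elev_m))
  # average duplicated locations
  key <- paste(pts$x, pts$y)
  pts <- do.call(rbind, lapply(split(pts, key), function(d)
    data.frame(x = d$x[1], y = d$y[1], z = mean(d$z))))
  if (nrow(pts) < 3L) stop("need at least 3 non-collinear samples", call. = FALSE)
  tris <- delaunay_triangulate(cbind(pts$x, pts$y))
  h <- dim_out[1]; w <- dim_out[2]
  out <- matrix(NA_real_, h, w)
  for (t in seq_len(nrow(tris))) {
    v <- tris[t, ]
    x <- pts$x[v]; y <- pts$y[v]; z <- pts$z[v]
    c0 <- max(0L, floor(min(x))); c1 <- min(w - 1L, ceiling(max(x)))
    r0 <- max(0L, floor(min(y))); r1 <- min(h - 1L, ceiling(max(y)))
    if (c1 < c0 || r1 < r0) next
    xs <- rep(c0:c1, each = r1 - r0 + 1)
    ys <- rep(r0:r1, times = c1 - c0 + 1)
    det <- (y[2] - y[3]) * (x[1] - x[3]) + (x[3] - x[2]) * (y[1] - y[3])
    if (abs(det) < 1e-12) next
    l1 <- ((y[2] - y[3]) * (xs - x[3]) + (x[3] - x[2]) * (ys - y[3])) / det
    l2 <- ((y[3] - y[1]) * (xs - x[3]) + (x[1] - x[3]) * (ys - y[3])) / det
    l3 <- 1 - l1 - l2
    # tolerance admits pixels on shared edges and on the hull boundary,
    # which the coordinate jitter would otherwise push marginally outside
    eps <- -1e-4
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (!any(inside)) next
    zi <- l1[inside] * z[1] + l2[inside] * z[2] + l3[inside] * z[3]
    out[cbind(ys[inside] + 1, xs[inside] + 1)] <- zi
  }
  miss <- which(is.na(out))
  if (length(miss)) {
    # nearest-sample extrapolation outside the hull, chunked to bound memory
    mx <- (miss - 1) %/% h  # 0-based col
    my <- (miss - 1) %% h   # 0-based row
    np <- nrow(pts)
    chunk <- max(1L, as.integer(2e6 / np))
    for (s in seq(1, length(miss), by = chunk)) {
      e <- min(length(miss), s + chunk - 1)
      d2 <- outer(mx[s:e], pts$x, `-`)^2 + outer(my[s:e], pts$y, `-`)^2
      out[miss[s:e]] <- pts$z[max.col(-d2, ties.method = "first")]
    }
  }
  raster_grid(out, gsd_cm = gsd_cm, nodata = nodata)
}

#' Compute the normalized DSM
#'
#' Per-pixel `dsm - dtm`; nodata in either input propagates to the output.
#'
#' @param dsm,dtm co-registered [raster_grid()]s of identical shape.
#' @return the nDSM as a [raster_grid()] (meters above local ground).
#' @export
compute_ndsm <- function(dsm, dtm) {
  if (!all(dim(dsm$values) == dim(dtm$values)))
    stop("DSM and DTM shapes differ", call. = FALSE)
  nd <- dsm$values == dsm$nodata | dtm$values == dtm$nodata
  out <- dsm$values - dtm$values
  out[nd] <- dsm$nodata
  raster_grid(out, gsd_cm = dsm$gsd_cm, origin = dsm$origin,
              nodata = dsm$nodata)
}
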