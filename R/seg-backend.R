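#' Segmentation backend configuration
#'
#' The pipeline talks to a promptable-segmentation backend through two
#' operations: [auto_masks()] (dense automatic mask proposal, used for
#' field localization) and [prompt_mask()] (foreground/background point
#' queries, used for plot segmentation).
#'
#' Two backends exist:
#' * `"classical"` (built in, default): vegetation-index thresholding
#'   (ExG-ExR > 0) plus connected components. Deterministic, needs no model
#'   weights. Its predicted-IoU and stability scores are a component
#'   solidity surrogate (component area / bounding-box area), which favors
#'   compact, complete regions.
#' * `"foundation"`: an adapter slot for an external promptable-segmentation
#'   foundation model. Requires a checkpoint; without one, configuration
#'   errors direct the user to the classical backend.
#'
#' Default parameters follow the automatic-generator settings used for
#' aerial orthomosaics: a 32 x 32 query grid, predicted-IoU and stability
#' thresholds of 0 (no quality filtering) and an NMS threshold of 1 (no
#' overlap suppression), with the longest image side resized to 1024 px.
#'
#' @param backend `"classical"` or `"foundation"`.
#' @param checkpoint_path path to foundation-model weights (foundation only).
#' @param variant foundation-model variant string, passed through.
#' @param grid_side query-grid side length.
#' @param iou_threshold,stability_threshold candidate quality thresholds.
#' @param nms_threshold overlap-suppression threshold (1 keeps everything).
#' @param max_long_side working resolution for automatic mask generation.
#' @return a `seg_backend` object.
#' @export
seg_backend <- function(backend = c("classical", "foundation"),
                        checkpoint_path = NULL, variant = "vit_h",
                        grid_side = 32L, iou_threshold = 0,
                        stability_threshold = 0, nms_threshold = 1,
                        max_long_side = 1024L) {
  backend <- match.arg(backend)
  stopifnot(grid_side >= 1,
            iou_threshold >= 0, iou_threshold <= 1,
            stability_threshold >= 0, stability_threshold <= 1,
            nms_threshold >= 0, nms_threshold <= 1)
  structure(list(backend = backend, checkpoint_path = checkpoint_path,
                 variant = variant, grid_side = as.integer(grid_side),
                 iou_threshold = iou_threshold,
                 stability_threshold = stability_threshold,
                 nms_threshold = nms_threshold,
                 max_long_side = as.integer(max_long_side)),
            class = "seg_backend")
}

assert_foundation_available <- function(be) {
  if (is.null(be$checkpoint_path) || !file.exists(be$checkpoint_path))
    stop("foundation backend requires a model checkpoint; ",
         "use seg_backend(\"classical\") to run without model weights",
         call. = FALSE)
  stop("no foundation-model runtime is linked into this installation; ",
       "use seg_backend(\"classical\")", call. = FALSE)
}

# ExG-ExR vegetation mask + connected components of an RGB array (0-255).
# Returns the integer label matrix (EBImage::bwlabel).
vegetation_components <- function(rgb_values) {
  veg <- vegetation_index_values(rgb_values)$mask
  lab <- EBImage::bwlabel(veg)
  matrix(as.integer(lab), nrow(veg), ncol(veg))
}

component_candidates <- function(lab) {
  n <- max(lab)
  out <- vector("list", n)
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (n == 0L) return(out)
  by_lab <- split(seq_len(nrow(idx)), lab[idx])
  for (k in seq_len(n)) {
    rows <- idx[by_lab[[as.character(k)]], , drop = FALSE]
    out[[k]] <- candidate_from_pixels(rows, dim(lab))
  }
  out
}

# build a CandidateMask record from pixel indices (row, col), 1-based
candidate_from_pixels <- function(rc, dm) {
  x0 <- min(rc[, 2]) - 1L; x1 <- max(rc[, 2]) - 1L
  y0 <- min(rc[, 1]) - 1L; y1 <- max(rc[, 1]) - 1L
  area <- nrow(rc)
  solidity <- area / ((x1 - x0 + 1) * (y1 - y0 + 1))
  mask <- matrix(FALSE, dm[1], dm[2])
  mask[rc] <- TRUE
  list(mask = mask,
       predicted_iou = solidity, stability = solidity,
       centroid = c(x = (x0 + x1) / 2, y = (y0 + y1) / 2),
       area = area)
}

#' Automatic mask generation
#'
#' Proposes candidate masks for every object in the image. The classical
#' backend returns one candidate per connected component of the ExG-ExR
#' vegetation mask plus one candidate for their union (the whole planted
#' area), each scored by the solidity surrogate; with `nms_threshold = 1`
#' no candidate is ever discarded for overlap.
#'
#' @param image an H x W x 3 RGB array (0--255) or an RGB [raster_grid()].
#' @param backend a [seg_backend()].
#' @return a list of candidate masks, each a list with elements `mask`
#'   (logical matrix), `predicted_iou`, `stability`, `centroid` (bounding
#'   box center, 0-based pixel coords) and `area`.
#' @export
auto_masks <- function(image, backend = seg_backend()) {
  vals <- if (inherits(image, "raster_grid")) image$values else image
  stopifnot(length(dim(vals)) == 3L)
  if (backend$backend == "foundation") assert_foundation_available(backend)
  lab <- vegetation_components(vals)
  cands <- component_candidates(lab)
  if (length(cands) > 1L) {
    rc <- which(lab > 0L, arr.ind = TRUE)
    cands <- c(cands, list(candidate_from_pixels(rc, dim(lab))))
  }
  keep <- vapply(cands, function(cc)
    cc$predicted_iou >= backend$iou_threshold &&
      cc$stability >= backend$stability_threshold, TRUE)
  cands[keep]
}

#' Point-prompted mask query
#'
#' The classical backend returns the vegetation connected component
#' containing the first foreground point, minus any component containing a
#' background point. A foreground point on non-vegetation yields an empty
#' mask with a warning; foreground and background points in the same
#' component leave the component unchanged (with a warning).
#'
#' @param image RGB array or [raster_grid()].
#' @param fg_points matrix/data.frame of foreground points `(x, y)`,
#'   0-based pixel coords; at least one required.
#' @param bg_points optional background points.
#' @param backend a [seg_backend()].
#' @param labels optional precomputed component label matrix (used by
#'   [segment_rows()] to avoid relabeling per prompt).
#' @return a logical mask matrix.
#' @export
prompt_mask <- function(image, fg_points, bg_points = NULL,
                        backend = seg_backend(), labels = NULL) {
  if (backend$backend == "foundation") assert_foundation_available(backend)
  fg <- as.matrix(fg_points)
  if (nrow(fg) < 1L) stop("at least one foreground point required", call. = FALSE)
  if (is.null(labels)) {
    vals <- if (inherits(image, "raster_grid")) image$values else image
    labels <- vegetation_components(vals)
  }
  at <- function(p) labels[round(p[2]) + 1L, round(p[1]) + 1L]
  fg_lab <- at(fg[1, ])
  if (fg_lab == 0L) {
    warning("foreground point on non-vegetation; returning empty mask")
    return(matrix(FALSE, nrow(labels), ncol(labels)))
  }
  if (!is.null(bg_points) && nrow(as.matrix(bg_points)) > 0L) {
    bg_labs <- apply(as.matrix(bg_points), 1, at)
    if (fg_lab %in% bg_labs)
      warning("foreground and background prompts fall in the same component")
  }
  labels == fg_lab
}
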