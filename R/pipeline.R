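#' Pipeline configuration
#'
#' One declarative object holding every stage's tunables. Defaults follow
#' the published protocol wherever it states a value (backend automatic
#' generator settings, 5 px center filter, 224 px plot boxes, maximum
#' statistic for canopy height) and the trial layout for the geometry
#' (0.91 m rows, 1.82 m beds, 2 m alleys).
#'
#' @param backend a [seg_backend()].
#' @param center_radius_px field-candidate center filter radius (resized px).
#' @param row_spacing_m,bed_width_m,alley_m trial geometry, meters.
#' @param valley_frac,peak_frac vegetation-profile thresholds.
#' @param k_bg background points per prompt.
#' @param offset_frac terrain-sample offset as a fraction of the alley
#'   width.
#' @param depth_threshold_m,angle_window_deg,min_support_frac bed-line
#'   detection parameters.
#' @param box_px plot bounding-box side (px).
#' @param ch_stat canopy-height statistic.
#' @param median3 read terrain samples as 3 x 3 medians.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(backend = seg_backend(),
                            center_radius_px = 5,
                            row_spacing_m = 0.91, bed_width_m = 1.82,
                            alley_m = 2.0,
                            valley_frac = 0.1, peak_frac = 0.3,
                            k_bg = 4,
                            offset_frac = 0.25,
                            depth_threshold_m = 0.01,
                            angle_window_deg = 2,
                            min_support_frac = 0.25,
                            box_px = 224L, ch_stat = "max",
                            median3 = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full phenotyping pipeline
#'
#' Stages, in order: field localization (`find-field`), range/row detection
#' and prompt-based row segmentation (`segment-plots`), terrain sampling,
#' Delaunay DTM and nDSM (`build-ndsm`), bed-line detection and plot
#' delineation (`delineate`), and per-plot canopy height extraction
#' (`extract-traits`). Any stage failure aborts with the stage name. With
#' the classical backend the whole pipeline is deterministic given the
#' config.
#'
#' @param ortho RGB orthomosaic [raster_grid()].
#' @param dsm co-registered DSM [raster_grid()], meters.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, the plot
#'   shapefile, DTM/nDSM rasters, the row-label raster, `traits.csv` and
#'   `report.json` are written there.
#' @return a `pheno_pipeline` list: `field`, `rotation`, `layout`,
#'   `segmentation`, `samples`, `dtm`, `ndsm`, `bed_lines`, `plots`,
#'   `patches`, `traits`, `report`.
#' @export
run_pipeline <- function(ortho, dsm, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(ortho, "raster_grid"), inherits(dsm, "raster_grid"))
  if (!all(dim(ortho$values)[1:2] == dim(dsm$values)[1:2]))
    stop("orthomosaic and DSM dimensions differ", call. = FALSE)
  gsd <- ortho$gsd_cm
  row_px <- config$row_spacing_m * 100 / gsd
  bed_px <- config$bed_width_m * 100 / gsd
  alley_px <- config$alley_m * 100 / gsd
  report <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    report[[length(report) + 1L]] <<- tibble::tibble(
      stage = name, seconds = as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  field <- stage("find-field",
                 locate_field(ortho, config$backend, config$center_radius_px))
  rta <- stage("find-field-rotate",
               rotate_to_axis(ortho, dsm, field, row_spacing_px = row_px))
  seg <- stage("segment-plots", {
    veg <- vegetation_index(rta$ortho)
    layout <- detect_layout(veg, row_px, config$valley_frac, config$peak_frac)
    if (is.null(layout$centroids) || nrow(layout$centroids) == 0L)
      stop("no plot centroids detected")
    s <- segment_rows(rta$ortho, layout, config$backend, config$k_bg)
    list(veg = veg, layout = layout, labels = s$labels,
         centroids = s$centroids)
  })
  nd <- stage("build-ndsm", {
    samples <- sample_terrain_points(seg$labels, rta$dsm,
                                     offset_px = config$offset_frac * alley_px,
                                     veg_mask = seg$veg$mask,
                                     median3 = config$median3)
    dtm <- build_dtm(samples, dim(rta$dsm$values), gsd_cm = gsd,
                     nodata = rta$dsm$nodata)
    list(samples = samples, dtm = dtm, ndsm = compute_ndsm(rta$dsm, dtm))
  })
  del <- stage("delineate", {
    lines <- detect_bed_lines(nd$ndsm, bed_width_px = bed_px,
                              depth_threshold_m = config$depth_threshold_m,
                              angle_window_deg = config$angle_window_deg,
                              min_support_frac = config$min_support_frac)
    plots <- delineate_plots(seg$layout$ranges, lines, seg$labels,
                             box_px = config$box_px)
    if (nrow(plots) == 0L) stop("no plots delineated")
    list(lines = lines, plots = plots)
  })
  traits <- stage("extract-traits", {
    patches <- plot_patches(del$plots, rta$ortho, nd$ndsm, seg$labels)
    tt <- extract_traits(patches, stat = config$ch_stat)
    tt$gh <- NA_character_; tt$mp <- NA_character_
    list(patches = patches, table = tt)
  })

  report <- dplyr::bind_rows(report)
  report$stage <- sub("find-field-rotate", "find-field", report$stage)
  report <- dplyr::summarise(dplyr::group_by(report, .data$stage),
                             seconds = sum(.data$seconds), .groups = "drop")
  report <- report[match(c("find-field", "segment-plots", "build-ndsm",
                           "delineate", "extract-traits"), report$stage), ]
  out <- structure(list(
    field = field, rotation = rta[c("angle_deg")],
    layout = seg$layout, segmentation = seg[c("labels", "centroids")],
    samples = nd$samples, dtm = nd$dtm, ndsm = nd$ndsm,
    bed_lines = del$lines, plots = del$plots,
    patches = traits$patches, traits = traits$table,
    report = list(stages = report,
                  n_plots = nrow(del$plots),
                  n_centroids = nrow(seg$centroids),
                  orientation_deg = field$orientation_deg,
                  config = config[setdiff(names(config), "backend")])),
    class = "pheno_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, rta, out_dir)
  out
}

write_pipeline_outputs <- function(res, rta, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gsd <- res$ndsm$gsd_cm
  write_plot_shapefile(res$plots, gsd_cm = gsd, origin = res$ndsm$origin,
                       path = file.path(out_dir, "plots"))
  write_raster(res$dtm, file.path(out_dir, "dtm.tif"))
  write_raster(res$ndsm, file.path(out_dir, "ndsm.tif"))
  labr <- raster_grid(res$segmentation$labels + 0, gsd_cm = gsd)
  write_raster(labr, file.path(out_dir, "row_labels.tif"))
  utils::write.csv(res$traits, file.path(out_dir, "traits.csv"),
                   row.names = FALSE)
  rep <- res$report
  rep$stages <- lapply(seq_len(nrow(rep$stages)), function(i)
    as.list(rep$stages[i, ]))
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' @export
print.pheno_pipeline <- function(x, ...) {
  cat(sprintf(
    "<pheno_pipeline: %d plots, orientation %.2f deg, %d row masks>\n",
    nrow(x$plots), x$field$orientation_deg,
    sum(x$segmentation$centroids$label > 0)))
  print(x$report$stages)
  invisible(x)
}
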