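#' Run the end-to-end vessel-density pipeline on one image
#'
#' Orchestrates the full measurement chain: multi-scale features, random-
#' forest pixel classification (training first if annotations rather than a
#' fitted model are supplied), avascular-core extraction, one peripapillary
#' annulus per configured band width, and a density measurement for every
#' annulus plus the whole image. The run is deterministic given the inputs
#' and the config seed. If no avascular component survives post-processing, a
#' partial result with the whole-image density only is returned with a
#' warning.
#'
#' @param image an [octa_image].
#' @param annotations_or_model an [annotation_set] (training is performed) or
#'   a fitted `octa_classifier` (prediction only).
#' @param config a [pipeline_config].
#' @param out_dir optional directory; when given, masks (PNG), the density
#'   table (CSV), the effective config and the run log are written there.
#' @return An object of class `pipeline_run`: config, model, segmentation,
#'   core and annulus masks, the list of `density_measurement`s, their table,
#'   and a stage-by-stage log.
#' @export
run_density_pipeline <- function(image, annotations_or_model,
                                 config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(image, "octa_image"))
  log <- character(0)
  t0 <- proc.time()[["elapsed"]]
  note <- function(stage, msg) {
    entry <- sprintf("[%7.2fs] %s: %s", proc.time()[["elapsed"]] - t0,
                     stage, msg)
    log <<- c(log, entry)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  note("input", sprintf("%dx%d px, %.3f um/px, signature %.6g",
                        image$width_px, image$height_px, image$pixel_size_um,
                        sum(image$pixels)))
  scales <- config$scales_um
  if (is.null(scales)) {
    scales <- default_scales(image$pixel_size_um,
                             config$vessel_diameter_range_um)
    note("scales", paste("derived:", paste(scales, collapse = ", "), "um"))
  }
  stack <- stage("features", compute_features(image, scales))
  note("features", sprintf("%d channels", dim(stack$features)[3]))

  if (inherits(annotations_or_model, "annotation_set")) {
    model <- stage("train",
                   train_pixel_classifier(stack, annotations_or_model, config))
    note("train", sprintf("training accuracy %.4f, oob %.4f (seed %d)",
                          model$training_accuracy, model$oob_accuracy,
                          config$seed))
  } else if (inherits(annotations_or_model, "octa_classifier")) {
    model <- annotations_or_model
    note("train", "skipped (fitted model supplied)")
  } else {
    stop("`annotations_or_model` must be an annotation_set or octa_classifier")
  }

  seg <- stage("predict", predict(model, stack, threshold = config$threshold))
  note("predict", sprintf("%d px avascular at threshold %.2f", sum(seg$mask),
                          config$threshold))

  densities <- list(whole = whole_image_mean(image))
  core <- NULL; annuli <- list()
  core_try <- tryCatch(
    extract_avascular_region(seg, config$min_area_px, image$pixel_size_um),
    error = function(e) e)
  if (inherits(core_try, "error")) {
    warning("no avascular region found; returning whole-image density only")
    note("core", paste("FAILED:", conditionMessage(core_try)))
  } else {
    core <- core_try
    note("core", sprintf("%d px (%.3g mm^2)", core$area_px,
                         core$area_um2 / 1e6))
    densities$core <- mean_gray_in_roi(image, core)
    for (bw in config$band_widths_um) {
      ann <- stage(sprintf("annulus_%g", bw),
                   build_peripapillary_annulus(core, bw, image$pixel_size_um))
      annuli[[sprintf("annulus_%g", bw)]] <- ann
      densities[[sprintf("annulus_%g", bw)]] <- mean_gray_in_roi(image, ann)
      note(sprintf("annulus_%g", bw),
           sprintf("%d px, mean gray %.4f", ann$area_px,
                   densities[[sprintf("annulus_%g", bw)]]$mean_gray))
    }
  }
  tab <- density_table(densities)
  run <- structure(list(config = config, model = model, segmentation = seg,
                        core = core, annuli = annuli, densities = densities,
                        table = tab, log = log),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline_run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_mask(run$segmentation$mask, file.path(out_dir, "segmentation.png"))
  if (!is.null(run$core))
    write_mask(run$core$mask, file.path(out_dir, "avascular_core.png"))
  for (nm in names(run$annuli))
    write_mask(run$annuli[[nm]]$mask, file.path(out_dir, paste0(nm, ".png")))
  write_density_csv(run$table, file.path(out_dir, "densities.csv"))
  write_config(run$config, file.path(out_dir, "config.txt"))
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
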