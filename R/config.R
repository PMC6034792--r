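#' Pipeline configuration
#'
#' Bundles every tunable parameter of the density pipeline. All defaults are
#' the package's stated operating point; see the methods vignette for the
#' rationale behind each.
#'
#' @param scales_um feature scales in micrometres. `NULL` (default) derives a
#'   geometric ladder from `vessel_diameter_range_um` at run time via
#'   [default_scales()].
#' @param band_widths_um peripapillary annulus band widths in micrometres.
#' @param ntree number of trees in the random forest.
#' @param mtry features tried per split; `NULL` means `floor(sqrt(F))`.
#' @param max_depth maximum tree depth; `0` = unlimited.
#' @param sample_cap per-class cap on training pixels (balanced subsampling,
#'   drawn with `seed`).
#' @param threshold avascular-probability threshold for the binary mask;
#'   ties (exactly at the threshold) are assigned to the avascular class.
#' @param min_area_px components smaller than this are not eligible as the
#'   avascular core.
#' @param vessel_diameter_range_um expected vessel diameter range, used to
#'   derive `scales_um` when it is `NULL`.
#' @param report_decimals decimal places at which reported percentages are
#'   truncated (floor).
#' @param seed master seed; every stochastic stage derives its own stream
#'   from it deterministically.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scales_um = NULL,
                            band_widths_um = c(640, 920, 1960),
                            ntree = 100L, mtry = NULL, max_depth = 0L,
                            sample_cap = 10000L, threshold = 0.5,
                            min_area_px = 50L,
                            vessel_diameter_range_um = c(10, 160),
                            report_decimals = 2L, seed = 1L) {
  if (!is.null(scales_um)) {
    if (length(scales_um) == 0 || any(scales_um <= 0))
      stop("`scales_um` must be non-empty and strictly positive")
  }
  if (any(band_widths_um <= 0)) stop("band widths must be positive")
  if (ntree < 1) stop("`ntree` must be at least 1")
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  structure(list(scales_um = scales_um, band_widths_um = band_widths_um,
                 ntree = as.integer(ntree),
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 max_depth = as.integer(max_depth),
                 sample_cap = as.integer(sample_cap), threshold = threshold,
                 min_area_px = as.integer(min_area_px),
                 vessel_diameter_range_um = vessel_diameter_range_um,
                 report_decimals = as.integer(report_decimals),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a configuration as a flat key-value text file
#'
#' One `key = value` pair per line; vector values are comma-separated.
#' A config round-trips exactly: `read_config(write_config(cfg, f))` is
#' identical to `cfg`.
#'
#' @param config a [pipeline_config].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return("NULL")
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = ",")
  }
  lines <- vapply(names(config), function(k) paste0(k, " = ", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_0-9]+)\\s*=\\s*(.*)$", lines))
  if (any(lengths(kv) != 3)) stop("malformed config line")
  out <- list()
  int_keys <- c("ntree", "mtry", "max_depth", "sample_cap", "min_area_px",
                "report_decimals", "seed")
  for (m in kv) {
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <- if (val == "NULL") NULL
      else if (key %in% int_keys) as.integer(strsplit(val, ",")[[1]])
      else as.numeric(strsplit(val, ",")[[1]])
  }
  do.call(pipeline_config, out)
}
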