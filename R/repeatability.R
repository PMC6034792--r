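#' Relative fluctuation of a repeat-measurement series
#'
#' Computes mean, standard deviation and the relative fluctuation
#' (coefficient of variation) `100 * sd / mean` of a series of repeated
#' density measurements, together with the value truncated (floored, not
#' rounded) at a stated decimal precision — the convention under which the
#' printed repeatability tables of this problem domain are reproducible from
#' their own sd/mean rows.
#'
#' @param values numeric vector, `n >= 2`, positive mean.
#' @param report_decimals decimals at which `reported_pct` is truncated.
#' @param sd_type `"population"` (divide by `n`, default) or `"sample"`
#'   (divide by `n - 1`).
#' @return An object of class `fluctuation_stats` with fields `n`,
#'   `mean_value`, `sd`, `sd_type`, `relative_fluctuation_pct` and
#'   `reported_pct`.
#' @export
fluctuation_stats <- function(values, report_decimals = 2L,
                              sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values (got ", n, ")")
  if (!all(is.finite(values))) stop("non-finite value in series")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive (got ", m, ")")
  s <- if (sd_type == "population") sqrt(mean((values - m)^2))
       else stats::sd(values)
  rel <- 100 * s / m
  structure(list(n = n, mean_value = m, sd = s, sd_type = sd_type,
                 relative_fluctuation_pct = rel,
                 reported_pct = truncate_at_precision(rel, report_decimals),
                 report_decimals = as.integer(report_decimals)),
            class = "fluctuation_stats")
}

#' @export
print.fluctuation_stats <- function(x, ...) {
  cat(sprintf(
    "fluctuation_stats: n = %d, mean %.4f, sd %.4f (%s), fluctuation %.4f%% (reported %s%%)\n",
    x$n, x$mean_value, x$sd, x$sd_type, x$relative_fluctuation_pct,
    format(x$reported_pct, nsmall = x$report_decimals)))
  invisible(x)
}

#' Truncate a non-negative value at a decimal precision
#'
#' `floor(x * 10^decimals) / 10^decimals`. A tiny relative epsilon guards
#' against values that are exactly representable at the target precision
#' landing one ulp below it (e.g. `truncate_at_precision(5.0, 3)` is `5`).
#'
#' @param x non-negative numeric.
#' @param decimals integer `>= 0`.
#' @return truncated value.
#' @export
truncate_at_precision <- function(x, decimals) {
  if (any(x < 0)) stop("`x` must be non-negative")
  if (decimals < 0) stop("`decimals` must be >= 0")
  f <- 10^decimals
  floor(x * f * (1 + 1e-12)) / f
}

#' Percent decrease between consecutive disease-stage means
#'
#' `100 * (mean_earlier - mean_later) / mean_earlier`: how much lower the
#' later (more severe) stage's mean density is, as a percentage of the
#' earlier stage's.
#'
#' @param mean_earlier,mean_later stage means; `mean_earlier` must be
#'   positive.
#' @return percentage (full precision; truncate for reporting with
#'   [truncate_at_precision()]).
#' @export
stage_difference_percent <- function(mean_earlier, mean_later) {
  if (any(mean_earlier <= 0)) stop("`mean_earlier` must be positive")
  100 * (mean_earlier - mean_later) / mean_earlier
}

#' Annotation-repeatability experiment
#'
#' Quantifies how much the final density measurement depends on where the
#' annotator placed the training scribbles. For each annotation set the full
#' pipeline is run on the image (features -> train -> predict -> avascular
#' core -> annulus -> mean gray), and the fluctuation statistics of the
#' resulting densities are returned.
#'
#' @param image an [octa_image].
#' @param annotation_sets list of at least two [annotation_set] objects.
#' @param config a [pipeline_config]; the first configured band width is the
#'   measured annulus.
#' @return A `fluctuation_stats` object; the individual densities are
#'   attached as attribute `"densities"`.
#' @export
annotation_repeatability <- function(image, annotation_sets,
                                     config = pipeline_config()) {
  if (length(annotation_sets) < 2)
    stop("need at least 2 annotation sets (got ", length(annotation_sets), ")")
  scales <- config$scales_um
  if (is.null(scales))
    scales <- default_scales(image$pixel_size_um,
                             config$vessel_diameter_range_um)
  stack <- compute_features(image, scales)
  densities <- vapply(annotation_sets, function(ann) {
    id <- if (inherits(ann, "annotation_set")) ann$annotation_id else "?"
    tryCatch({
      model <- train_pixel_classifier(stack, ann, config)
      seg <- predict(model, stack, threshold = config$threshold)
      core <- extract_avascular_region(seg, config$min_area_px,
                                       image$pixel_size_um)
      ann_roi <- build_peripapillary_annulus(core, config$band_widths_um[1],
                                             image$pixel_size_um)
      mean_gray_in_roi(image, ann_roi)$mean_gray
    }, error = function(e)
      stop("annotation '", id, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }, numeric(1))
  out <- fluctuation_stats(densities, config$report_decimals)
  attr(out, "densities") <- densities
  out
}
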