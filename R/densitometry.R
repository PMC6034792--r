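#' Gray-level vessel density over a region of interest
#'
#' Vessel density is quantified as the arithmetic mean gray value over the
#' ROI; the integrated gray-level density (the plain sum) is reported
#' alongside, since the two conventions coincide up to the fixed pixel count
#' and either may be consumed downstream.
#'
#' @param image an [octa_image].
#' @param roi an `roi_mask` (or logical matrix) of the same shape; must be
#'   non-empty.
#' @return An object of class `density_measurement` with fields `mean_gray`,
#'   `integrated_density`, `n_pixels`, `roi_role`, `band_width_um` and the
#'   image's acquisition metadata.
#' @export
mean_gray_in_roi <- function(image, roi) {
  stopifnot(inherits(image, "octa_image"))
  role <- if (inherits(roi, "roi_mask")) roi$role else "custom"
  band <- if (inherits(roi, "roi_mask")) roi$band_width_um else NA_real_
  mask <- if (inherits(roi, "roi_mask")) roi$mask else as_binary_mask(roi)
  check_same_shape(mask, image$pixels, "ROI", "image")
  n <- sum(mask)
  if (n == 0) stop("empty ROI: density is undefined")
  total <- sum(image$pixels[mask])
  density_measurement(mean_gray = total / n, integrated_density = total,
                      n_pixels = n, roi_role = role, band_width_um = band,
                      image = image)
}

#' @rdname mean_gray_in_roi
#' @description `whole_image_mean()` measures the mean gray value of the
#'   entire image (the repeat-acquisition statistic).
#' @export
whole_image_mean <- function(image) {
  stopifnot(inherits(image, "octa_image"))
  density_measurement(mean_gray = mean(image$pixels),
                      integrated_density = sum(image$pixels),
                      n_pixels = length(image$pixels),
                      roi_role = "whole_image", band_width_um = NA_real_,
                      image = image)
}

density_measurement <- function(mean_gray, integrated_density, n_pixels,
                                roi_role, band_width_um, image) {
  structure(list(mean_gray = mean_gray,
                 integrated_density = integrated_density,
                 n_pixels = n_pixels, roi_role = roi_role,
                 band_width_um = band_width_um, layer = image$layer,
                 device_label = image$device_label,
                 subject_id = image$subject_id, eye = image$eye,
                 acquisition_index = image$acquisition_index),
            class = "density_measurement")
}

#' @export
print.density_measurement <- function(x, ...) {
  cat(sprintf("density_measurement (%s%s): mean gray %.3f over %d px\n",
              x$roi_role,
              if (!is.na(x$band_width_um))
                sprintf(", band %g um", x$band_width_um) else "",
              x$mean_gray, x$n_pixels))
  invisible(x)
}

#' Collect density measurements into a table
#'
#' One row per (subject, eye, acquisition, layer, roi_role, band_width_um),
#' the package's CSV interchange format.
#'
#' @param measurements list of `density_measurement` objects.
#' @return data.frame.
#' @export
density_table <- function(measurements) {
  do.call(rbind, lapply(measurements, function(m)
    data.frame(subject_id = as.character(m$subject_id),
               eye = as.character(m$eye),
               acquisition_index = as.character(m$acquisition_index),
               layer = m$layer, device_label = m$device_label,
               roi_role = m$roi_role, band_width_um = m$band_width_um,
               n_pixels = m$n_pixels, mean_gray = m$mean_gray,
               integrated_density = m$integrated_density)))
}

#' @rdname density_table
#' @param table data.frame from `density_table()`.
#' @param path CSV path.
#' @export
write_density_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname density_table
#' @export
read_density_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
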