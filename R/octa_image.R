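#' En-face OCT-A image with physical calibration
#'
#' Container for a 2D 8-bit grayscale en-face angiogram together with its
#' physical pixel calibration and acquisition metadata. Pixels are stored as a
#' numeric matrix (rows = image rows, origin top-left, 0-based coordinate
#' convention in all documentation) with intensities in `[0, 255]`.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size_um physical size of one (isotropic) pixel in micrometres.
#' @param layer retinal layer the en-face projection was taken from: `"SCN"`
#'   (superficial capillary network), `"DCN"` (deep capillary network) or
#'   `"other"`.
#' @param device_label free-text device identifier (e.g. `"Angioplex"`).
#' @param subject_id,eye,acquisition_index acquisition metadata, free form.
#' @return An object of class `octa_image`.
#' @export
octa_image <- function(pixels, pixel_size_um, layer = c("other", "SCN", "DCN"),
                       device_label = "", subject_id = NA, eye = NA,
                       acquisition_index = NA) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("`pixels` must be a non-empty matrix")
  if (!all(is.finite(pixels)))
    stop("`pixels` contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("intensities must lie within [0, 255]")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  layer <- match.arg(layer)
  structure(
    list(pixels = pixels,
         width_px = ncol(pixels), height_px = nrow(pixels),
         pixel_size_um = pixel_size_um, layer = layer,
         device_label = device_label, subject_id = subject_id, eye = eye,
         acquisition_index = acquisition_index),
    class = "octa_image")
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf("octa_image: %d x %d px, %.3f um/px (%.2f x %.2f mm), layer %s\n",
              x$width_px, x$height_px, x$pixel_size_um,
              x$width_px * x$pixel_size_um / 1000,
              x$height_px * x$pixel_size_um / 1000, x$layer))
  cat(sprintf("  intensity range [%.1f, %.1f], mean %.2f\n",
              min(x$pixels), max(x$pixels), mean(x$pixels)))
  invisible(x)
}

#' Sparse scribble annotations for classifier training
#'
#' A label image aligned with an [octa_image]: `0` = unlabeled, `1` =
#' avascular, `2` = vascular. At least one pixel of each of the two classes
#' must be present, because both are needed to train the pixel classifier.
#'
#' @param label_image integer-valued matrix with values in `{0, 1, 2}`.
#' @param annotation_id identifier carried through reports.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(label_image, annotation_id = "annotation") {
  if (!is.matrix(label_image)) stop("`label_image` must be a matrix")
  vals <- unique(as.vector(label_image))
  if (!all(vals %in% c(0, 1, 2)))
    stop("annotation labels must be in {0, 1, 2}; found: ",
         paste(setdiff(vals, 0:2), collapse = ", "))
  if (!any(label_image == 1))
    stop("no annotated pixels for class avascular (label 1)")
  if (!any(label_image == 2))
    stop("no annotated pixels for class vascular (label 2)")
  structure(list(label_image = label_image, annotation_id = annotation_id),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set '%s': %d avascular px, %d vascular px on %d x %d grid\n",
              x$annotation_id, sum(x$label_image == 1), sum(x$label_image == 2),
              ncol(x$label_image), nrow(x$label_image)))
  invisible(x)
}

# shared shape check
check_same_shape <- function(a, b, what_a, what_b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s shape (%s) does not match %s shape (%s)",
                 what_a, paste(dim(a), collapse = "x"),
                 what_b, paste(dim(b), collapse = "x")))
  invisible(TRUE)
}
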