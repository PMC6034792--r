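#' Read an en-face OCT-A image and attach physical calibration
#'
#' Reads a PNG or uncompressed grayscale TIFF, converts it to a single-channel
#' 8-bit intensity matrix, and derives the isotropic pixel calibration from
#' the declared field of view: `pixel_size_um = 1000 * field_of_view_mm /
#' width_px`. Higher bit depths are linearly rescaled so the full dynamic
#' range maps to `[0, 255]`; RGB exports (pseudo-gray) are collapsed by
#' channel averaging.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param field_of_view_mm lateral field of view in millimetres (e.g. `3` for
#'   the usual 3 x 3 mm optic-nerve scan).
#' @param layer,device_label,subject_id,eye,acquisition_index metadata passed
#'   to [octa_image()].
#' @return An [octa_image].
#' @export
read_image <- function(path, field_of_view_mm, layer = "other",
                       device_label = "", subject_id = NA, eye = NA,
                       acquisition_index = NA) {
  if (!file.exists(path)) stop("cannot read image, file not found: ", path)
  if (!is.numeric(field_of_view_mm) || field_of_view_mm <= 0)
    stop("`field_of_view_mm` must be positive")
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      a <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG: ", path,
                                             " (", conditionMessage(e), ")"))
      # readPNG returns [0,1] regardless of source bit depth -> linear 8-bit
      if (length(dim(a)) == 3L) a <- channel_average(a)
      a * 255
    },
    tif = ,
    tiff = {
      t <- read_tiff_gray(path)
      t$pixels / (2^t$bits - 1) * 255
    },
    stop("unsupported image format '.", ext, "' (PNG or TIFF expected)"))
  if (length(px) == 0L) stop("zero-size image: ", path)
  octa_image(px, pixel_size_um = 1000 * field_of_view_mm / ncol(px),
             layer = layer, device_label = device_label,
             subject_id = subject_id, eye = eye,
             acquisition_index = acquisition_index)
}

channel_average <- function(a) {
  nch <- dim(a)[3]
  if (nch >= 3) (a[, , 1] + a[, , 2] + a[, , 3]) / 3   # ignore alpha
  else a[, , 1]
}

#' Read sparse annotations aligned with an image
#'
#' The annotation raster is a grayscale PNG whose pixel values encode the
#' class labels directly: 0 = unlabeled, 1 = avascular, 2 = vascular.
#'
#' @param path path to the label PNG.
#' @param image the [octa_image] the labels refer to (shape is validated).
#' @param annotation_id identifier stored on the returned set.
#' @return An [annotation_set].
#' @export
read_annotations <- function(path, image, annotation_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read annotations, file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  lab <- round(a * 255)
  check_same_shape(lab, image$pixels, "annotation raster", "image")
  annotation_set(lab, annotation_id = annotation_id)
}

#' @rdname read_annotations
#' @param annotations an [annotation_set] to write.
#' @export
write_annotations <- function(annotations, path) {
  png::writePNG(annotations$label_image / 255, path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks use a fixed PNG dialect: single channel, 0 = background,
#' 255 = foreground. Round-trips are bit-exact.
#'
#' @param mask logical matrix (or 0/1 numeric) to write.
#' @param path file path.
#' @return `read_mask` returns a logical matrix.
#' @export
write_mask <- function(mask, path) {
  m <- as_binary_mask(mask)
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask, file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  a >= 0.5
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) return(mask)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (logical or 0/1)")
  mask == 1
}
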