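#' Extract the avascular core region from a classifier segmentation
#'
#' Post-processes the binary avascular mask into a single region of interest:
#' keeps the largest 8-connected component (components below `min_area_px`
#' are ignored) and fills its interior holes, so vessels crossing the disc do
#' not perforate the core. When two surviving components tie on area, the one
#' whose top-left-most pixel comes first in row-major order wins.
#'
#' @param seg a `segmentation_mask` (or a logical matrix, `TRUE` = avascular).
#' @param min_area_px minimum component area in pixels.
#' @param pixel_size_um micrometres per pixel, for the physical area field.
#' @return An object of class `roi_mask` with role `"avascular_core"`.
#' @export
extract_avascular_region <- function(seg, min_area_px = 50L, pixel_size_um = 1) {
  mask <- if (inherits(seg, "segmentation_mask")) seg$mask else as_binary_mask(seg)
  lab <- .label_components(mask, 8L)
  n_comp <- max(lab)
  if (n_comp == 0) stop("no avascular region found")
  areas <- tabulate(lab[lab > 0], nbins = n_comp)
  eligible <- which(areas >= min_area_px)
  if (length(eligible) == 0) stop("no avascular region found (all ", n_comp,
                                  " components below ", min_area_px, " px)")
  # labels are assigned in row-major anchor order, so which.max's preference
  # for the lowest index is exactly the documented tie-break
  best <- eligible[which.max(areas[eligible])]
  core <- fill_holes(lab == best)
  roi_mask(core, role = "avascular_core", pixel_size_um = pixel_size_um)
}

#' Fill interior holes of a binary mask
#'
#' A hole is a 4-connected background component that does not touch the
#' image border (4-connectivity for the background is the standard dual of
#' 8-connectivity for the foreground).
#'
#' @param mask logical matrix.
#' @return logical matrix with holes set to `TRUE`.
#' @export
fill_holes <- function(mask) {
  mask <- as_binary_mask(mask)
  bg <- .label_components(!mask, 4L)
  if (max(bg) == 0) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Build a peripapillary annulus at a physical band width
#'
#' The annulus is the set of pixels outside the core whose Euclidean distance
#' to the core is at most `band_width_um` (converted to pixels), i.e. the
#' morphological dilation of the core by a Euclidean disc of that radius,
#' minus the core, clipped at the image borders. Computed with an exact
#' Euclidean distance transform, so no structuring element (and no radius
#' rounding) is involved.
#'
#' @param core an `roi_mask` with role `"avascular_core"` (or logical matrix).
#' @param band_width_um band width beyond the core margin, micrometres.
#' @param pixel_size_um micrometres per pixel.
#' @return An `roi_mask` with role `"annulus"` and the band width recorded.
#' @export
build_peripapillary_annulus <- function(core, band_width_um, pixel_size_um) {
  mask <- if (inherits(core, "roi_mask")) core$mask else as_binary_mask(core)
  if (!any(mask)) stop("core mask is empty")
  if (band_width_um <= 0) stop("band width must be positive")
  if (band_width_um < pixel_size_um)
    stop("band width ", band_width_um, " um is below one pixel (",
         pixel_size_um, " um)")
  r_px <- um_to_px(band_width_um, pixel_size_um)
  d2 <- .edt_squared(mask)
  ann <- d2 > 0 & d2 <= r_px^2
  roi_mask(ann, role = "annulus", pixel_size_um = pixel_size_um,
           band_width_um = band_width_um)
}

#' Convert a physical length to pixels
#'
#' Plain ratio, never rounded; discretisation happens only where a mask is
#' thresholded.
#'
#' @param length_um length in micrometres (`>= 0`).
#' @param pixel_size_um micrometres per pixel (`> 0`).
#' @return length in pixel units (real-valued).
#' @export
um_to_px <- function(length_um, pixel_size_um) {
  if (any(length_um < 0)) stop("`length_um` must be non-negative")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  length_um / pixel_size_um
}

#' Region-of-interest mask
#'
#' @param mask logical matrix.
#' @param role `"avascular_core"`, `"annulus"` or `"whole_image"`.
#' @param pixel_size_um micrometres per pixel.
#' @param band_width_um band width (annulus role only).
#' @return An `roi_mask` with `area_px` and `area_um2` fields.
#' @export
roi_mask <- function(mask, role = c("avascular_core", "annulus", "whole_image"),
                     pixel_size_um = 1, band_width_um = NA_real_) {
  mask <- as_binary_mask(mask)
  role <- match.arg(role)
  area_px <- sum(mask)
  structure(list(mask = mask, role = role, band_width_um = band_width_um,
                 area_px = area_px, area_um2 = area_px * pixel_size_um^2,
                 pixel_size_um = pixel_size_um),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask (%s%s): %d px, %.0f um^2\n", x$role,
              if (!is.na(x$band_width_um))
                sprintf(", band %g um", x$band_width_um) else "",
              x$area_px, x$area_um2))
  invisible(x)
}

#' Per-ROI area report
#'
#' @param rois list of `roi_mask` objects.
#' @return data.frame with columns role, band_width_um, area_px, area_um2.
#' @export
roi_area_report <- function(rois) {
  do.call(rbind, lapply(rois, function(r)
    data.frame(role = r$role, band_width_um = r$band_width_um,
               area_px = r$area_px, area_um2 = r$area_um2)))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  check_same_shape(a, b, "mask a", "mask b")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
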