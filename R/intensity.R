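#' Intensity projections, ROI means and normalizations
#'
#' Region-normalized filament-reporter intensity is computed on a 10 um
#' average intensity projection: rectangular ROIs are drawn at the fold
#' constriction (MHBC) and in the adjacent midbrain and hindbrain regions,
#' and the MHBC mean is divided by the mean of the two flanking region
#' means within the same embryo. Apical/middle/basal polarity ratios
#' divide the apical and basal box means by the middle box mean. Western
#' blot densitometry divides a target band by its loading-control band.
#'
#' `average_projection()` averages `round(z_extent / sz)` consecutive z
#' planes starting at `z_start` (um).
#'
#' @param stack an [image_stack()].
#' @param z_extent extent of the projection in um (default 10).
#' @param z_start start of the projected window in um from the first plane.
#' @return an [image2d()] in the xy plane.
#' @export
average_projection <- function(stack, z_extent = 10, z_start = 0) {
  stopifnot(inherits(stack, "fs_stack"))
  sz <- stack$spacing[3]
  nz <- dim(stack$voxels)[3]
  n <- round(z_extent / sz)
  if (n < 1) stopf("z_extent %g um is below one plane (%g um)", z_extent, sz)
  i0 <- floor(z_start / sz) + 1
  if (i0 < 1 || i0 + n - 1 > nz)
    stopf("projection window [%g, %g] um exceeds the stack depth %g um",
          z_start, z_start + z_extent, nz * sz)
  planes <- stack$voxels[, , i0:(i0 + n - 1), drop = FALSE]
  image2d(rowMeans(planes, dims = 2), pixel_spacing = stack$spacing[1:2])
}

#' @rdname average_projection
#'
#' @details
#' `roi_mean()` averages the pixels whose centres fall inside the
#' half-open ROI rectangle.
#'
#' @param image an [image2d()].
#' @param roi an [roi_rect()] in um.
#' @export
roi_mean <- function(image, roi) {
  stopifnot(inherits(image, "fs_image2d"), inherits(roi, "fs_roi"))
  sp <- image$pixel_spacing
  d <- dim(image$pixels)
  if (roi$x < 0 || roi$y < 0 ||
      roi$x + roi$width > d[1] * sp[1] + 1e-9 ||
      roi$y + roi$height > d[2] * sp[2] + 1e-9)
    stopf("ROI [%g,%g)x[%g,%g) um extends outside the %g x %g um image",
          roi$x, roi$x + roi$width, roi$y, roi$y + roi$height,
          d[1] * sp[1], d[2] * sp[2])
  ix <- halfopen_index_range(roi$x, roi$x + roi$width, sp[1])
  iy <- halfopen_index_range(roi$y, roi$y + roi$height, sp[2])
  ix <- ix[ix >= 1 & ix <= d[1]]
  iy <- iy[iy >= 1 & iy <= d[2]]
  if (!length(ix) || !length(iy))
    stopf("ROI contains no pixel centres")
  mean(image$pixels[ix, iy])
}

#' @rdname average_projection
#'
#' @details
#' `normalized_region_intensity()` returns the MHBC ROI mean divided by
#' the average of the midbrain and hindbrain ROI means (the mean of the
#' two region means, not a pooled pixel mean). Overlapping ROIs are
#' computed anyway with a warning.
#'
#' @param roi_mhbc,roi_mid,roi_hind the three region ROIs.
#' @return `normalized_region_intensity()`: a one-row tibble with the
#'   three region means and `normalized_mhbc`.
#' @export
normalized_region_intensity <- function(image, roi_mhbc, roi_mid, roi_hind) {
  rois <- list(roi_mhbc, roi_mid, roi_hind)
  for (i in 1:2) for (j in (i + 1):3)
    if (rois_overlap(rois[[i]], rois[[j]]))
      warning("region ROIs overlap; ratio computed anyway", call. = FALSE)
  m_mhbc <- roi_mean(image, roi_mhbc)
  m_mid <- roi_mean(image, roi_mid)
  m_hind <- roi_mean(image, roi_hind)
  fs_table(tibble::tibble(
    mhbc_mean = m_mhbc, midbrain_mean = m_mid, hindbrain_mean = m_hind,
    normalized_mhbc = m_mhbc / ((m_mid + m_hind) / 2)), "region_intensity")
}

#' @rdname average_projection
#'
#' @details
#' `polarity_ratios()` divides the apical and basal box means by the
#' middle box mean of the same cell region.
#'
#' @param box_apical,box_middle,box_basal the apical/middle/basal boxes.
#' @return `polarity_ratios()`: a one-row tibble with the three means,
#'   `basal_ratio` and `apical_ratio`.
#' @export
polarity_ratios <- function(image, box_apical, box_middle, box_basal) {
  m_ap <- roi_mean(image, box_apical)
  m_mid <- roi_mean(image, box_middle)
  m_ba <- roi_mean(image, box_basal)
  if (m_mid == 0) stopf("middle box mean is zero; ratios undefined")
  fs_table(tibble::tibble(
    apical_mean = m_ap, middle_mean = m_mid, basal_mean = m_ba,
    basal_ratio = m_ba / m_mid, apical_ratio = m_ap / m_mid),
    "polarity")
}

#' Western-blot band normalization
#'
#' Densitometry on pre-integrated band intensities: the target band is
#' divided by the loading-control band of the same lane, and optionally
#' expressed as a percentage of a control lane's normalized level.
#'
#' @param target_band,loading_band integrated band intensities.
#' @param control_value normalized level of the control lane (default 1).
#' @return a one-row tibble with `normalized_level` and
#'   `percent_of_control`.
#' @examples
#' band_normalize(50, 100, control_value = 1)   # 50% of control
#' @export
band_normalize <- function(target_band, loading_band, control_value = 1) {
  if (!is.numeric(loading_band) || loading_band <= 0)
    stopf("loading_band must be > 0")
  lev <- target_band / loading_band
  fs_table(tibble::tibble(
    target_band = target_band, loading_band = loading_band,
    normalized_level = lev,
    percent_of_control = 100 * lev / control_value), "band")
}

rois_overlap <- function(a, b) {
  a$x < b$x + b$width && b$x < a$x + a$width &&
    a$y < b$y + b$height && b$y < a$y + a$height
}

#' Square polarity boxes along a cell axis
#'
#' Convenience constructor for the apical/middle/basal quantification
#' boxes: squares of area `box_area_um2` centred on the cell axis at the
#' given fractional positions between the apical and basal surface.
#'
#' @param x_center x position of the cell axis, um.
#' @param y_apical,y_basal y positions of the apical and basal surface, um.
#' @param box_area_um2 area of each square box (um^2), default 10.
#' @param fractions fractional positions along the axis,
#'   default `c(1/6, 1/2, 5/6)`.
#' @return list of three [roi_rect()]s named apical, middle, basal.
#' @export
polarity_boxes <- function(x_center, y_apical, y_basal,
                           box_area_um2 = 10,
                           fractions = c(1 / 6, 1 / 2, 5 / 6)) {
  side <- sqrt(box_area_um2)
  ys <- y_apical + fractions * (y_basal - y_apical)
  out <- lapply(ys, function(y)
    roi_rect(x_center - side / 2, y - side / 2, side, side))
  names(out) <- c("apical", "middle", "basal")
  out
}
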