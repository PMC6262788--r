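#' Align stacks and extract digital orthogonal slices
#'
#' The shape pipeline mirrors the manual confocal workflow: rotate the
#' z-stack in the xy plane so the apical-basal axis of the cell of interest
#' runs parallel to y, measure the cell length along y, divide it into six
#' equal sections, and cut single-voxel xz slices at the section points
#' immediately inside the apical and basal surfaces (1/6 and 5/6 of the
#' length).
#'
#' `rotate_stack_xy()` rotates every xy plane about its centre by `angle`
#' degrees (positive rotates +x towards +y). Intensity stacks are sampled
#' bilinearly, label volumes nearest-neighbour; z planes are untouched.
#'
#' @param volume an [image_stack()] or [cell_labels()] volume.
#' @param angle rotation angle in degrees.
#' @return an object of the same class as `volume`.
#' @export
rotate_stack_xy <- function(volume, angle) {
  if (!is.numeric(angle) || length(angle) != 1 || !is.finite(angle))
    stopf("angle must be a single finite number of degrees")
  if (inherits(volume, "fs_stack")) {
    v <- volume$voxels
    sp <- volume$spacing
    mp <- rotate_plane_map(dim(v)[1], dim(v)[2], sp[1], sp[2], angle)
    out <- v
    for (k in seq_len(dim(v)[3]))
      out[, , k] <- sample_bilinear(v[, , k], mp$ix, mp$iy, fill = 0)
    image_stack(out, spacing = sp, channel = volume$channel)
  } else if (inherits(volume, "fs_labels")) {
    v <- volume$labels
    sp <- volume$spacing
    mp <- rotate_plane_map(dim(v)[1], dim(v)[2], sp[1], sp[2], angle)
    out <- v
    for (k in seq_len(dim(v)[3]))
      out[, , k] <- sample_nearest(v[, , k], mp$ix, mp$iy, fill = 0L)
    cell_labels(out, spacing = sp)
  } else {
    stopf("volume must be an image stack or a label volume")
  }
}

#' @rdname rotate_stack_xy
#'
#' @details
#' `estimate_alignment_angle()` automates the manual orientation step: it
#' computes the principal axis of the cell's xy projection from second
#' moments and returns the angle (degrees) by which the volume should be
#' rotated with `rotate_stack_xy()` to bring that axis parallel to y. A
#' cell whose projection is isotropic (no principal axis) is an error.
#'
#' @param labels a [cell_labels()] volume.
#' @param cell_id integer label of the cell.
#' @export
estimate_alignment_angle <- function(labels, cell_id) {
  stopifnot(inherits(labels, "fs_labels"))
  idx <- which(labels$labels == cell_id, arr.ind = TRUE)
  if (!nrow(idx)) stopf("cell %s not present in label volume", cell_id)
  sp <- labels$spacing
  x <- px_center(idx[, 1], sp[1])
  y <- px_center(idx[, 2], sp[2])
  cxx <- stats::var(x); cyy <- stats::var(y); cxy <- stats::cov(x, y)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  if ((ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-12) < 0.05)
    stopf("cell %s has an isotropic xy projection; no principal axis", cell_id)
  v <- ev$vectors[, 1]
  # angle of the principal axis measured from +y towards +x, in (-90, 90]
  psi <- atan2(v[1], v[2]) * 180 / pi
  if (psi > 90) psi <- psi - 180
  if (psi <= -90) psi <- psi + 180
  # rotating by +psi moves the axis onto y (rotation is +x towards +y)
  psi
}

#' @rdname rotate_stack_xy
#'
#' @details
#' `cell_length_y()` measures the apical-basal length of an aligned cell
#' as `(max y index - min y index + 1) * sy` over the cell's voxels, in um.
#'
#' @export
cell_length_y <- function(labels, cell_id) {
  stopifnot(inherits(labels, "fs_labels"))
  hit <- which(apply(labels$labels == cell_id, 2, any))
  if (!length(hit)) stopf("cell %s not present in label volume", cell_id)
  (max(hit) - min(hit) + 1) * labels$spacing[2]
}

#' Apical and basal slice positions from cell length
#'
#' The cell length is divided into six equal sections; slices are taken at
#' the section point immediately below the apical surface (1/6 of the
#' length) and immediately above the basal surface (5/6). For the 30-42 um
#' cells typical of the folding neuroepithelium this puts the slices about
#' 5-7 um into the cell from either surface.
#'
#' @param cell_length cell length in um.
#' @return named numeric `c(apical =, basal =)`: offsets in um from the
#'   apical surface.
#' @examples
#' slice_positions(36)
#' @export
slice_positions <- function(cell_length) {
  if (!is.numeric(cell_length) || length(cell_length) != 1 ||
      !is.finite(cell_length) || cell_length <= 0)
    stopf("cell_length must be a single positive length in um")
  c(apical = cell_length / 6, basal = 5 * cell_length / 6)
}

#' Extract a digital xz slice at an apical-basal position
#'
#' Cuts the xz plane at the voxel row whose centre is nearest to `y` (um).
#' With `average_um > 0` the slice is the mean over the rows whose centres
#' fall within `y +/- average_um / 2` (intensity stacks only).
#'
#' @param volume an [image_stack()] or [cell_labels()] volume, aligned so
#'   the apical-basal axis is parallel to y.
#' @param y apical-basal position of the slice in um.
#' @param average_um y-averaging window in um; 0 takes a single voxel plane.
#' @return an [xz_slice()]; for label input its `pixels` are integer labels.
#' @export
extract_xz_slice <- function(volume, y, average_um = 0) {
  is_lab <- inherits(volume, "fs_labels")
  if (!is_lab && !inherits(volume, "fs_stack"))
    stopf("volume must be an image stack or a label volume")
  v <- if (is_lab) volume$labels else volume$voxels
  sp <- volume$spacing
  ny <- dim(v)[2]
  if (!is.numeric(y) || length(y) != 1 || !is.finite(y) ||
      y < 0 || y > ny * sp[2])
    stopf("slice position y = %s um is outside the stack extent [0, %g] um",
          format(y), ny * sp[2])
  if (is_lab || average_um <= 0) {
    j <- nearest_index(y, sp[2], ny)
    px <- v[, j, ]
  } else {
    js <- halfopen_index_range(y - average_um / 2, y + average_um / 2, sp[2])
    js <- js[js >= 1 & js <= ny]
    if (!length(js)) js <- nearest_index(y, sp[2], ny)
    px <- apply(v[, js, , drop = FALSE], c(1, 3), mean)
  }
  if (!is.matrix(px)) px <- matrix(px, nrow = dim(v)[1])
  xz_slice(px, spacing = sp[c(1, 3)], y_position = y)
}

#' Per-cell masks present in a label slice
#'
#' @param slice an [xz_slice()] cut from a label volume.
#' @param cells optional integer vector restricting which labels to return.
#' @return named list of logical matrices (one per label present at that
#'   y position); labels absent from the slice are omitted.
#' @export
slice_masks <- function(slice, cells = NULL) {
  stopifnot(inherits(slice, "fs_slice"))
  ids <- sort(setdiff(unique(as.vector(slice$pixels)), 0))
  if (!is.null(cells)) ids <- intersect(ids, cells)
  out <- lapply(ids, function(id) slice$pixels == id)
  names(out) <- as.character(ids)
  out
}
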