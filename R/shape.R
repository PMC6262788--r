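#' Anisotropic cell shape metrics on an xz mask
#'
#' The anisotropy of a neuroepithelial cell is quantified on its xz
#' cross-section by three measurements: cell area, the maximal depth chord
#' (the longest straight segment lying inside the mask whose direction is
#' within 45 degrees of the z-axis, inclusive), and the maximal width
#' perpendicular to that depth chord. The x:z ratio is width divided by
#' depth; a ratio different from 1 marks an anisotropic (polarized) cross
#' section.
#'
#' `mask_area()` is pixel count times pixel area.
#'
#' @param mask logical matrix indexed `[x, z]`.
#' @param spacing um per pixel along (x, z).
#' @return `mask_area()`: area in um^2.
#' @export
mask_area <- function(mask, spacing) {
  check_mask(mask)
  check_spacing(spacing, 2L)
  sum(mask) * spacing[1] * spacing[2]
}

#' @rdname mask_area
#'
#' @details
#' Chords are searched exhaustively over pairs of boundary pixels; a
#' candidate segment must stay inside the mask over every pixel cell its
#' closed supercover rasterization touches (grazing a cell corner counts).
#' Chord length and angle are physical, so anisotropic pixel spacing is
#' respected. Ties in length are broken by the chord closer to the target
#' direction, then by smaller endpoint coordinates.
#'
#' @param max_angle maximal angle (degrees) of the depth chord from the
#'   z-axis; the bound is inclusive.
#' @return `max_depth_chord()`: a list with `depth_um`, `angle_deg`
#'   (absolute angle from z, in `[0, max_angle]`), `angle_signed_deg`, and
#'   the 1-based pixel endpoints `x1, z1, x2, z2`.
#' @export
max_depth_chord <- function(mask, spacing, max_angle = 45) {
  check_mask(mask)
  check_spacing(spacing, 2L)
  res <- .chord_best_cpp(mask, spacing[1], spacing[2], 0, max_angle)
  if (!res$found)
    stopf("no admissible depth chord within %g degrees of the z-axis", max_angle)
  list(depth_um = res$length_um, angle_deg = abs(res$angle_deg),
       angle_signed_deg = res$angle_deg,
       x1 = res$x1, z1 = res$z1, x2 = res$x2, z2 = res$z2)
}

#' @rdname mask_area
#'
#' @details
#' `max_width_perpendicular()` finds the longest in-mask chord
#' perpendicular to the realized depth chord (the two coincide with the
#' x-axis when the depth chord is z-aligned). On a pixel grid exact
#' perpendicularity is only available at special angles, so chords within
#' `angle_tol` degrees of the perpendicular are admitted; if none exists
#' the tolerance is doubled until a chord is found.
#'
#' @param depth_angle signed angle (degrees from the z-axis) of the depth
#'   chord, as returned in `angle_signed_deg`.
#' @param angle_tol angular tolerance in degrees.
#' @return `max_width_perpendicular()`: width in um.
#' @export
max_width_perpendicular <- function(mask, spacing, depth_angle,
                                    angle_tol = 3) {
  check_mask(mask)
  check_spacing(spacing, 2L)
  target <- wrap180(depth_angle + 90)
  tol <- angle_tol
  repeat {
    res <- .chord_best_cpp(mask, spacing[1], spacing[2], target, tol)
    if (res$found) return(res$length_um)
    if (tol >= 90) stopf("no admissible width chord found")
    tol <- min(2 * tol, 90)
  }
}

#' @rdname mask_area
#'
#' @param width_x,depth_z width and depth in um.
#' @param tolerance |ratio - 1| above which the shape is called anisotropic.
#' @return `xz_ratio()`: a list with `ratio` and logical `is_anisotropic`.
#' @export
xz_ratio <- function(width_x, depth_z, tolerance = 0.05) {
  if (!is.numeric(depth_z) || depth_z <= 0)
    stopf("depth_z must be > 0")
  r <- width_x / depth_z
  list(ratio = r, is_anisotropic = abs(r - 1) > tolerance)
}

#' Measure apical/basal cell shape from an aligned stack
#'
#' Runs the full orthogonal-slice protocol for one cell of an aligned
#' volume: measure cell length along y, place the apical and basal slice
#' positions at the one-sixth section points, extract the xz label slice at
#' each position, and compute area, depth chord, perpendicular width and
#' x:z ratio on the cell's mask.
#'
#' @param labels an aligned [cell_labels()] volume.
#' @param cell_id cell to measure.
#' @param surface `"apical"`, `"basal"` or `"both"`.
#' @param config a [foldshape_config()].
#' @return a tibble with one row per surface: `cell_id`, `surface`,
#'   `y_position_um`, `area_um2`, `depth_um`, `depth_angle_deg`,
#'   `width_um`, `xz_ratio`, `anisotropic`.
#' @export
measure_cell_shape <- function(labels, cell_id,
                               surface = c("both", "apical", "basal"),
                               config = foldshape_config()) {
  stopifnot(inherits(labels, "fs_labels"))
  surface <- match.arg(surface)
  cfg <- config
  hit <- which(apply(labels$labels == cell_id, 2, any))
  if (!length(hit)) stopf("cell %s not present in label volume", cell_id)
  sy <- labels$spacing[2]
  len <- (max(hit) - min(hit) + 1) * sy
  y0 <- (min(hit) - 1) * sy                      # apical surface (min y end)
  fr <- cfg$slice_fractions
  if (!isTRUE(cfg$apical_min_y)) fr <- rev(1 - fr)
  pos <- c(apical = y0 + fr[1] * len, basal = y0 + fr[2] * len)
  wanted <- if (surface == "both") c("apical", "basal") else surface
  rows <- lapply(wanted, function(sf) {
    sl <- extract_xz_slice(labels, pos[[sf]])
    mask <- sl$pixels == cell_id
    if (!any(mask))
      stopf("slice extraction: cell %s absent at the %s slice (y = %.2f um)",
            cell_id, sf, pos[[sf]])
    measure_mask_row(mask, sl$spacing, cfg, cell_id, sf, pos[[sf]])
  })
  fs_table(dplyr::bind_rows(rows), "shape")
}

# area/depth/width/ratio on one mask -> one tibble row
measure_mask_row <- function(mask, spacing, cfg, cell_id, surface, y_pos) {
  area <- mask_area(mask, spacing)
  dep <- max_depth_chord(mask, spacing, max_angle = cfg$depth_max_angle)
  wid <- if (cfg$width_mode == "x_axis") {
    max_width_perpendicular(mask, spacing, 0, angle_tol = cfg$width_angle_tol)
  } else {
    max_width_perpendicular(mask, spacing, dep$angle_signed_deg,
                            angle_tol = cfg$width_angle_tol)
  }
  rat <- xz_ratio(wid, dep$depth_um, tolerance = cfg$anisotropy_tol)
  tibble::tibble(cell_id = cell_id, surface = surface,
                 y_position_um = y_pos, area_um2 = area,
                 depth_um = dep$depth_um, depth_angle_deg = dep$angle_deg,
                 width_um = wid, xz_ratio = rat$ratio,
                 anisotropic = rat$is_anisotropic)
}

#' Measure every cell of a label volume, aligning each cell first
#'
#' For each cell the alignment angle is estimated from its xy projection;
#' cells with similar angles (rounded to 1 degree) share one rotation of a
#' cropped sub-volume, after which the orthogonal-slice protocol of
#' [measure_cell_shape()] runs per cell.
#'
#' @param labels a [cell_labels()] volume (unaligned).
#' @param cells integer vector of cells to measure; default all.
#' @param config a [foldshape_config()].
#' @return a tibble with two rows (apical, basal) per cell.
#' @export
measure_cells <- function(labels, cells = NULL,
                          config = foldshape_config()) {
  stopifnot(inherits(labels, "fs_labels"))
  if (is.null(cells)) cells <- label_ids(labels)
  angles <- vapply(cells, function(id)
    estimate_alignment_angle(labels, id), numeric(1))
  key <- round(angles)
  rows <- list()
  for (a in unique(key)) {
    ids <- cells[key == a]
    for (id in ids) {
      sub <- crop_cell(labels, id)
      subr <- rotate_stack_xy(sub, angles[match(id, cells)])
      rows[[length(rows) + 1L]] <-
        measure_cell_shape(subr, id, "both", config)
    }
  }
  fs_table(dplyr::bind_rows(rows), "shape")
}

# crop a label volume to one cell plus a rotation-safe square margin in xy
crop_cell <- function(labels, cell_id) {
  idx <- which(labels$labels == cell_id, arr.ind = TRUE)
  if (!nrow(idx)) stopf("cell %s not present in label volume", cell_id)
  sp <- labels$spacing
  d <- dim(labels$labels)
  rx <- range(idx[, 1]); ry <- range(idx[, 2])
  # half-diagonal of the xy bounding box, so any rotation stays inside
  half <- ceiling(sqrt(((diff(rx) + 1) * sp[1])^2 +
                       ((diff(ry) + 1) * sp[2])^2) / 2)
  cx <- mean(rx); cy <- mean(ry)
  xs <- max(1, floor(cx - half / sp[1] - 1)):min(d[1], ceiling(cx + half / sp[1] + 1))
  ys <- max(1, floor(cy - half / sp[2] - 1)):min(d[2], ceiling(cy + half / sp[2] + 1))
  sub <- labels$labels[xs, ys, , drop = FALSE]
  sub[sub != cell_id] <- 0L
  cell_labels(sub, spacing = sp)
}

#' Tissue fold angle from basal surface points
#'
#' Fits a total-least-squares line to the basal surface points on each
#' side of the fold vertex (points within `fit_span` um of the vertex) and
#' returns the interior angle between the two fitted directions, in
#' (0, 180] degrees. Collinear surfaces give 180 degrees.
#'
#' @param points data frame with columns `x_um`, `y_um`, ordered along the
#'   basal surface.
#' @param vertex_index row index of the vertex point.
#' @param fit_span span in um on each side of the vertex used for the fits.
#' @return a tibble with `vertex_x_um`, `vertex_y_um`, `angle_deg`,
#'   `n_left`, `n_right`.
#' @export
measure_mhb_angle <- function(points, vertex_index, fit_span = 20) {
  stopifnot(is.data.frame(points), all(c("x_um", "y_um") %in% names(points)))
  n <- nrow(points)
  if (vertex_index < 1 || vertex_index > n) stopf("vertex_index out of range")
  vx <- points$x_um[vertex_index]; vy <- points$y_um[vertex_index]
  d <- sqrt((points$x_um - vx)^2 + (points$y_um - vy)^2)
  near <- d <= fit_span
  left <- which(near & seq_len(n) <= vertex_index)
  right <- which(near & seq_len(n) >= vertex_index)
  if (length(left) < 3 || length(right) < 3)
    stopf("need at least 3 basal points within %g um on each side of the vertex",
          fit_span)
  dir_left <- tls_direction(points$x_um[left], points$y_um[left], vx, vy)
  dir_right <- tls_direction(points$x_um[right], points$y_um[right], vx, vy)
  ang <- acos(pmin(1, pmax(-1, sum(dir_left * dir_right)))) * 180 / pi
  if (ang <= 0) ang <- 180
  fs_table(tibble::tibble(vertex_x_um = vx, vertex_y_um = vy,
                          angle_deg = ang,
                          n_left = length(left), n_right = length(right)),
           "mhb_angle")
}

# principal direction of a point cloud, oriented away from the vertex
tls_direction <- function(x, y, vx, vy) {
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2); cyy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v * c(mx - vx, my - vy)) < 0) v <- -v
  v
}

check_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stopf("mask must be a logical matrix")
  if (!any(mask)) stopf("empty mask")
  invisible(mask)
}

wrap180 <- function(a) {
  a <- ((a + 90) %% 180) - 90
  if (a <= -90) a <- a + 180
  a
}
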