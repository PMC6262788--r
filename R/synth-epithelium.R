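#' Parameters for the synthetic folded epithelium
#'
#' The generator emulates the tissue the shape pipeline is built for: a
#' single-layer pseudostratified neuroepithelium folded basally at a
#' vertex (the fold constriction), imaged dorsally. Two sheets of columnar
#' cells meet at the vertex; the basal surface forms a V with interior
#' angle `fold_angle` (180 gives a flat sheet). Cell axes fan gently
#' around the fold (they converge towards a focal point below the basal
#' vertex at distance `focal_depth`), so cells near the vertex are nearly
#' vertical and cells further out tilt progressively in the xy plane - the
#' alignment step of the pipeline has real work to do. Each cell is a
#' prism along its apical-basal axis whose xz cross-section is an ellipse:
#' depth (z) is constant, width (x) interpolates linearly along the axis
#' such that the cross-sections at the 1/6 and 5/6 measurement planes have
#' exactly the requested apical and basal x:z ratios.
#'
#' @param n_cells_per_side cells in each sheet (default 6).
#' @param cell_length apical-basal cell length, um (default 36).
#' @param apical_xz_ratio x:z ratio at the apical (1/6) plane (default 0.7).
#' @param basal_xz_ratio x:z ratio at the basal (5/6) plane (default 0.5).
#' @param cell_depth_z cell depth along z, um (default 12).
#' @param fold_angle interior basal angle in degrees, in (0, 180]
#'   (default 90).
#' @param cell_gap gap between neighbouring cell ellipses, um (default 1).
#' @param focal_depth distance below the basal vertex of the fan focal
#'   point, um (default 3 cell lengths).
#' @param membrane_thickness membrane shell thickness, um (default 0.4).
#' @param psf_sigma Gaussian point-spread sigma, um (default 0.3).
#' @param noise_sd additive Gaussian noise sd on the unit-peak membrane
#'   channel (default 0.1, i.e. peak SNR 10).
#' @param spacing voxel spacing (x, y, z) um (default 0.2 x 0.2 x 0.5).
#' @param seed integer seed.
#' @return a validated parameter list of class `fs_epithelium_params`.
#' @export
epithelium_params <- function(n_cells_per_side = 6, cell_length = 36,
                              apical_xz_ratio = 0.7, basal_xz_ratio = 0.5,
                              cell_depth_z = 12, fold_angle = 90,
                              cell_gap = 1, focal_depth = 3 * cell_length,
                              membrane_thickness = 0.4, psf_sigma = 0.3,
                              noise_sd = 0.1, spacing = c(0.2, 0.2, 0.5),
                              seed = 1L) {
  p <- list(n_cells_per_side = as.integer(n_cells_per_side),
            cell_length = cell_length, apical_xz_ratio = apical_xz_ratio,
            basal_xz_ratio = basal_xz_ratio, cell_depth_z = cell_depth_z,
            fold_angle = fold_angle, cell_gap = cell_gap,
            focal_depth = focal_depth,
            membrane_thickness = membrane_thickness, psf_sigma = psf_sigma,
            noise_sd = noise_sd, spacing = spacing, seed = as.integer(seed))
  if (p$n_cells_per_side < 1) stopf("n_cells_per_side must be >= 1")
  for (key in c("cell_length", "apical_xz_ratio", "basal_xz_ratio",
                "cell_depth_z", "cell_gap", "focal_depth"))
    if (!is.numeric(p[[key]]) || p[[key]] <= 0)
      stopf("epithelium parameter '%s' must be > 0", key)
  if (p$fold_angle <= 0 || p$fold_angle > 180)
    stopf("fold_angle must be in (0, 180] degrees")
  if (p$membrane_thickness <= 0) stopf("membrane_thickness must be > 0")
  if (p$psf_sigma < 0 || p$noise_sd < 0)
    stopf("psf_sigma and noise_sd must be >= 0")
  check_spacing(p$spacing, 3L)
  structure(p, class = "fs_epithelium_params")
}

#' Generate a folded epithelium stack with ground truth
#'
#' Builds the cell geometry of [epithelium_params()], voxelizes it into a
#' label volume, renders a membrane channel (the label-boundary shell
#' blurred with a Gaussian PSF, peak-normalized to 1, plus Gaussian
#' noise), and tabulates the constructed ground truth per cell.
#'
#' @param params an [epithelium_params()] list.
#' @return a list with elements
#'   \describe{
#'     \item{stack}{membrane-channel [image_stack()]}
#'     \item{labels}{[cell_labels()] ground-truth segmentation}
#'     \item{truth}{tibble of per-cell constructed geometry: tilt, widths
#'       and ratios at the apical/basal measurement planes, depth, length}
#'     \item{basal_surface}{tibble of basal surface points (um) ordered
#'       along the surface, with the vertex row index in
#'       `attr(, "vertex_index")`}
#'   }
#' @export
generate_epithelium_stack <- function(params = epithelium_params()) {
  stopifnot(inherits(params, "fs_epithelium_params"))
  p <- params
  geo <- epithelium_geometry(p)
  sp <- p$spacing
  ext <- geo$extent
  d <- pmax(c(ceiling(ext$x / sp[1]), ceiling(ext$y / sp[2]),
              ceiling(ext$z / sp[3])), 3L)
  lab <- array(0L, d)
  xs <- px_center(seq_len(d[1]), sp[1])
  ys <- px_center(seq_len(d[2]), sp[2])
  zs <- px_center(seq_len(d[3]), sp[3])
  half_d <- p$cell_depth_z / 2
  for (i in seq_len(nrow(geo$cells))) {
    cl <- geo$cells[i, ]
    # bounding box of the cell in um, padded by the largest half width
    pad <- max(cl$half_w_end0, cl$half_w_end1) + 1
    bx <- range(c(cl$ax, cl$bx)) + c(-pad, pad)
    by <- range(c(cl$ay, cl$by)) + c(-pad, pad)
    ix <- which(xs >= bx[1] & xs <= bx[2])
    iy <- which(ys >= by[1] & ys <= by[2])
    iz <- which(abs(zs - geo$z_center) <= half_d + sp[3])
    if (!length(ix) || !length(iy) || !length(iz))
      stopf("cell %d leaves the volume; adjust n_cells_per_side or fold_angle", i)
    X <- matrix(xs[ix], length(ix), length(iy))
    Y <- matrix(ys[iy], length(ix), length(iy), byrow = TRUE)
    # axial coordinate s in [0, L] from apical end, lateral offset q
    ux <- (cl$bx - cl$ax) / p$cell_length
    uy <- (cl$by - cl$ay) / p$cell_length
    S <- (X - cl$ax) * ux + (Y - cl$ay) * uy
    Q <- -(X - cl$ax) * uy + (Y - cl$ay) * ux
    inside_ax <- S >= 0 & S <= p$cell_length
    # half width interpolates linearly in s (calibrated at 1/6 and 5/6)
    HW <- cl$half_w_end0 + (cl$half_w_end1 - cl$half_w_end0) *
      (S / p$cell_length)
    for (k in iz) {
      rz <- (zs[k] - geo$z_center) / half_d
      if (abs(rz) > 1) next
      ok <- inside_ax & (Q / HW)^2 + rz^2 <= 1
      if (!any(ok)) next
      plane <- lab[ix, iy, k]
      if (any(plane[ok] != 0L))
        stopf("cells %d and %d overlap; increase cell_gap or fold_angle",
              unique(plane[ok][plane[ok] != 0])[1], i)
      plane[ok] <- i
      lab[ix, iy, k] <- plane
    }
  }
  labels <- cell_labels(lab, spacing = sp)
  membrane <- render_membrane(lab, p)
  stack <- image_stack(membrane, spacing = sp, channel = "membrane")
  list(stack = stack, labels = labels, truth = geo$truth,
       basal_surface = geo$basal_surface)
}

# cell axes, endpoints and ground truth for the folded sheet geometry
epithelium_geometry <- function(p) {
  half <- p$fold_angle / 2 * pi / 180      # limb angle from the y axis
  L <- p$cell_length
  D <- p$cell_depth_z
  # width profile: linear in s with the requested ratios met at the
  # 1/6 and 5/6 measurement planes
  r16 <- p$apical_xz_ratio
  r56 <- p$basal_xz_ratio
  slope <- (r56 - r16) / (4 / 6)
  ratio_at <- function(f) r16 + slope * (f - 1 / 6)
  r0 <- ratio_at(0); r1 <- ratio_at(1)
  if (r0 <= 0 || r1 <= 0)
    stopf("apical/basal ratio combination gives a non-positive end width")
  w_max <- D * max(r0, r1)
  pitch <- w_max + p$cell_gap
  n <- p$n_cells_per_side
  # limb directions (away from the vertex, up = -y) and fan focal point
  limb <- list(R = c(sin(half), -cos(half)), L = c(-sin(half), -cos(half)))
  cells <- list()
  basal_pts <- list()
  for (side in c("L", "R")) {
    u <- limb[[side]]
    d_i <- numeric(n)
    # first cell: clear of the vertex AND of its mirror image on the
    # other sheet (basal centres 2 d sin(fold/2) apart must exceed pitch)
    d_cur <- max(0.6 * pitch, pitch / (2 * sin(half)) + 0.1 * pitch)
    for (i in seq_len(n)) {
      d_i[i] <- d_cur
      # next basal point: perpendicular separation >= pitch from this axis
      bx <- u[1] * d_cur; by <- u[2] * d_cur           # vertex at origin
      ax_dir <- fan_axis(bx, by, p$focal_depth)
      sep <- abs(u[1] * -ax_dir[2] + u[2] * ax_dir[1]) # |u x axis|
      d_cur <- d_cur + pitch / max(sep, 0.2)
    }
    for (i in seq_len(n)) {
      bx <- u[1] * d_i[i]; by <- u[2] * d_i[i]
      a <- fan_axis(bx, by, p$focal_depth)             # apical->basal unit
      cells[[length(cells) + 1L]] <- tibble::tibble(
        side = side, order = i,
        ax = bx - L * a[1], ay = by - L * a[2],        # apical end
        bx = bx, by = by,                              # basal end
        tilt_deg = atan2(a[1], a[2]) * 180 / pi,
        half_w_end0 = D * r0 / 2, half_w_end1 = D * r1 / 2)
      basal_pts[[length(basal_pts) + 1L]] <- tibble::tibble(
        side = side, order = i, x = bx, y = by)
    }
  }
  cells <- dplyr::bind_rows(cells)
  basal <- dplyr::bind_rows(basal_pts)
  # shift into a positive um frame with a margin
  margin <- 4
  xmin <- min(cells$ax - w_max, cells$bx - w_max) - margin
  ymin <- min(cells$ay, cells$by) - margin
  cells$ax <- cells$ax - xmin; cells$bx <- cells$bx - xmin
  cells$ay <- cells$ay - ymin; cells$by <- cells$by - ymin
  basal$x <- basal$x - xmin; basal$y <- basal$y - ymin
  vx <- -xmin; vy <- -ymin                              # vertex position
  xmax <- max(cells$ax + w_max, cells$bx + w_max) + margin
  ymax <- max(cells$ay, cells$by, vy) + margin
  z_ext <- D + 4
  cells$cell_id <- seq_len(nrow(cells))
  truth <- tibble::tibble(
    cell_id = cells$cell_id, side = cells$side, order = cells$order,
    tilt_deg = cells$tilt_deg,
    length_um = L, depth_um = D,
    apical_width_um = D * r16, basal_width_um = D * r56,
    apical_ratio = r16, basal_ratio = r56)
  # basal surface: the two limbs sampled densely (2 um steps) from the far
  # left end through the vertex to the far right end
  d_max <- max(sqrt((basal$x - vx)^2 + (basal$y - vy)^2))
  ds <- seq(2, d_max, by = 2)
  surf <- tibble::tibble(
    x_um = c(vx + rev(ds) * limb$L[1], vx, vx + ds * limb$R[1]),
    y_um = c(vy + rev(ds) * limb$L[2], vy, vy + ds * limb$R[2]))
  attr(surf, "vertex_index") <- length(ds) + 1L
  list(cells = cells, truth = fs_table(truth, "epithelium_truth"),
       basal_surface = surf,
       z_center = z_ext / 2,
       extent = list(x = xmax, y = ymax, z = z_ext),
       vertex = c(vx, vy))
}

# unit apical->basal axis direction of the cell whose basal point is
# (bx, by) (vertex frame): the ray from the focal point below the vertex
fan_axis <- function(bx, by, focal_depth) {
  f <- c(0, focal_depth)       # focal point, +y is basal-ward
  v <- c(bx, by) - f
  v <- v / sqrt(sum(v^2))
  -v                            # apical->basal points towards +y
}

# membrane channel: 6-neighbour boundary shell of the labels, thickened to
# membrane_thickness, blurred with the PSF, peak-normalized, plus noise
render_membrane <- function(lab, p) {
  shell <- label_boundary(lab)
  steps <- max(0L, round(p$membrane_thickness / (2 * min(p$spacing))) - 1L)
  if (steps > 0) {
    interior <- lab > 0 & !shell
    for (s in seq_len(steps)) {
      shell <- shell | (label_boundary((lab > 0 & !shell) * 1L) & interior)
    }
  }
  m <- shell * 1
  m <- gauss_blur3(m, p$psf_sigma, p$spacing)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  if (p$noise_sd > 0) {
    withr::local_seed(p$seed)
    m <- m + stats::rnorm(length(m), 0, p$noise_sd)
    dim(m) <- dim(lab)
  }
  m
}

# voxels whose 6-neighbourhood contains a different value (or the edge)
label_boundary <- function(lab) {
  d <- dim(lab)
  b <- array(FALSE, d)
  shift_ne <- function(ax, by) {
    out <- array(TRUE, d)   # edge counts as different
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq_len(d[ax] - by) + by
                  idx_src[[ax]] <- seq_len(d[ax] - by) }
    else        { idx_dst[[ax]] <- seq_len(d[ax] + by)
                  idx_src[[ax]] <- seq_len(d[ax] + by) - by }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      lab[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] !=
      lab[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) b <- b | shift_ne(ax, by)
  b & (lab > 0)
}
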