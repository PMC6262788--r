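#' Image and annotation containers
#'
#' `foldshape` works in the axis convention of dorsally imaged neural-tube
#' stacks: x is anterior-posterior (width), y is apical-basal (cell length,
#' apical at small y), z is dorsal-ventral (depth). In memory a stack is a
#' numeric 3D array indexed `[x, y, z]`; on disk it is a multi-page TIFF
#' whose pages are z planes with rows = y and columns = x. Voxel indices are
#' 0-based in all physical formulas; the centre of voxel `i` along an axis
#' with spacing `s` um sits at `(i + 0.5) * s` um. Rectangular ROIs are
#' half-open in um: a pixel belongs to the ROI when its centre falls in
#' `[origin, origin + size)`.
#'
#' @param voxels numeric 3D array indexed `[x, y, z]`.
#' @param spacing numeric length-3, um per voxel along (x, y, z).
#' @param channel optional channel name.
#' @return `image_stack()` returns an object of class `"fs_stack"`:
#'   a list with elements `voxels`, `spacing` and `channel`.
#' @examples
#' s <- image_stack(array(runif(24), c(4, 3, 2)), spacing = c(0.2, 0.2, 0.5))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing = c(0.2, 0.2, 0.5), channel = "") {
  voxels <- as_array3d(voxels)
  check_spacing(spacing, 3L)
  if (!all(is.finite(voxels))) stop("stack intensities must be finite")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 channel = as.character(channel)[1]),
            class = "fs_stack")
}

#' @rdname image_stack
#' @param labels integer 3D array, 0 = background, positive integers = cells.
#' @return `cell_labels()` returns an object of class `"fs_labels"`.
#' @export
cell_labels <- function(labels, spacing = c(0.2, 0.2, 0.5)) {
  labels <- as_array3d(labels)
  check_spacing(spacing, 3L)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = as.numeric(spacing)),
            class = "fs_labels")
}

#' @rdname image_stack
#' @param frames numeric 3D array indexed `[x, y, t]`, one plane per frame.
#' @param pixel_spacing um per pixel along (x, y).
#' @param frame_interval seconds between frames.
#' @return `time_lapse()` returns an object of class `"fs_movie"`.
#' @export
time_lapse <- function(frames, pixel_spacing = c(0.2, 0.2),
                       frame_interval = 4) {
  frames <- as_array3d(frames)
  check_spacing(pixel_spacing, 2L)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a single positive number of seconds")
  if (!all(is.finite(frames))) stop("frame intensities must be finite")
  structure(list(frames = frames, pixel_spacing = as.numeric(pixel_spacing),
                 frame_interval = frame_interval),
            class = "fs_movie")
}

#' @rdname image_stack
#' @param pixels numeric matrix indexed `[x, y]` (or `[x, z]` for xz slices).
#' @export
image2d <- function(pixels, pixel_spacing = c(0.2, 0.2)) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  check_spacing(pixel_spacing, 2L)
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing)),
            class = "fs_image2d")
}

#' @rdname image_stack
#' @param x,y origin of the rectangle in um.
#' @param width,height extent in um; the rectangle is `[x, x+width) x
#'   [y, y+height)`.
#' @export
roi_rect <- function(x, y, width, height) {
  v <- c(x = x, y = y, width = width, height = height)
  if (!all(is.finite(v))) stop("ROI coordinates must be finite")
  if (width <= 0 || height <= 0) stop("ROI width and height must be > 0")
  structure(as.list(v), class = "fs_roi")
}

#' A digital orthogonal xz slice
#'
#' The xz-plane image extracted from an aligned stack at a fixed
#' apical-basal (y) position; `pixels` is indexed `[x, z]`.
#'
#' @param pixels matrix indexed `[x, z]`.
#' @param spacing um per pixel along (x, z).
#' @param y_position apical-basal position of the slice, um.
#' @export
xz_slice <- function(pixels, spacing, y_position) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  check_spacing(spacing, 2L)
  structure(list(pixels = pixels, spacing = as.numeric(spacing),
                 y_position = as.numeric(y_position)),
            class = "fs_slice")
}

#' @export
print.fs_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<fs_stack> %d x %d x %d voxels (x,y,z), spacing %s um%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x "),
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' @export
print.fs_labels <- function(x, ...) {
  d <- dim(x$labels)
  ids <- setdiff(unique(as.vector(x$labels)), 0L)
  cat(sprintf("<fs_labels> %d x %d x %d voxels, %d cells\n",
              d[1], d[2], d[3], length(ids)))
  invisible(x)
}

#' @export
print.fs_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fs_movie> %d frames of %d x %d px, %.3g s/frame, %s um/px\n",
              d[3], d[1], d[2], x$frame_interval,
              paste(signif(x$pixel_spacing, 3), collapse = " x ")))
  invisible(x)
}

#' @export
print.fs_roi <- function(x, ...) {
  cat(sprintf("<fs_roi> [%g, %g) x [%g, %g) um\n",
              x$x, x$x + x$width, x$y, x$y + x$height))
  invisible(x)
}

#' Cell ids present in a label volume
#' @param labels an `fs_labels` volume.
#' @return sorted integer vector of nonzero labels.
#' @export
label_ids <- function(labels) {
  stopifnot(inherits(labels, "fs_labels"))
  sort(setdiff(unique(as.vector(labels$labels)), 0L))
}

# --- internal validation helpers ------------------------------------------

as_array3d <- function(a) {
  if (is.matrix(a)) dim(a) <- c(dim(a), 1L)
  if (!is.array(a) || length(dim(a)) != 3)
    stop("expected 3 dimensions")
  if (any(dim(a) < 1)) stop("all dimensions must be >= 1")
  a
}

check_spacing <- function(spacing, n) {
  if (!is.numeric(spacing) || length(spacing) != n ||
      !all(is.finite(spacing)) || any(spacing <= 0))
    stop(sprintf("spacing must be %d positive finite numbers (um)", n))
  invisible(spacing)
}

# physical centre (um) of 1-based index i along an axis with spacing s
px_center <- function(i, s) (i - 0.5) * s

# 1-based index of the voxel whose centre is nearest to position u (um)
nearest_index <- function(u, s, n) {
  i <- floor(u / s) + 1L
  pmin(pmax(i, 1L), n)
}

# 1-based index range of pixels whose centres fall in the half-open
# um interval [a, b); integer(0) if empty
halfopen_index_range <- function(a, b, s) {
  # centre (i - 0.5) s in [a, b)  <=>  a/s + 0.5 <= i < b/s + 0.5
  lo <- as.integer(ceiling(a / s + 0.5 - 1e-9))
  hi <- as.integer(ceiling(b / s + 0.5 - 1e-9)) - 1L
  if (hi < lo) integer(0) else seq.int(lo, hi)
}
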