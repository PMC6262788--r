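#' Read and write image stacks, label volumes and time-lapse movies
#'
#' Stacks are stored as multi-page TIFF (one page per z plane, rows = y,
#' columns = x, i.e. the usual planes-rows-columns layout) with a plain-text
#' YAML sidecar `<path>.meta.yaml` holding the voxel spacing and, for
#' movies, the frame interval. Intensities are written as 32-bit float
#' after rescaling into [0, 1]; the scale and offset are recorded in the
#' sidecar so that `read_stack()` restores the original values (to 32-bit
#' float precision). Label volumes are written as 16-bit integers and
#' round-trip exactly for up to 65535 cells.
#'
#' @param stack an [image_stack()].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `read_stack()` returns an [image_stack()]; the writers return
#'   `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fs_stack"))
  v <- stack$voxels
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) t((v[, , k] - lo) / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(kind = "stack", spacing = stack$spacing,
                           channel = stack$channel,
                           offset = lo, scale = scale))
  invisible(path)
}

#' @rdname write_stack
#' @param spacing optional spacing override (um per voxel, x/y/z) used when
#'   the sidecar is absent.
#' @export
read_stack <- function(path, spacing = NULL) {
  pages <- read_tiff_pages(path)
  if (length(pages) < 2)
    stopf("expected 3 dimensions: '%s' holds a single plane", path)
  meta <- read_sidecar(path)
  if (is.null(spacing)) {
    if (is.null(meta) || is.null(meta$spacing))
      stopf("missing voxel spacing for '%s': supply `spacing` or a '%s' sidecar",
            path, sidecar_path(path))
    spacing <- as.numeric(meta$spacing)
  }
  v <- pages_to_array(pages)
  if (!is.null(meta) && !is.null(meta$scale))
    v <- v * meta$scale + meta$offset
  image_stack(v, spacing = spacing,
              channel = if (!is.null(meta$channel)) meta$channel else "")
}

#' @rdname write_stack
#' @param labels an [cell_labels()] volume.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "fs_labels"))
  v <- labels$labels
  if (max(v) > 65535L) stopf("label ids above 65535 are not supported")
  pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  write_sidecar(path, list(kind = "labels", spacing = labels$spacing))
  invisible(path)
}

#' @rdname write_stack
#' @export
read_labels <- function(path, spacing = NULL) {
  pages <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  if (is.null(spacing)) {
    if (is.null(meta) || is.null(meta$spacing))
      stopf("missing voxel spacing for '%s': supply `spacing` or a '%s' sidecar",
            path, sidecar_path(path))
    spacing <- as.numeric(meta$spacing)
  }
  v <- round(pages_to_array(pages) * 65535)
  cell_labels(v, spacing = spacing)
}

#' @rdname write_stack
#' @param movie an [time_lapse()] movie.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "fs_movie"))
  v <- movie$frames
  lo <- min(v); hi <- max(v)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) t((v[, , k] - lo) / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  write_sidecar(path, list(kind = "movie", spacing = movie$pixel_spacing,
                           frame_interval = movie$frame_interval,
                           offset = lo, scale = scale))
  invisible(path)
}

#' @rdname write_stack
#' @param frame_interval optional frame interval override (seconds).
#' @export
read_movie <- function(path, spacing = NULL, frame_interval = NULL) {
  pages <- read_tiff_pages(path)
  meta <- read_sidecar(path)
  if (is.null(spacing)) {
    if (is.null(meta) || is.null(meta$spacing))
      stopf("missing pixel spacing for '%s': supply `spacing` or a '%s' sidecar",
            path, sidecar_path(path))
    spacing <- as.numeric(meta$spacing)
  }
  if (is.null(frame_interval)) {
    if (is.null(meta) || is.null(meta$frame_interval))
      stopf("missing frame interval for '%s': supply `frame_interval` or a sidecar",
            path)
    frame_interval <- as.numeric(meta$frame_interval)
  }
  v <- pages_to_array(pages)
  if (!is.null(meta) && !is.null(meta$scale))
    v <- v * meta$scale + meta$offset
  time_lapse(v, pixel_spacing = spacing, frame_interval = frame_interval)
}

# --- measurement tables ----------------------------------------------------

#' Write and re-read measurement tables
#'
#' Measurement tables are plain tibbles whose numeric column names carry
#' their units (`area_um2`, `depth_um`, `mean_speed_um_min`, ...). They are
#' written as comma-delimited UTF-8 with full numeric precision so that a
#' written table re-parses to the same values. Tables produced by different
#' measurement stages carry a `kind` attribute; mixing kinds in one file is
#' refused.
#'
#' @param records a tibble from one measurement stage, or a list of such
#'   tibbles of the same kind (they are row-bound).
#' @param path output CSV path.
#' @return `read_measurements()` returns a tibble.
#' @export
write_measurements <- function(records, path) {
  if (is.data.frame(records)) records <- list(records)
  if (!length(records)) stopf("no records to write")
  kinds <- unique(vapply(records, function(r) {
    k <- attr(r, "fs_kind")
    if (is.null(k)) paste(sort(names(r)), collapse = "|") else k
  }, character(1)))
  if (length(kinds) > 1)
    stopf("mixed record kinds in one table: %s", paste(kinds, collapse = ", "))
  df <- dplyr::bind_rows(records)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# tag a tibble with its record kind
fs_table <- function(df, kind) {
  df <- tibble::as_tibble(df)
  attr(df, "fs_kind") <- kind
  df
}

# --- internal TIFF helpers -------------------------------------------------

sidecar_path <- function(path) paste0(path, ".meta.yaml")

write_sidecar <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  yaml::read_yaml(sp)
}

read_tiff_pages <- function(path) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # collapse extra samples
    p
  })
  pages
}

# pages (rows = y, cols = x) -> array [x, y, z]
pages_to_array <- function(pages) {
  d <- dim(pages[[1]])
  if (is.null(d) || length(d) != 2) stop("expected 3 dimensions")
  arr <- array(0, c(d[2], d[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  arr
}
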