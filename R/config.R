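#' Pipeline configuration
#'
#' All tunables of the shape, intensity, comet and statistics stages in one
#' validated list. `foldshape_config()` returns the defaults, overridden by
#' any named arguments; `read_config()` loads a YAML file of the same keys.
#' Unknown keys are rejected so a typo cannot silently fall back to a
#' default.
#'
#' Key defaults (units in parentheses):
#' \describe{
#'   \item{slice_fractions}{apical/basal slice points as fractions of cell
#'     length, `c(1/6, 5/6)`; the sixths convention places slices about
#'     5-7 um into 30-42 um cells.}
#'   \item{depth_max_angle}{maximal angle of the depth chord from the
#'     z-axis (degrees), 45, inclusive.}
#'   \item{width_mode}{`"perpendicular"` measures width perpendicular to
#'     the realized depth chord; `"x_axis"` measures along the raw x-axis.}
#'   \item{width_angle_tol}{angular tolerance (degrees) when searching the
#'     pixelated mask for a chord in the width direction, 3.}
#'   \item{anisotropy_tol}{|ratio - 1| above which a cell is flagged
#'     anisotropic, 0.05.}
#'   \item{slice_average_um}{y-averaging window for digital slices (um),
#'     0 = single voxel plane.}
#'   \item{apical_min_y}{if `TRUE` (default) the apical surface is the
#'     minimum-y end of the aligned cell (ventricle side).}
#'   \item{mhb_fit_span}{span (um) of basal-surface points on each side of
#'     the vertex used for the tissue-angle line fits, 20.}
#'   \item{proj_extent_um}{z extent of the average intensity projection
#'     (um), 10.}
#'   \item{emtb_roi_um}{EMTB region ROI width x height (um), `c(40, 50)`.}
#'   \item{polarity_box_area_um2}{area of the square apical/middle/basal
#'     boxes (um^2), 10.}
#'   \item{polarity_fractions}{fractional apical/middle/basal box positions
#'     along the cell axis, `c(1/6, 1/2, 5/6)`.}
#'   \item{movie_duration_s}{analysis window of comet movies (s), 200.}
#'   \item{movie_roi_um}{comet ROI width x height (um), `c(50, 40)`.}
#'   \item{particle_area_um2}{min/max particle area kept by the Otsu
#'     branch (um^2), `c(0.08, 3)`.}
#'   \item{log_blob_diameter_um}{LoG estimated blob diameter (um), 1.}
#'   \item{log_quality}{LoG quality threshold on the normalized response
#'     (fraction of the dynamic range), or `"auto"` (default) for an Otsu
#'     split of the spot qualities.}
#'   \item{log_subpixel}{quadratic sub-pixel refinement, `TRUE`.}
#'   \item{link_max_radius_um}{linking search radius around the predicted
#'     position (um), 1.5.}
#'   \item{gap_frames}{frames a track survives unmatched, 2.}
#'   \item{min_track_length}{minimum spots per reported track, 3.}
#'   \item{tukey_gate}{ANOVA p-value below which Tukey HSD runs, 0.05.}
#'   \item{seed}{integer seed for any stochastic step.}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class `"fs_config"`.
#' @examples
#' cfg <- foldshape_config(log_quality = 0.4)
#' cfg$log_quality
#' @export
foldshape_config <- function(...) {
  cfg <- list(
    slice_fractions      = c(1 / 6, 5 / 6),
    depth_max_angle      = 45,
    width_mode           = "perpendicular",
    width_angle_tol      = 3,
    anisotropy_tol       = 0.05,
    slice_average_um     = 0,
    apical_min_y         = TRUE,
    mhb_fit_span         = 20,
    proj_extent_um       = 10,
    emtb_roi_um          = c(40, 50),
    polarity_box_area_um2 = 10,
    polarity_fractions   = c(1 / 6, 1 / 2, 5 / 6),
    movie_duration_s     = 200,
    movie_roi_um         = c(50, 40),
    particle_area_um2    = c(0.08, 3),
    log_blob_diameter_um = 1,
    log_quality          = "auto",
    log_subpixel         = TRUE,
    link_max_radius_um   = 1.5,
    gap_frames           = 2L,
    min_track_length     = 3L,
    tukey_gate           = 0.05,
    seed                 = 1L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) || is.null(names(over)) || any(names(over) == ""))
      stopf("unknown config keys: %s", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

#' @rdname foldshape_config
#' @param path YAML file of config keys.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: '%s'", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(foldshape_config, vals)
}

#' @rdname foldshape_config
#' @param config an `fs_config` list.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fs_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_config <- function(cfg) {
  pos <- function(key, n = 1) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != n || !all(is.finite(v)) || any(v <= 0))
      stopf("config '%s' must be %d positive number(s)", key, n)
  }
  pos("depth_max_angle"); pos("anisotropy_tol"); pos("width_angle_tol")
  pos("mhb_fit_span"); pos("proj_extent_um"); pos("emtb_roi_um", 2)
  pos("polarity_box_area_um2"); pos("movie_duration_s"); pos("movie_roi_um", 2)
  pos("particle_area_um2", 2); pos("log_blob_diameter_um")
  if (!identical(cfg$log_quality, "auto")) pos("log_quality")
  pos("link_max_radius_um"); pos("tukey_gate")
  sf <- cfg$slice_fractions
  if (!is.numeric(sf) || length(sf) != 2 || any(sf <= 0) || any(sf >= 1) ||
      sf[1] >= sf[2])
    stopf("config 'slice_fractions' must be two increasing fractions in (0,1)")
  pf <- cfg$polarity_fractions
  if (!is.numeric(pf) || length(pf) != 3 || any(pf <= 0) || any(pf >= 1))
    stopf("config 'polarity_fractions' must be three fractions in (0,1)")
  if (!cfg$width_mode %in% c("perpendicular", "x_axis"))
    stopf("config 'width_mode' must be 'perpendicular' or 'x_axis'")
  if (!is.numeric(cfg$slice_average_um) || cfg$slice_average_um < 0)
    stopf("config 'slice_average_um' must be >= 0")
  if (cfg$particle_area_um2[1] >= cfg$particle_area_um2[2])
    stopf("config 'particle_area_um2' must be an increasing (min, max) pair")
  for (key in c("gap_frames", "min_track_length", "seed")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v) || v < 0)
      stopf("config '%s' must be a non-negative integer", key)
    cfg[[key]] <- as.integer(v)
  }
  if (!is.logical(cfg$apical_min_y) || !is.logical(cfg$log_subpixel))
    stopf("config 'apical_min_y' and 'log_subpixel' must be logical")
  structure(cfg, class = "fs_config")
}
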