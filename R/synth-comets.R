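#' Parameters for synthetic comet movies
#'
#' Emulates single-plane time-lapse acquisitions of GFP-tagged
#' plus-end-tracking comets: point-like particles moving ballistically at
#' a few um/min, imaged at one frame per 4 s for 10 min. Comets are 2D
#' Gaussian blobs of unit peak amplitude; each comet draws a speed from
#' `N(speed, speed_sd^2)` and an isotropic (or apical-basal biased)
#' direction and moves at constant velocity. Comets whose centre leaves
#' the field are removed and replaced by a fresh comet at a random
#' position, holding the expected count. The background is a constant
#' detector offset plus Gaussian noise with sd `1/snr`, clipped at zero,
#' so the peak signal-to-noise ratio is `snr`.
#'
#' @param n_comets expected comets in the field (default 30).
#' @param speed mean comet speed, um/min (default 4.5).
#' @param speed_sd per-comet speed sd, um/min (default 0.5).
#' @param comet_sigma Gaussian blob sd, um (default 0.4, FWHM about
#'   1 um, the nominal comet diameter).
#' @param direction_model `"isotropic"` or `"apical_basal"` (directions
#'   biased along y).
#' @param duration movie length, s (default 600).
#' @param frame_interval s per frame (default 4).
#' @param snr peak signal to noise sd ratio (default 20, the
#'   high-contrast regime that histogram-threshold comet counting
#'   presupposes; see the methods vignette).
#' @param background offset of the detector background, as a fraction of
#'   the comet peak amplitude (default 0.1).
#' @param field field of view (width, height) um (default 60 x 50).
#' @param spacing um per pixel (default 0.2 x 0.2).
#' @param seed integer seed.
#' @return a validated list of class `fs_comet_params`.
#' @export
comet_params <- function(n_comets = 30, speed = 4.5, speed_sd = 0.5,
                         comet_sigma = 0.4,
                         direction_model = c("isotropic", "apical_basal"),
                         duration = 600, frame_interval = 4, snr = 20,
                         background = 0.1,
                         field = c(60, 50), spacing = c(0.2, 0.2),
                         seed = 1L) {
  direction_model <- match.arg(direction_model)
  p <- list(n_comets = as.integer(n_comets), speed = speed,
            speed_sd = speed_sd, comet_sigma = comet_sigma,
            direction_model = direction_model, duration = duration,
            frame_interval = frame_interval, snr = snr,
            background = background,
            field = field, spacing = spacing, seed = as.integer(seed))
  if (p$n_comets < 0) stopf("n_comets must be >= 0")
  if (p$speed < 0 || p$speed_sd < 0) stopf("speed and speed_sd must be >= 0")
  if (p$comet_sigma <= 0) stopf("comet_sigma must be > 0")
  if (p$frame_interval <= 0) stopf("frame_interval must be > 0")
  if (p$duration < p$frame_interval)
    stopf("duration must be at least one frame_interval")
  if (p$snr <= 0) stopf("snr must be > 0")
  if (p$background < 0) stopf("background must be >= 0")
  check_spacing(p$field, 2L)
  check_spacing(p$spacing, 2L)
  structure(p, class = "fs_comet_params")
}

#' Generate a comet movie with ground-truth tracks
#'
#' @param params a [comet_params()] list.
#' @return a list with `movie` (a [time_lapse()]) and `truth` (tibble
#'   `track_id`, `frame`, `x_um`, `y_um`, `speed_um_min`; one row per
#'   comet per frame in which it is inside the field).
#' @export
generate_comet_movie <- function(params = comet_params()) {
  stopifnot(inherits(params, "fs_comet_params"))
  p <- params
  withr::local_seed(p$seed)
  nt <- floor(p$duration / p$frame_interval)
  d <- c(round(p$field[1] / p$spacing[1]), round(p$field[2] / p$spacing[2]))
  frames <- array(0, c(d[1], d[2], nt))
  step_per_frame <- p$frame_interval / 60           # minutes per frame
  new_comet <- function(id) {
    ang <- if (p$direction_model == "isotropic") stats::runif(1, 0, 2 * pi)
           else stats::rnorm(1, ifelse(stats::runif(1) < 0.5, pi / 2, -pi / 2), 0.3)
    sp <- max(0, stats::rnorm(1, p$speed, p$speed_sd))
    list(id = id, x = stats::runif(1, 0, p$field[1]),
         y = stats::runif(1, 0, p$field[2]),
         vx = sp * cos(ang) * step_per_frame,
         vy = sp * sin(ang) * step_per_frame,
         speed = sp)
  }
  comets <- list()
  next_id <- 1L
  if (p$n_comets > 0) {
    for (i in seq_len(p$n_comets)) {
      comets[[i]] <- new_comet(next_id)
      next_id <- next_id + 1L
    }
  }
  truth <- vector("list", nt)
  xs <- px_center(seq_len(d[1]), p$spacing[1])
  ys <- px_center(seq_len(d[2]), p$spacing[2])
  win <- ceiling(4 * p$comet_sigma / min(p$spacing))
  for (t in seq_len(nt)) {
    img <- matrix(0, d[1], d[2])
    rows <- list()
    for (i in seq_along(comets)) {
      cm <- comets[[i]]
      img <- add_blob(img, xs, ys, cm$x, cm$y, p$comet_sigma, win, p$spacing)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        track_id = cm$id, frame = t, x_um = cm$x, y_um = cm$y,
        speed_um_min = cm$speed)
      cm$x <- cm$x + cm$vx
      cm$y <- cm$y + cm$vy
      if (cm$x < 0 || cm$x > p$field[1] || cm$y < 0 || cm$y > p$field[2]) {
        cm <- new_comet(next_id)
        next_id <- next_id + 1L
      }
      comets[[i]] <- cm
    }
    truth[[t]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
    noise <- matrix(stats::rnorm(prod(d), 0, 1 / p$snr), d[1], d[2])
    frames[, , t] <- pmax(img + p$background + noise, 0)
  }
  movie <- time_lapse(frames, pixel_spacing = p$spacing,
                      frame_interval = p$frame_interval)
  tt <- dplyr::bind_rows(truth)
  if (!nrow(tt))
    tt <- tibble::tibble(track_id = integer(0), frame = integer(0),
                         x_um = numeric(0), y_um = numeric(0),
                         speed_um_min = numeric(0))
  list(movie = movie, truth = fs_table(tt, "comet_truth"))
}

# add a unit-peak Gaussian blob at (cx, cy) um within a +/- win px window
add_blob <- function(img, xs, ys, cx, cy, sigma, win, spacing) {
  i0 <- nearest_index(cx, spacing[1], length(xs))
  j0 <- nearest_index(cy, spacing[2], length(ys))
  ix <- max(1, i0 - win):min(length(xs), i0 + win)
  iy <- max(1, j0 - win):min(length(ys), j0 + win)
  gx <- exp(-(xs[ix] - cx)^2 / (2 * sigma^2))
  gy <- exp(-(ys[iy] - cy)^2 / (2 * sigma^2))
  img[ix, iy] <- img[ix, iy] + outer(gx, gy)
  img
}

#' Generate a piecewise-constant region-intensity stack
#'
#' A noiseless (or noisy) fixture for the region-normalization workflow:
#' three disjoint rectangular regions with stated mean intensities on a
#' background equal to the mean of the three (so equal means give a
#' spatially uniform stack).
#'
#' @param mhbc_mean,midbrain_mean,hindbrain_mean region intensities.
#' @param layout list of three [roi_rect()]s named `mhbc`, `midbrain`,
#'   `hindbrain`.
#' @param field stack extent (x, y) um.
#' @param n_planes number of z planes.
#' @param noise_sd additive Gaussian noise sd.
#' @param spacing voxel spacing um.
#' @param seed integer seed.
#' @return an [image_stack()]; the stated means are attached as attribute
#'   `"truth"`.
#' @export
generate_region_intensity_stack <- function(mhbc_mean, midbrain_mean,
                                            hindbrain_mean, layout,
                                            field = c(150, 60),
                                            n_planes = 20, noise_sd = 0,
                                            spacing = c(0.2, 0.2, 0.5),
                                            seed = 1L) {
  stopifnot(is.list(layout),
            all(c("mhbc", "midbrain", "hindbrain") %in% names(layout)))
  rois <- layout[c("mhbc", "midbrain", "hindbrain")]
  for (r in rois) stopifnot(inherits(r, "fs_roi"))
  for (i in 1:2) for (j in (i + 1):3)
    if (rois_overlap(rois[[i]], rois[[j]]))
      stopf("region ROIs '%s' and '%s' overlap", names(rois)[i], names(rois)[j])
  means <- c(mhbc = mhbc_mean, midbrain = midbrain_mean,
             hindbrain = hindbrain_mean)
  if (any(!is.finite(means)) || any(means < 0))
    stopf("region means must be finite and >= 0")
  d <- c(round(field[1] / spacing[1]), round(field[2] / spacing[2]), n_planes)
  plane <- matrix(mean(means), d[1], d[2])
  for (k in 1:3) {
    r <- rois[[k]]
    ix <- halfopen_index_range(r$x, r$x + r$width, spacing[1])
    iy <- halfopen_index_range(r$y, r$y + r$height, spacing[2])
    ix <- ix[ix >= 1 & ix <= d[1]]; iy <- iy[iy >= 1 & iy <= d[2]]
    plane[ix, iy] <- means[k]
  }
  v <- array(rep(plane, d[3]), d)
  if (noise_sd > 0) {
    withr::local_seed(seed)
    v <- v + array(stats::rnorm(prod(d), 0, noise_sd), d)
  }
  st <- image_stack(v, spacing = spacing, channel = "region_fixture")
  attr(st, "truth") <- means
  st
}
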