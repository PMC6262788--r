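#' EB3 comet pipeline: preparation, segmentation, detection, tracking
#'
#' The comet pipeline mirrors the two-branch Fiji workflow: the movie is
#' cropped in time and space and converted to 8-bit; comet number and size
#' come from Otsu thresholding plus particle analysis; comet speed comes
#' from Laplacian-of-Gaussian sub-pixel detection followed by
#' linear-motion predictive linking and per-track speed in um/min.
#'
#' `prepare_movie()` keeps the first `floor(duration / frame_interval)`
#' frames, crops them to `roi`, and min-max rescales the whole cropped
#' series to 8-bit (integer 0-255).
#'
#' @param movie a [time_lapse()] movie.
#' @param duration analysis window in seconds (default 200).
#' @param roi an [roi_rect()] crop region in um; `NULL` keeps the full
#'   field.
#' @param verbose log to stderr.
#' @return a [time_lapse()] whose frames are 8-bit integers.
#' @export
prepare_movie <- function(movie, duration = 200, roi = NULL, verbose = FALSE) {
  stopifnot(inherits(movie, "fs_movie"))
  nt <- dim(movie$frames)[3]
  nkeep <- floor(duration / movie$frame_interval)
  if (nkeep < 1) stopf("duration %g s is below one frame interval", duration)
  if (nkeep > nt)
    stopf("movie (%g s) is shorter than the analysis window (%g s)",
          nt * movie$frame_interval, duration)
  fr <- movie$frames[, , seq_len(nkeep), drop = FALSE]
  sp <- movie$pixel_spacing
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "fs_roi"))
    d <- dim(fr)
    if (roi$x < 0 || roi$y < 0 ||
        roi$x + roi$width > d[1] * sp[1] + 1e-9 ||
        roi$y + roi$height > d[2] * sp[2] + 1e-9)
      stopf("crop ROI extends outside the %g x %g um field",
            d[1] * sp[1], d[2] * sp[2])
    ix <- halfopen_index_range(roi$x, roi$x + roi$width, sp[1])
    iy <- halfopen_index_range(roi$y, roi$y + roi$height, sp[2])
    fr <- fr[ix, iy, , drop = FALSE]
  }
  lo <- min(fr); hi <- max(fr)
  if (hi > lo) {
    fr <- round((fr - lo) / (hi - lo) * 255)
  } else {
    log_msg(verbose, "prepare_movie: degenerate intensity range; output all zero")
    warning("constant-value movie: 8-bit output is all zero", call. = FALSE)
    fr[] <- 0
  }
  out <- time_lapse(fr, pixel_spacing = sp,
                    frame_interval = movie$frame_interval)
  attr(out, "eightbit") <- TRUE
  out
}

#' @rdname prepare_movie
#'
#' @details
#' `otsu_threshold()` maximizes the between-class variance over the 256-bin
#' histogram of an 8-bit frame and returns the cut point `t`; foreground is
#' `frame > t`. The smallest maximizing cut is returned.
#'
#' @param frame integer matrix with values 0-255.
#' @return `otsu_threshold()`: integer threshold in 0-254, or `NA` when
#'   the histogram has a single occupied bin.
#' @export
otsu_threshold <- function(frame) {
  h <- tabulate(as.integer(frame) + 1L, nbins = 256L)
  if (sum(h > 0) < 2) return(NA_integer_)
  n <- sum(h)
  p <- h / n
  levels <- 0:255
  omega <- cumsum(p)                     # class 0 weight for cut at t
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  t_candidates <- 0:254
  w0 <- omega[t_candidates + 1L]
  m0 <- mu[t_candidates + 1L]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(t_candidates))
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  t_candidates[which.max(sigma_b)]
}

#' @rdname prepare_movie
#'
#' @details
#' `segment_particles()` applies the Otsu threshold to one 8-bit frame,
#' labels 8-connected components, discards components outside
#' `[min_area, max_area]` um^2 and returns centroids (um, pixel-centre
#' convention) and areas.
#'
#' @param spacing um per pixel (x, y) of the frame.
#' @param min_area,max_area particle area bounds in um^2.
#' @return `segment_particles()`: tibble with `x_um`, `y_um`, `area_um2`.
#' @export
segment_particles <- function(frame, spacing, min_area = 0.08, max_area = 3) {
  if (!is.matrix(frame)) stopf("frame must be a matrix")
  check_spacing(spacing, 2L)
  thr <- otsu_threshold(frame)
  empty <- tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          area_um2 = numeric(0))
  if (is.na(thr)) {
    warning("single-valued histogram: no particles segmented", call. = FALSE)
    return(empty)
  }
  fg <- frame > thr
  if (!any(fg)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- EBImage::imageData(lab)
  ids <- seq_len(max(lab))
  px_area <- spacing[1] * spacing[2]
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(counts * px_area >= min_area & counts * px_area <= max_area)
  if (!length(keep)) return(empty)
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  sel <- l %in% keep
  idx <- idx[sel, , drop = FALSE]
  l <- l[sel]
  cx <- tapply(px_center(idx[, 1], spacing[1]), l, mean)
  cy <- tapply(px_center(idx[, 2], spacing[2]), l, mean)
  ord <- as.integer(names(cx))
  tibble::tibble(x_um = as.numeric(cx), y_um = as.numeric(cy),
                 area_um2 = counts[ord] * px_area)
}

#' @rdname prepare_movie
#'
#' @details
#' `detect_log()` computes the scale-normalized Laplacian-of-Gaussian
#' response with `sigma = (blob_diameter / 2) / sqrt(2)` (the radius of the
#' matched blob over sqrt 2). The response is calibrated so that a matched
#' Gaussian blob of amplitude A (on the 0-1 intensity scale) scores about
#' A; the quality threshold 0.5 therefore keeps blobs brighter than half
#' the dynamic range. Spots are strict 8-neighbourhood local maxima with
#' response at or above `quality_threshold`; positions are refined to
#' sub-pixel precision by a separable quadratic fit when `subpixel` is
#' `TRUE`. With `quality_threshold = "auto"` (the pipeline default) the
#' threshold is instead found by an Otsu split of the candidate-maximum
#' qualities, the auto initial quality filter of the usual tracking
#' workflow; this is robust to the series-wide rescaling that a single
#' blob-overlap event causes.
#'
#' @param blob_diameter estimated comet diameter in um (default 1).
#' @param quality_threshold minimal normalized response, or `"auto"`.
#' @param subpixel quadratic sub-pixel refinement (default `TRUE`).
#' @return `detect_log()`: tibble with `x_um`, `y_um`, `quality`.
#' @export
detect_log <- function(frame, spacing, blob_diameter = 1,
                       quality_threshold = "auto", subpixel = TRUE) {
  if (!is.matrix(frame)) stopf("frame must be a matrix")
  check_spacing(spacing, 2L)
  auto <- identical(quality_threshold, "auto")
  floor_q <- if (auto) 1e-3 else quality_threshold
  sigma_um <- (blob_diameter / 2) / sqrt(2)
  if (blob_diameter < 2 * min(spacing))
    stopf("blob_diameter %g um is below 2 px (%g um): undetectable scale",
          blob_diameter, 2 * min(spacing))
  f <- frame / if (max(frame) > 1) 255 else 1
  resp <- 2 * log_response(f, sigma_um, spacing)
  nx <- nrow(resp); ny <- ncol(resp)
  if (nx < 3 || ny < 3) return(tibble::tibble(x_um = numeric(0),
                                              y_um = numeric(0),
                                              quality = numeric(0)))
  core <- resp[2:(nx - 1), 2:(ny - 1)]
  ismax <- core >= floor_q
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    ismax <- ismax & core > resp[2:(nx - 1) + dx, 2:(ny - 1) + dy]
  }
  hit <- which(ismax, arr.ind = TRUE)
  if (!nrow(hit)) return(tibble::tibble(x_um = numeric(0),
                                        y_um = numeric(0),
                                        quality = numeric(0)))
  ix <- hit[, 1] + 1L   # back to full-frame indices
  iy <- hit[, 2] + 1L
  off_x <- off_y <- rep(0, length(ix))
  if (isTRUE(subpixel)) {
    off_x <- quad_offset(resp[cbind(ix - 1L, iy)], resp[cbind(ix, iy)],
                         resp[cbind(ix + 1L, iy)])
    off_y <- quad_offset(resp[cbind(ix, iy - 1L)], resp[cbind(ix, iy)],
                         resp[cbind(ix, iy + 1L)])
  }
  out <- tibble::tibble(x_um = (ix - 0.5 + off_x) * spacing[1],
                        y_um = (iy - 0.5 + off_y) * spacing[2],
                        quality = resp[cbind(ix, iy)])
  if (auto) out <- out[out$quality > auto_quality_split(out$quality), ]
  out
}

# Otsu-style split of continuous spot qualities (512 bins); the quality
# analogue of the auto initial threshold of interactive tracking tools
auto_quality_split <- function(q, nbins = 512L) {
  if (length(q) < 2) return(-Inf)
  lo <- min(q); hi <- max(q)
  if (hi <= lo) return(-Inf)
  b <- pmin(floor((q - lo) / (hi - lo) * nbins), nbins - 1L)
  h <- tabulate(b + 1L, nbins = nbins)
  p <- h / sum(h)
  mids <- (seq_len(nbins) - 0.5) / nbins
  w0 <- cumsum(p)
  m0 <- cumsum(p * mids)
  mt <- m0[nbins]
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, nbins)
  sb[valid] <- (mt * w0[valid] - m0[valid])^2 / (w0[valid] * (1 - w0[valid]))
  cut <- which.max(sb)
  lo + (cut / nbins) * (hi - lo)
}

# scale-normalized LoG response -sigma^2 * Laplacian(G_sigma * f),
# positive on bright blobs; computed as two separable convolutions
log_response <- function(f, sigma_um, spacing) {
  sx <- sigma_um / spacing[1]
  sy <- sigma_um / spacing[2]
  gx <- gauss_kernel(sx); gy <- gauss_kernel(sy)
  # d2/dx2 G(x) with x in um: (x^2/s^4 - 1/s^2) g(x), discretized per pixel
  dd <- function(s_px, step_um) {
    rr <- max(2L, ceiling(4 * s_px))
    u <- (-rr:rr) * step_um
    s <- s_px * step_um
    g <- exp(-u^2 / (2 * s^2))
    g <- g / sum(g)
    k <- (u^2 / s^4 - 1 / s^2) * g
    k - sum(k) * g          # discrete zero-sum: flat background -> 0 response
  }
  lxx <- sep_conv2(f, dd(sx, spacing[1]), gy)
  lyy <- sep_conv2(f, gx, dd(sy, spacing[2]))
  -sigma_um^2 * (lxx + lyy)
}

# sub-pixel offset of a parabola through (-1, fm), (0, f0), (1, fp)
quad_offset <- function(fm, f0, fp) {
  a <- (fp + fm - 2 * f0) / 2
  b <- (fp - fm) / 2
  off <- ifelse(a < 0, -b / (2 * a), 0)
  pmin(pmax(off, -0.5), 0.5)
}

#' Linear-motion predictive linking of detected spots
#'
#' Frame-to-frame linking with a constant-velocity motion model: every
#' open track predicts its next position from its last observed position
#' and velocity; candidate links within `max_link_radius` of the
#' prediction are assigned by a globally minimal linear assignment (cost =
#' squared distance to the prediction, alternative cost =
#' `1.05 * max_link_radius^2` for starting or dropping). Unmatched tracks
#' coast for up to `gap_frames` frames before closing; unmatched spots
#' seed new tracks; tracks shorter than `min_track_length` spots are
#' discarded.
#'
#' @param spots tibble with columns `frame`, `x_um`, `y_um` (frames need
#'   not be consecutive; missing frames count toward the gap limit).
#' @param max_link_radius search radius around the prediction, um.
#' @param gap_frames frames a track may remain unmatched.
#' @param min_track_length minimal spots per reported track.
#' @return a tibble with `track_id`, `frame`, `x_um`, `y_um`, of class
#'   kind `"tracks"`.
#' @export
link_tracks <- function(spots, max_link_radius = 1.5, gap_frames = 2,
                        min_track_length = 3) {
  stopifnot(is.data.frame(spots),
            all(c("frame", "x_um", "y_um") %in% names(spots)))
  empty <- fs_table(tibble::tibble(track_id = integer(0), frame = integer(0),
                                   x_um = numeric(0), y_um = numeric(0)),
                    "tracks")
  if (!nrow(spots)) return(empty)
  spots <- spots[order(spots$frame), , drop = FALSE]
  frames <- sort(unique(spots$frame))
  # open track state: id, last position, velocity (um/frame), last frame
  open <- list()
  done <- list()
  next_id <- 1L
  rows <- list()
  alt <- 1.05 * max_link_radius^2
  blocked <- 1e9
  for (fr in seq.int(min(frames), max(frames))) {
    sp <- spots[spots$frame == fr, , drop = FALSE]
    nS <- nrow(sp)
    nT <- length(open)
    assign_spot <- rep(NA_integer_, nS)   # track index per spot
    if (nT > 0 && nS > 0) {
      pred <- t(vapply(open, function(tr) {
        dt <- fr - tr$last_frame
        tr$pos + tr$vel * dt
      }, numeric(2)))
      d2 <- outer(pred[, 1], sp$x_um, "-")^2 + outer(pred[, 2], sp$y_um, "-")^2
      link <- d2
      link[sqrt(d2) > max_link_radius] <- blocked
      # square LAP with start/stop alternatives (Jaqaman-style blocks)
      n <- nT + nS
      cost <- matrix(blocked, n, n)
      cost[seq_len(nT), seq_len(nS)] <- link
      for (i in seq_len(nT)) cost[i, nS + i] <- alt
      for (j in seq_len(nS)) cost[nT + j, j] <- alt
      cost[(nT + 1):n, (nS + 1):n] <- t(link)
      sol <- .solve_lap_cpp(cost)
      for (i in seq_len(nT)) {
        j <- sol[i]
        if (j <= nS && link[i, j] < blocked) assign_spot[j] <- i
      }
    }
    new_open <- list()
    matched_tracks <- stats::na.omit(assign_spot)
    for (i in seq_len(nT)) {
      tr <- open[[i]]
      if (i %in% matched_tracks) {
        j <- which(assign_spot == i)[1]
        newpos <- c(sp$x_um[j], sp$y_um[j])
        dt <- fr - tr$last_frame
        tr$vel <- (newpos - tr$pos) / dt
        tr$pos <- newpos
        tr$last_frame <- fr
        tr$spots[[length(tr$spots) + 1L]] <- c(fr, newpos)
        new_open[[length(new_open) + 1L]] <- tr
      } else if (fr - tr$last_frame >= gap_frames + 1) {
        done[[length(done) + 1L]] <- tr
      } else {
        new_open[[length(new_open) + 1L]] <- tr
      }
    }
    for (j in seq_len(nS)) {
      if (is.na(assign_spot[j])) {
        tr <- list(id = next_id, pos = c(sp$x_um[j], sp$y_um[j]),
                   vel = c(0, 0), last_frame = fr,
                   spots = list(c(fr, sp$x_um[j], sp$y_um[j])))
        next_id <- next_id + 1L
        new_open[[length(new_open) + 1L]] <- tr
      }
    }
    open <- new_open
  }
  done <- c(done, open)
  keep <- Filter(function(tr) length(tr$spots) >= min_track_length, done)
  if (!length(keep)) return(empty)
  out <- purrr::map_dfr(keep, function(tr) {
    m <- do.call(rbind, tr$spots)
    tibble::tibble(track_id = tr$id, frame = as.integer(m[, 1]),
                   x_um = m[, 2], y_um = m[, 3])
  })
  out <- out[order(out$track_id, out$frame), ]
  out$track_id <- match(out$track_id, unique(out$track_id))
  fs_table(out, "tracks")
}

#' Mean track speed in um/min
#'
#' Mean over consecutive spot pairs of displacement (um) divided by the
#' elapsed time (frame gap times `frame_interval` seconds), scaled to
#' um/min.
#'
#' @param track data frame with `frame`, `x_um`, `y_um` for one track.
#' @param frame_interval seconds per frame.
#' @return speed in um/min.
#' @export
track_speed <- function(track, frame_interval) {
  stopifnot(is.data.frame(track))
  n <- nrow(track)
  if (n < 2) stopf("track speed needs at least 2 spots")
  track <- track[order(track$frame), ]
  d <- sqrt(diff(track$x_um)^2 + diff(track$y_um)^2)
  dt <- diff(track$frame) * frame_interval
  mean(d / dt) * 60
}

#' Summarize a comet movie
#'
#' Runs both branches of the comet pipeline on a prepared movie: the
#' Otsu/particle branch gives the mean per-frame comet count and the mean
#' particle area; the LoG/linking branch gives the unweighted mean of
#' per-track speeds.
#'
#' @param movie a [time_lapse()] movie (prepared with [prepare_movie()],
#'   or raw, in which case it is prepared with the config's window and
#'   ROI first).
#' @param config a [foldshape_config()].
#' @return a one-row tibble: `mean_speed_um_min` (NA when no track
#'   survives), `comet_number`, `comet_size_um2`, `n_tracks`, `n_frames`;
#'   the spot-level track table is attached as attribute `"tracks"`.
#' @export
summarize_comets <- function(movie, config = foldshape_config()) {
  stopifnot(inherits(movie, "fs_movie"))
  cfg <- config
  if (!isTRUE(attr(movie, "eightbit"))) {
    roi <- roi_rect(0, 0, cfg$movie_roi_um[1], cfg$movie_roi_um[2])
    movie <- prepare_movie(movie, duration = cfg$movie_duration_s, roi = roi)
  }
  fr <- movie$frames
  sp <- movie$pixel_spacing
  nt <- dim(fr)[3]
  counts <- numeric(nt)
  areas <- list()
  spots <- list()
  for (k in seq_len(nt)) {
    pt <- segment_particles(fr[, , k], sp,
                            min_area = cfg$particle_area_um2[1],
                            max_area = cfg$particle_area_um2[2])
    counts[k] <- nrow(pt)
    areas[[k]] <- pt$area_um2
    det <- detect_log(fr[, , k], sp,
                      blob_diameter = cfg$log_blob_diameter_um,
                      quality_threshold = cfg$log_quality,
                      subpixel = cfg$log_subpixel)
    det$frame <- rep(k, nrow(det))
    spots[[k]] <- det
  }
  all_spots <- dplyr::bind_rows(spots)
  tracks <- link_tracks(all_spots,
                        max_link_radius = cfg$link_max_radius_um,
                        gap_frames = cfg$gap_frames,
                        min_track_length = cfg$min_track_length)
  speeds <- if (nrow(tracks)) {
    vapply(split(tracks, tracks$track_id), track_speed, numeric(1),
           frame_interval = movie$frame_interval)
  } else numeric(0)
  out <- tibble::tibble(
    mean_speed_um_min = if (length(speeds)) mean(speeds) else NA_real_,
    comet_number = mean(counts),
    comet_size_um2 = if (length(unlist(areas))) mean(unlist(areas)) else NA_real_,
    n_tracks = length(speeds),
    n_frames = nt)
  out <- fs_table(out, "comet_summary")
  attr(out, "tracks") <- tracks
  out
}
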