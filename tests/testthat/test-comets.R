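# Movie preparation, Otsu particles, LoG detection, linking, speeds.

test_that("prepare_movie crops the window and rescales to 8-bit", {
  withr::local_seed(12)
  mv <- time_lapse(array(runif(50 * 40 * 150, 10, 210), c(50, 40, 150)),
                   pixel_spacing = c(1, 1), frame_interval = 4)
  pm <- prepare_movie(mv, duration = 200)
  expect_identical(dim(pm$frames)[3], 50L)      # 200 s / 4 s per frame
  expect_identical(range(pm$frames), c(0, 255)) # 10 -> 0, 210 -> 255
  # spatial crop
  pm2 <- prepare_movie(mv, duration = 200, roi = roi_rect(0, 0, 30, 20))
  expect_identical(dim(pm2$frames)[1:2], c(30L, 20L))
  expect_error(prepare_movie(mv, duration = 200, roi = roi_rect(40, 0, 30, 20)),
               "outside")
  expect_error(prepare_movie(mv, duration = 1000), "shorter")
  expect_warning(prepare_movie(
    time_lapse(array(5, c(10, 10, 60)), frame_interval = 4), duration = 200),
    "constant")
})

test_that("Otsu threshold equals the exhaustive between-class search", {
  brute_otsu <- function(f) {
    h <- tabulate(as.integer(f) + 1L, 256L)
    n <- sum(h)
    best_t <- NA_integer_; best_v <- -Inf
    for (t in 0:254) {
      n0 <- sum(h[1:(t + 1)]); n1 <- n - n0
      if (n0 == 0 || n1 == 0) next
      m0 <- sum((0:t) * h[1:(t + 1)]) / n0
      m1 <- sum(((t + 1):255) * h[(t + 2):256]) / n1
      v <- (n0 / n) * (n1 / n) * (m0 - m1)^2
      if (v > best_v) { best_v <- v; best_t <- t }
    }
    best_t
  }
  withr::local_seed(13)
  for (i in 1:12) {
    f <- matrix(sample(0:255, 400, TRUE, prob = runif(256)^3), 20, 20)
    expect_identical(otsu_threshold(f), brute_otsu(f))
  }
  # two-level image: threshold strictly between the levels
  f2 <- matrix(20L, 30, 30); f2[5:7, 5:7] <- 200L
  thr <- otsu_threshold(f2)
  expect_true(thr >= 20 && thr < 200)
  expect_true(is.na(otsu_threshold(matrix(7L, 5, 5))))
})

test_that("segment_particles counts blobs and filters by area", {
  f <- matrix(20L, 50, 50)
  f[5:8, 5:8] <- 200L; f[20:23, 30:33] <- 210L; f[40, 40] <- 220L
  pt <- segment_particles(f, c(0.2, 0.2), min_area = 0.1, max_area = 3)
  expect_identical(nrow(pt), 2L)               # the 1-px speck is filtered
  expect_equal(sort(pt$area_um2), rep(16 * 0.04, 2))
  expect_equal(sort(pt$x_um)[1], mean((5:8) - 0.5) * 0.2)
  expect_warning(empty <- segment_particles(matrix(0L, 10, 10), c(1, 1)),
                 "single-valued")
  expect_identical(nrow(empty), 0L)
})

test_that("LoG detection localizes blobs to sub-pixel accuracy", {
  sp <- c(0.2, 0.2)
  xs <- ((1:120) - 0.5) * 0.2; ys <- ((1:100) - 0.5) * 0.2
  blob <- function(cx, cy, s) outer(exp(-(xs - cx)^2 / (2 * s^2)),
                                    exp(-(ys - cy)^2 / (2 * s^2)))
  s_matched <- 0.5 / sqrt(2)
  f <- blob(7.03, 11.91, s_matched)
  det <- detect_log(f, sp, quality_threshold = 0.5)
  expect_identical(nrow(det), 1L)
  expect_lt(sqrt((det$x_um - 7.03)^2 + (det$y_um - 11.91)^2) / 0.2, 0.2)
  # blank frame
  expect_identical(nrow(detect_log(matrix(0, 50, 50), sp,
                                   quality_threshold = 0.5)), 0L)
  # two blobs 5 um apart resolve into two spots
  f2 <- blob(8, 10, s_matched) + blob(13, 10, s_matched)
  expect_identical(nrow(detect_log(f2, sp, quality_threshold = 0.5)), 2L)
  expect_error(detect_log(f, c(0.6, 0.6), blob_diameter = 1), "undetectable")
})

test_that("raising the quality threshold never increases the spot count", {
  withr::local_seed(14)
  f <- matrix(rnorm(80 * 80, 0.2, 0.05), 80, 80)
  xs <- ((1:80) - 0.5) * 0.2
  for (k in 1:6)
    f <- f + runif(1, 0.3, 1) *
      outer(exp(-(xs - runif(1, 3, 13))^2 / 0.125),
            exp(-(xs - runif(1, 3, 13))^2 / 0.125))
  counts <- vapply(seq(0.05, 0.9, by = 0.05), function(q)
    nrow(detect_log(f, c(0.2, 0.2), quality_threshold = q)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the assignment solver matches brute-force enumeration", {
  withr::local_seed(15)
  for (n in c(2, 3, 4, 5, 6)) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n, 0, 10), n, n)
      sol <- foldshape:::.solve_lap_cpp(cost)
      got <- sum(cost[cbind(seq_len(n), sol)])
      expect_equal(got, oracle_lap_cost(cost), tolerance = 1e-12)
    }
  }
})

test_that("linear-motion linking keeps identities and closes gaps", {
  # one noiseless constant-velocity comet -> one track with every frame
  fr <- 1:20
  one <- tibble::tibble(frame = fr, x_um = 1 + 0.3 * fr, y_um = 5 + 0.1 * fr)
  tr <- link_tracks(one, max_link_radius = 1.5, gap_frames = 2,
                    min_track_length = 3)
  expect_identical(unique(tr$track_id), 1L)
  expect_identical(tr$frame, fr)

  # two parallel comets closer than the radius but with opposite velocities:
  # prediction keeps their identities (0 swaps against ground truth)
  a <- tibble::tibble(frame = fr, x_um = 2 + 0.3 * fr, y_um = 10, truth = "a")
  b <- tibble::tibble(frame = fr, x_um = 9 - 0.3 * fr, y_um = 10.5, truth = "b")
  both <- dplyr::bind_rows(a, b)
  tr2 <- link_tracks(both[, 1:3], max_link_radius = 1.5, gap_frames = 2,
                     min_track_length = 3)
  expect_identical(length(unique(tr2$track_id)), 2L)
  merged <- dplyr::left_join(tr2, both, by = c("frame", "x_um", "y_um"))
  swaps <- tapply(merged$truth, merged$track_id,
                  function(v) length(unique(v)))
  expect_true(all(swaps == 1))

  # one missed detection with gap_frames = 1 -> a single unbroken track
  dropped <- one[one$frame != 10, ]
  tr3 <- link_tracks(dropped, max_link_radius = 1.5, gap_frames = 1,
                     min_track_length = 3)
  expect_identical(length(unique(tr3$track_id)), 1L)
  expect_identical(nrow(tr3), 19L)
  # with no gap allowance the track splits in two
  tr4 <- link_tracks(dropped, max_link_radius = 1.5, gap_frames = 0,
                     min_track_length = 3)
  expect_identical(length(unique(tr4$track_id)), 2L)
  expect_identical(nrow(link_tracks(one[0, ])), 0L)
})

test_that("track speed averages consecutive displacements in um/min", {
  tk <- tibble::tibble(frame = 1:6, x_um = 0.3 * (1:6), y_um = 0)
  expect_equal(track_speed(tk, frame_interval = 4), 4.5)  # 0.3 um / 4 s
  still <- tibble::tibble(frame = 1:5, x_um = 2, y_um = 3)
  expect_equal(track_speed(still, 4), 0)
  expect_error(track_speed(still[1, ], 4), "at least 2")
  # a gap contributes displacement over the elapsed frames
  gap <- tibble::tibble(frame = c(1, 2, 4), x_um = c(0, 0.3, 0.9), y_um = 0)
  expect_equal(track_speed(gap, 4), 4.5)
})

test_that("summarize_comets integrates both branches on a generated movie", {
  g <- generate_comet_movie(comet_params(n_comets = 12, duration = 240,
                                         field = c(30, 25), seed = 16))
  s <- summarize_comets(prepare_movie(g$movie, duration = 200))
  tr <- g$truth[g$truth$frame <= 50, ]
  true_count <- mean(table(tr$frame))
  expect_lt(abs(s$comet_number - true_count) / true_count, 0.1)
  per <- unique(tr[, c("track_id", "speed_um_min")])
  expect_lt(abs(s$mean_speed_um_min - mean(per$speed_um_min)) /
              mean(per$speed_um_min), 0.05)
  # a blank (signal-free, noise-free) movie yields zero counts, no tracks
  # and a missing speed
  blank <- time_lapse(array(0, c(150, 125, 60)), pixel_spacing = c(0.2, 0.2),
                      frame_interval = 4)
  s0 <- suppressWarnings(summarize_comets(prepare_movie(blank, duration = 200)))
  expect_identical(s0$n_tracks, 0L)
  expect_identical(s0$comet_number, 0)
  expect_true(is.na(s0$mean_speed_um_min))
  # determinism: identical movie and config give identical summaries
  s2 <- summarize_comets(prepare_movie(g$movie, duration = 200))
  expect_identical(as.data.frame(s), as.data.frame(s2))
})
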