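# Chord metrics, areas, ratios and the tissue fold angle.

test_that("mask area is pixel count times pixel area", {
  m <- matrix(TRUE, 10, 10)
  expect_equal(mask_area(m, c(0.5, 0.5)), 25)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(mask_area(single, c(0.2, 0.5)), 0.1)
  expect_error(mask_area(matrix(FALSE, 3, 3), c(1, 1)), "empty mask")
  # ellipse area approaches pi*a*b at adequate sampling
  m <- ellipse_mask(3, 5, 0.2, 0.2)
  expect_lt(abs(mask_area(m, c(0.2, 0.2)) - pi * 15) / (pi * 15), 0.05)
})

test_that("depth chord finds the deepest in-mask segment within 45 degrees", {
  # axis-aligned ellipse: a = 2 um (x), b = 5 um (z) -> depth 10 at 0 deg
  m <- ellipse_mask(2, 5, 0.2, 0.2)
  d <- max_depth_chord(m, c(0.2, 0.2))
  expect_lt(abs(d$depth_um - 10), 0.3)
  expect_lt(d$angle_deg, 5)
  # square of side s: the diagonal at exactly 45 degrees (inclusive)
  sq <- matrix(TRUE, 25, 25)
  d <- max_depth_chord(sq, c(0.2, 0.2))
  expect_equal(d$angle_deg, 45, tolerance = 1e-9)
  expect_lt(abs(d$depth_um - 24 * 0.2 * sqrt(2)), 0.2 * sqrt(2) + 1e-9)
  # 1-px-wide vertical bar of length L
  bar <- matrix(FALSE, 5, 30); bar[3, 4:27] <- TRUE
  d <- max_depth_chord(bar, c(0.2, 0.5))
  expect_equal(d$depth_um, 23 * 0.5)
  expect_equal(d$angle_deg, 0)
  expect_error(max_depth_chord(matrix(FALSE, 2, 2), c(1, 1)), "empty")
})

test_that("width is measured perpendicular to the depth chord", {
  m <- ellipse_mask(2, 5, 0.2, 0.2)
  d <- max_depth_chord(m, c(0.2, 0.2))
  w <- max_width_perpendicular(m, c(0.2, 0.2), d$angle_signed_deg)
  expect_lt(abs(w - 4), 0.3)
  # circle: width equals depth and the ratio is 1
  circ <- ellipse_mask(3, 3, 0.2, 0.2)
  d <- max_depth_chord(circ, c(0.2, 0.2))
  w <- max_width_perpendicular(circ, c(0.2, 0.2), d$angle_signed_deg)
  expect_lt(abs(w / d$depth_um - 1), 0.05)
})

test_that("chord metrics equal the exhaustive boundary-pair brute force", {
  withr::local_seed(101)
  spacings <- list(c(0.2, 0.2), c(0.2, 0.5), c(0.3, 0.4))
  for (i in 1:25) {
    m <- random_blob_mask(nmax = 26, steps = 30)
    sp <- spacings[[1 + i %% 3]]
    d <- max_depth_chord(m, sp)
    o <- oracle_chord(m, sp[1], sp[2], 0, 45)
    expect_identical(d$depth_um, o$len)
    expect_identical(d$angle_signed_deg, o$ang)
    expect_identical(c(d$x1, d$z1, d$x2, d$z2), o$ep)
    w <- max_width_perpendicular(m, sp, d$angle_signed_deg, angle_tol = 3)
    target <- foldshape:::wrap180(d$angle_signed_deg + 90)
    ow <- oracle_chord(m, sp[1], sp[2], target, 3)
    tol <- 3
    while (is.null(ow) && tol < 90) {
      tol <- min(2 * tol, 90)
      ow <- oracle_chord(m, sp[1], sp[2], target, tol)
    }
    expect_identical(w, ow$len)
  }
})

test_that("rotating a bar tilts the measured angle but conserves length", {
  base <- embed_mask(ellipse_mask(0.9, 3.4, 0.2, 0.2), 51)
  d0 <- max_depth_chord(base, c(0.2, 0.2))
  expect_lt(d0$angle_deg, 5)
  for (th in c(10, 25, 40)) {
    rot <- rotate_mask(base, th)
    d <- max_depth_chord(rot, c(0.2, 0.2))
    expect_lt(abs(d$angle_deg - th), 6)
    expect_lt(abs(d$depth_um - d0$depth_um) / d0$depth_um, 0.08)
    expect_lte(d$angle_deg, 45 + 1e-9)
  }
})

test_that("xz ratio flags anisotropy beyond the tolerance", {
  r <- xz_ratio(4, 10)
  expect_equal(r$ratio, 0.4)
  expect_true(r$is_anisotropic)
  r <- xz_ratio(7, 7)
  expect_equal(r$ratio, 1)
  expect_false(r$is_anisotropic)
  expect_error(xz_ratio(10, 0), "depth_z")
})

test_that("measure_cell_shape runs the slice protocol on an aligned cell", {
  g <- generate_epithelium_stack(small_epithelium(
    fold_angle = 180, noise_sd = 0, psf_sigma = 0, seed = 5))
  ids <- label_ids(g$labels)
  m <- measure_cell_shape(g$labels, ids[1], "both")
  expect_identical(m$surface, c("apical", "basal"))
  tr <- g$truth[g$truth$cell_id == ids[1], ]
  expect_lt(abs(m$xz_ratio[m$surface == "basal"] - tr$basal_ratio), 0.05)
  expect_lt(abs(m$xz_ratio[m$surface == "apical"] - tr$apical_ratio), 0.05)
  expect_lt(abs(m$depth_um[1] - tr$depth_um), 0.8)
  expect_error(measure_cell_shape(g$labels, 999L), "not present")
})

test_that("measure_cells aligns tilted cells before slicing", {
  g <- generate_epithelium_stack(small_epithelium(
    fold_angle = 90, noise_sd = 0, psf_sigma = 0, seed = 6))
  m <- measure_cells(g$labels)
  expect_identical(nrow(m), 2L * length(label_ids(g$labels)))
  basal <- m$xz_ratio[m$surface == "basal"]
  apical <- m$xz_ratio[m$surface == "apical"]
  expect_lt(abs(median(basal) - 0.5), 0.05)
  expect_lt(abs(median(apical) - 0.7), 0.05)
})

test_that("tissue angle comes from total-least-squares limb fits", {
  # two perpendicular rays
  s <- seq(1, 15)
  pts <- tibble::tibble(x_um = c(rev(-s), 0, s) + 50,
                        y_um = c(rev(s), 0, s) + 50)
  a <- measure_mhb_angle(pts, vertex_index = 16, fit_span = 20)
  expect_equal(a$angle_deg, 90, tolerance = 1e-6)
  # collinear points -> 180
  pts2 <- tibble::tibble(x_um = seq(0, 30), y_um = rep(5, 31))
  a2 <- measure_mhb_angle(pts2, vertex_index = 16, fit_span = 10)
  expect_equal(a2$angle_deg, 180, tolerance = 1e-6)
  expect_error(measure_mhb_angle(pts[14:18, ], 3, fit_span = 1), "at least 3")
})
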