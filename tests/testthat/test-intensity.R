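# Projections, ROI means and the normalization ratios.

test_that("average projection means the requested z window", {
  v <- array(7, c(10, 10, 20))
  st <- image_stack(v, spacing = c(0.2, 0.2, 0.5))
  expect_true(all(average_projection(st, z_extent = 10)$pixels == 7))
  # planes valued 1..10 over the full extent -> 5.5 everywhere
  v2 <- array(rep(1:10, each = 25), c(5, 5, 10))
  st2 <- image_stack(v2, spacing = c(0.2, 0.2, 1))
  expect_true(all(average_projection(st2, z_extent = 10)$pixels == 5.5))
  expect_error(average_projection(st2, z_extent = 30), "exceeds")
  # variance of a noise-only projection is about noise_sd^2 / n_planes
  withr::local_seed(8)
  n <- array(rnorm(50 * 50 * 16, 0, 2), c(50, 50, 16))
  pj <- average_projection(image_stack(n, spacing = c(0.2, 0.2, 0.5)),
                           z_extent = 8)
  expect_lt(abs(var(as.vector(pj$pixels)) - 4 / 16) / (4 / 16), 0.15)
})

test_that("roi_mean uses the half-open pixel-centre convention", {
  img <- image2d(matrix(3, 20, 20), c(0.5, 0.5))
  expect_equal(roi_mean(img, roi_rect(1, 1, 5, 5)), 3)
  # pixels are indexed [x, y]: split the image along x
  half <- image2d(rbind(matrix(0, 10, 10), matrix(100, 10, 10)), c(1, 1))
  expect_equal(roi_mean(half, roi_rect(5, 2, 10, 5)), 50)
  expect_error(roi_mean(img, roi_rect(8, 8, 5, 5)), "outside")
  # adjacent half-open ROIs tile the image with no pixel counted twice
  a <- roi_mean(half, roi_rect(0, 0, 10, 10))
  b <- roi_mean(half, roi_rect(10, 0, 10, 10))
  expect_equal((a + b) / 2, mean(half$pixels))
  expect_equal(a, 0)
  expect_equal(b, 100)
})

test_that("region normalization divides by the mean of the flanking means", {
  lay <- list(mhbc = roi_rect(55, 5, 40, 50),
              midbrain = roi_rect(5, 5, 40, 50),
              hindbrain = roi_rect(105, 5, 40, 50))
  img <- average_projection(
    generate_region_intensity_stack(80, 100, 60, lay), z_extent = 10)
  r <- normalized_region_intensity(img, lay$mhbc, lay$midbrain, lay$hindbrain)
  expect_equal(r$normalized_mhbc, 1)
  img2 <- average_projection(
    generate_region_intensity_stack(60, 100, 100, lay), z_extent = 10)
  r2 <- normalized_region_intensity(img2, lay$mhbc, lay$midbrain, lay$hindbrain)
  expect_equal(r2$normalized_mhbc, 0.6)
  # uniform image -> 1 for any layout
  ru <- normalized_region_intensity(image2d(matrix(42, 800, 300), c(0.2, 0.2)),
                                    lay$mhbc, lay$midbrain, lay$hindbrain)
  expect_equal(ru$normalized_mhbc, 1)
  expect_warning(
    normalized_region_intensity(img, lay$mhbc, roi_rect(50, 5, 40, 50),
                                lay$hindbrain), "overlap")
})

test_that("polarity ratios divide apical and basal boxes by the middle box", {
  img <- image2d(matrix(100, 150, 300), c(0.2, 0.2))
  boxes <- polarity_boxes(15, 5, 55)
  img$pixels[, 1:100] <- 90    # apical third
  img$pixels[, 201:300] <- 50  # basal third
  pr <- polarity_ratios(img, boxes$apical, boxes$middle, boxes$basal)
  expect_equal(pr$apical_ratio, 0.9)
  expect_equal(pr$basal_ratio, 0.5)
  # uniform image -> both ratios 1
  pu <- polarity_ratios(image2d(matrix(5, 150, 300), c(0.2, 0.2)),
                        boxes$apical, boxes$middle, boxes$basal)
  expect_equal(pu$apical_ratio, 1)
  expect_equal(pu$basal_ratio, 1)
})

test_that("polarity ratios on a linear gradient match the analytic means", {
  # intensity f(y) = 2 + 3 y; box means equal f at the box centres
  ny <- 400
  img <- image2d(outer(rep(1, 100), 2 + 3 * ((1:ny) - 0.5) * 0.2), c(0.2, 0.2))
  boxes <- polarity_boxes(10, 10, 70, box_area_um2 = 16)
  pr <- polarity_ratios(img, boxes$apical, boxes$middle, boxes$basal)
  f <- function(y) 2 + 3 * y
  expect_equal(pr$apical_ratio, f(20) / f(40), tolerance = 1e-10)
  expect_equal(pr$basal_ratio, f(60) / f(40), tolerance = 1e-10)
})

test_that("normalizations are invariant to intensity scaling", {
  lay <- list(mhbc = roi_rect(55, 5, 40, 50),
              midbrain = roi_rect(5, 5, 40, 50),
              hindbrain = roi_rect(105, 5, 40, 50))
  img <- average_projection(
    generate_region_intensity_stack(83, 91, 57, lay, noise_sd = 3, seed = 5),
    z_extent = 10)
  r0 <- normalized_region_intensity(img, lay$mhbc, lay$midbrain, lay$hindbrain)
  boxes <- polarity_boxes(20, 5, 55)
  p0 <- polarity_ratios(img, boxes$apical, boxes$middle, boxes$basal)
  for (k in c(0.5, 2, 10)) {
    sc <- image2d(img$pixels * k, img$pixel_spacing)
    rk <- normalized_region_intensity(sc, lay$mhbc, lay$midbrain, lay$hindbrain)
    expect_equal(rk$normalized_mhbc, r0$normalized_mhbc, tolerance = 1e-12)
    pk <- polarity_ratios(sc, boxes$apical, boxes$middle, boxes$basal)
    expect_equal(pk$basal_ratio, p0$basal_ratio, tolerance = 1e-12)
    expect_equal(pk$apical_ratio, p0$apical_ratio, tolerance = 1e-12)
  }
})

test_that("band normalization follows the loading control", {
  b <- band_normalize(50, 100, control_value = 1)
  expect_equal(b$normalized_level, 0.5)
  expect_equal(b$percent_of_control, 50)     # the ~50% knockdown reading
  expect_equal(band_normalize(80, 80)$percent_of_control, 100)
  expect_error(band_normalize(10, 0), "loading_band")
})
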