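test_that("membrane_cytoplasm_ratio computes pooled disc-mean ratios", {
  img <- pixel_image(matrix(77, 120, 120), 0.1)
  on <- list(disc_roi(30, 30, 1.5), disc_roi(60, 30, 1.5))
  off <- list(disc_roi(30, 80, 1.5), disc_roi(60, 80, 1.5))
  r <- membrane_cytoplasm_ratio(img, on, off)
  expect_equal(r$ratio, 1.0)
  expect_equal(r$log2_ratio, 0.0)

  # constructed 200 AU on-discs over 100 AU off-discs
  v <- matrix(100, 120, 120)
  for (d in on) v[disc_mask(img, d)] <- 200
  img2 <- pixel_image(v, 0.1)
  r2 <- membrane_cytoplasm_ratio(img2, on, off)
  expect_equal(r2$ratio, 2.0)
  expect_equal(r2$log2_ratio, 1.0)

  expect_error(membrane_cytoplasm_ratio(pixel_image(matrix(0, 120, 120), 0.1),
                                        on, off), "zero")
})

test_that("membrane_cytoplasm_ratio matches the brute-force masked-mean oracle", {
  set.seed(7)
  for (rep in 1:8) {
    spec <- make_test_scene_spec(noise_sd = 15, seed = 100L + rep)
    scene <- generate_coelomocyte(spec)
    img <- scene$channels[[1]]
    discs <- place_measurement_discs(img, scene$truth$cell,
                                     scene$truth$endosome_rois,
                                     seed = 200L + rep)
    r <- membrane_cytoplasm_ratio(img, discs$on_discs, discs$off_discs)
    om <- function(d) oracle_disc_mean(img$values, img$pixel_size_um,
                                       d$center_x, d$center_y, d$radius_um)$mean
    expected <- mean(sapply(discs$on_discs, om)) /
      mean(sapply(discs$off_discs, om))
    expect_equal(r$ratio, expected, tolerance = 1e-12)
  }
})

test_that("microdomain_spread obeys its boundary cases and recovers arc coverage", {
  p_hi <- angular_profile((0:99) * 3.6, rep(100, 100))
  expect_equal(microdomain_spread(p_hi, 50)$fraction_above, 1.0)
  expect_equal(microdomain_spread(p_hi, 100)$fraction_above, 0.0)  # strict >

  for (cov in c(0.1, 0.5)) {
    spec <- make_test_scene_spec(arc_coverage = cov)
    scene <- generate_coelomocyte(spec)
    profs <- lapply(scene$truth$endosome_rois, function(r)
      circle_profile(scene$channels[[1]], r, n_samples = 360))
    sp <- microdomain_spread(profs, (150 + 400) / 2)
    expect_lt(abs(sp$fraction_above - cov), 1 / 360 + 0.02)
    expect_equal(sp$n_endosomes_averaged, 3L)
  }
})

test_that("microdomain_spread is non-increasing in the threshold", {
  spec <- make_test_scene_spec(arc_coverage = 0.4, noise_sd = 20, seed = 8L)
  scene <- generate_coelomocyte(spec)
  profs <- lapply(scene$truth$endosome_rois, function(r)
    circle_profile(scene$channels[[1]], r))
  fr <- sapply(seq(50, 450, by = 25), function(t)
    microdomain_spread(profs, t)$fraction_above)
  expect_true(all(diff(fr) <= 0))
})

test_that("interior_peripheral_ratio reproduces the documented log2 semantics", {
  two_in <- make_interior_peripheral_image(2)
  expect_equal(interior_peripheral_ratio(two_in$image, two_in$cell,
                                         two_in$threshold)$log2_ratio, 1.0)
  equal <- make_interior_peripheral_image(1)
  expect_equal(interior_peripheral_ratio(equal$image, equal$cell,
                                         equal$threshold)$log2_ratio, 0.0)
  two_out <- make_interior_peripheral_image(0.5)
  expect_equal(interior_peripheral_ratio(two_out$image, two_out$cell,
                                         two_out$threshold)$log2_ratio, -1.0)
})

test_that("interior_peripheral_ratio: antisymmetry, scale invariance, empty-region error", {
  a <- make_interior_peripheral_image(3.7)
  b <- make_interior_peripheral_image(1 / 3.7)
  la <- interior_peripheral_ratio(a$image, a$cell, a$threshold)$log2_ratio
  lb <- interior_peripheral_ratio(b$image, b$cell, b$threshold)$log2_ratio
  expect_equal(la, -lb, tolerance = 1e-12)

  scaled <- pixel_image(a$image$values * 7.3, a$image$pixel_size_um)
  ls <- interior_peripheral_ratio(scaled, a$cell, a$threshold * 7.3)$log2_ratio
  expect_equal(ls, la, tolerance = 1e-12)

  dark <- pixel_image(matrix(1, 160, 160), 0.1)
  expect_error(interior_peripheral_ratio(dark, a$cell, 10), "ratio undefined")
})

test_that("thresholded_pearson matches the direct-formula oracle and its bounds", {
  set.seed(11)
  v1 <- matrix(runif(80 * 80, 0, 300), 80, 80)
  v2 <- 0.6 * v1 + matrix(rnorm(80 * 80, 0, 30), 80, 80)
  v2 <- pmax(v2, 0)
  ch1 <- pixel_image(v1, 0.1); ch2 <- pixel_image(v2, 0.1)

  cc <- thresholded_pearson(ch1, ch2, t1 = 120, t2 = 90)
  keep <- v1 > 120 | v2 > 90
  expect_equal(cc$pearson_r, oracle_pearson(v1[keep], v2[keep]),
               tolerance = 1e-12)
  expect_equal(cc$n_pixels, sum(keep))

  # identical / complemented channels
  expect_equal(thresholded_pearson(ch1, ch1, t1 = 50, t2 = 50)$pearson_r, 1.0)
  comp <- pixel_image(300 - v1, 0.1)
  expect_equal(thresholded_pearson(ch1, comp, t1 = 50, t2 = 50)$pearson_r,
               -1.0)

  # intersection rule restricts the pixel set
  ci <- thresholded_pearson(ch1, ch2, t1 = 120, t2 = 90,
                            include = "intersection")
  expect_equal(ci$n_pixels, sum(v1 > 120 & v2 > 90))

  flat <- pixel_image(matrix(c(rep(0, 50), rep(10, 6350)), 80, 80), 0.1)
  expect_error(thresholded_pearson(flat, flat, t1 = 5, t2 = 5),
               "zero variance")
})

test_that("thresholded_pearson and membrane ratio are scale invariant", {
  spec <- make_test_scene_spec(noise_sd = 10, seed = 17L, n_channels = 2L)
  scene <- generate_coelomocyte(spec)
  ch1 <- scene$channels[[1]]; ch2 <- scene$channels[[2]]
  k <- 4.25
  s1 <- pixel_image(ch1$values * k, 0.1); s2 <- pixel_image(ch2$values * k, 0.1)
  r0 <- thresholded_pearson(ch1, ch2, t1 = 120, t2 = 120)$pearson_r
  r1 <- thresholded_pearson(s1, s2, t1 = 120 * k, t2 = 120 * k)$pearson_r
  expect_equal(r1, r0, tolerance = 1e-12)

  discs <- place_measurement_discs(ch1, scene$truth$cell,
                                   scene$truth$endosome_rois, seed = 3L)
  m0 <- membrane_cytoplasm_ratio(ch1, discs$on_discs, discs$off_discs)$ratio
  m1 <- membrane_cytoplasm_ratio(s1, discs$on_discs, discs$off_discs)$ratio
  expect_equal(m1, m0, tolerance = 1e-12)
})

test_that("mean_intensity_above_threshold handles full, empty and mixed regions", {
  img <- pixel_image(matrix(50, 40, 40), 0.1)
  all_m <- matrix(TRUE, 40, 40)
  r <- mean_intensity_above_threshold(img, all_m, 10)
  expect_equal(r$mean, 50)
  expect_equal(r$n_pixels, 1600L)

  r0 <- mean_intensity_above_threshold(img, all_m, 50)  # strict >
  expect_true(r0$empty)
  expect_equal(r0$n_pixels, 0L)
  expect_true(is.na(r0$mean))

  set.seed(23)
  v <- matrix(runif(1600, 0, 100), 40, 40)
  rm_ <- mean_intensity_above_threshold(pixel_image(v, 0.1), all_m, 60)
  expect_equal(rm_$mean, mean(v[v > 60]), tolerance = 1e-12)

  expect_error(mean_intensity_above_threshold(img, matrix(FALSE, 40, 40), 1),
               "empty")
})

test_that("cell_area converts pixel counts and approximates disc area", {
  expect_equal(cell_area(matrix(FALSE, 10, 10), 0.1), 0)
  m <- matrix(FALSE, 20, 20); m[1:10, 1:10] <- TRUE
  expect_equal(cell_area(m, 0.1), 1.0)
  img <- pixel_image(matrix(0, 101, 101), 1)
  dm <- disc_mask(img, disc_roi(50, 50, 22))
  expect_lt(abs(cell_area(dm, 1) - pi * 22^2) / (pi * 22^2), 0.02)
})

test_that("fiber_length measures skeleton path length per component", {
  m <- matrix(FALSE, 20, 30)
  m[10, 5:15] <- TRUE                       # 11-px horizontal line
  expect_equal(fiber_length(m, 0.1), 1.0)

  d <- matrix(FALSE, 20, 20)
  for (i in 0:10) d[5 + i, 5 + i] <- TRUE   # 11-px diagonal
  expect_equal(fiber_length(d, 0.1), 10 * sqrt(2) * 0.1, tolerance = 1e-12)

  expect_identical(fiber_length(matrix(FALSE, 5, 5), 0.1), numeric(0))

  # two components -> two lengths; a 3-px-thick bar thins to ~its length
  both <- matrix(FALSE, 40, 40)
  both[5, 2:12] <- TRUE
  both[20:22, 5:30] <- TRUE
  lens <- sort(fiber_length(both, 0.1))
  expect_length(lens, 2L)
  expect_equal(lens[1], 1.0)
  expect_gt(lens[2], 0.8 * 2.5)
  expect_lt(lens[2], 1.1 * 2.6)
})
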