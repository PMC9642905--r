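test_that("disc_mask selects pixel centers within the radius", {
  img <- pixel_image(matrix(0, 51, 51), 1)
  # radius 0.5 px centered on a pixel center -> exactly that pixel
  m <- disc_mask(img, disc_roi(25, 25, 0.5))
  expect_equal(sum(m), 1L)
  expect_true(m[26, 26])

  # pixel-count area approximates pi r^2 for moderate radii
  for (r in c(20, 24)) {
    m <- disc_mask(img, disc_roi(25, 25, r))
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.02)
  }

  expect_error(disc_mask(img, disc_roi(500, 500, 2)), "not intersect")
})

test_that("circle_profile samples a constant image exactly and refines consistently", {
  img <- pixel_image(matrix(42, 101, 101), 0.1)
  ring <- ring_roi(50, 50, radius_um = 2, width_um = 0.5)
  p <- circle_profile(img, ring, n_samples = 64)
  expect_equal(p$intensities, rep(42, 64))
  expect_equal(p$angles_deg, (0:63) * 360 / 64)

  # smooth image: 720-sample profile decimated 2x matches the 360-sample one
  vals <- outer(0:100, 0:100, function(r, c) 100 + 20 * sin(c / 15) + 10 * cos(r / 11))
  smooth <- pixel_image(vals, 0.1)
  p360 <- circle_profile(smooth, ring, n_samples = 360)
  p720 <- circle_profile(smooth, ring, n_samples = 720)
  expect_equal(p720$intensities[seq(1, 720, by = 2)], p360$intensities,
               tolerance = 1e-10)

  expect_error(circle_profile(img, ring_roi(3, 50, 2, 0.5)), "outside")
})

test_that("circle_profile recovers rendered arc coverage and is rotation-covariant", {
  spec <- make_test_scene_spec(arc_coverage = 0.25)
  scene <- generate_coelomocyte(spec)
  n <- 360L
  prof <- circle_profile(scene$channels[[1]], scene$truth$endosome_rois[[1]],
                         n_samples = n)
  frac <- mean(prof$intensities > (150 + 400) / 2)
  expect_lt(abs(frac - 0.25), 1.5 / n + 0.02)  # angular pixelation tolerance

  # rotating every arc center by delta circularly shifts the profile
  delta <- 40
  spec_rot <- make_test_scene_spec(arc_coverage = 0.25,
                                   arc_center_deg = c(90, 210, 330) + delta)
  scene_rot <- generate_coelomocyte(spec_rot)
  prof_rot <- circle_profile(scene_rot$channels[[1]],
                             scene_rot$truth$endosome_rois[[1]], n_samples = n)
  shift <- delta * n / 360
  shifted <- c(prof_rot$intensities[(shift + 1):n], prof_rot$intensities[1:shift])
  # compare thresholded occupancy patterns, allowing pixelation at arc edges
  agree <- mean((shifted > 275) == (prof$intensities > 275))
  expect_gt(agree, 0.97)
})

test_that("split_equal_area partitions the cell into equal-area regions", {
  cell <- disc_roi(80, 80, 100)
  parts <- split_equal_area(cell)
  expect_equal(parts$interior$radius_um, 100 / sqrt(2))

  img <- pixel_image(matrix(0, 161, 161), 1)
  cell_px <- disc_roi(80, 80, 60)
  parts <- split_equal_area(cell_px)
  m_in <- disc_mask(img, parts$interior)
  m_out <- annulus_mask(img, parts$peripheral)
  m_cell <- disc_mask(img, cell_px)
  expect_false(any(m_in & m_out))            # disjoint
  expect_equal(m_in | m_out, m_cell)         # union is the cell disc
  expect_lt(abs(sum(m_in) - sum(m_out)) / sum(m_cell), 0.01)
})

test_that("place_measurement_discs is deterministic and avoids endosome rings", {
  spec <- make_test_scene_spec()
  scene <- generate_coelomocyte(spec)
  img <- scene$channels[[1]]
  d1 <- place_measurement_discs(img, scene$truth$cell,
                                scene$truth$endosome_rois, seed = 11)
  d2 <- place_measurement_discs(img, scene$truth$cell,
                                scene$truth$endosome_rois, seed = 11)
  expect_identical(d1, d2)
  expect_length(d1$on_discs, 3)
  expect_length(d1$off_discs, 3)
  # each on-disc sits on a distinct endosome center
  for (i in 1:3) {
    expect_equal(d1$on_discs[[i]]$center_x,
                 scene$truth$endosome_rois[[i]]$center_x)
  }
  # off-discs contain no ring pixels (ground-truth mask intersection)
  ring_px <- Reduce(`|`, lapply(scene$truth$endosome_rois,
                                function(r) ring_mask(img, r)))
  for (d in d1$off_discs)
    expect_false(any(disc_mask(img, d) & ring_px))

  # impossible placement errors out with the constraint
  tiny_cell <- disc_roi(127.5, 127.5, 2)
  expect_error(
    place_measurement_discs(img, tiny_cell, scene$truth$endosome_rois,
                            n_off = 3, disc_diameter_um = 3, seed = 1,
                            max_tries = 50),
    "could not place")
})

test_that("otsu_threshold maximizes between-class variance", {
  img <- pixel_image(matrix(c(rep(10, 50), rep(200, 50)), 10, 10), 1)
  t0 <- otsu_threshold(img)
  expect_gt(t0, 10)
  expect_lt(t0, 200)

  # invariant under duplication of the data
  v <- c(rep(10, 30), rep(60, 20), rep(200, 50))
  expect_equal(otsu_threshold(matrix(v, 10, 10)),
               otsu_threshold(matrix(rep(v, 2), 20, 10)))

  # matches the exhaustive search oracle on a 16-bin histogram
  set.seed(4)
  vals <- c(rnorm(300, 40, 6), rnorm(200, 160, 12))
  vals <- vals[vals > 0]
  expect_equal(otsu_threshold(matrix(vals, ncol = 1), n_bins = 16L),
               oracle_otsu_binned(vals, 16L), tolerance = 1e-12)

  expect_error(otsu_threshold(matrix(5, 4, 4)), "fewer than 2 distinct")
})
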