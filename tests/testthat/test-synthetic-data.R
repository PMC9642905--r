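test_that("noise-free scenes are piecewise constant with the stated levels", {
  spec <- scene_spec(image_shape = c(128L, 128L), pixel_size_um = 0.1,
                     cell_radius_um = 5, nucleus_radius_um = 1.5,
                     nucleus_intensity = 20, cytoplasm_intensity = 100,
                     background_intensity = 10, endosomes = list(),
                     noise_sd = 0)
  scene <- generate_coelomocyte(spec)
  v <- scene$channels[[1]]$values
  d <- sqrt(outer((0:127 - 63.5)^2, (0:127 - 63.5)^2, `+`))
  expect_true(all(v[t(d) > 50] == 10))                 # background
  expect_true(all(v[t(d) <= 50 & t(d) > 15] == 100))   # cytoplasm
  expect_true(all(v[t(d) <= 15] == 20))                # nucleus
  expect_setequal(unique(as.numeric(v)), c(10, 100, 20))
})

test_that("rendered arcs occupy the specified fraction of the ring", {
  for (cov in c(0.25, 0.6)) {
    spec <- make_test_scene_spec(arc_coverage = cov)
    scene <- generate_coelomocyte(spec)
    img <- scene$channels[[1]]
    for (ring in scene$truth$endosome_rois) {
      m <- ring_mask(img, ring)
      frac <- mean(img$values[m] > (150 + 400) / 2)
      expect_lt(abs(frac - cov), 0.05)  # full-ring pixel fraction
    }
  }
})

test_that("scene generation is bit-identical under a fixed seed and validates placement", {
  spec <- make_test_scene_spec(noise_sd = 8, seed = 99L)
  s1 <- generate_coelomocyte(spec)
  s2 <- generate_coelomocyte(spec)
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$truth$arc_table, s2$truth$arc_table)

  bad <- scene_spec(cell_radius_um = 5, nucleus_radius_um = 1,
                    endosomes = list(
                      endosome_spec(127.5, 127.5, 1, 0.3),
                      endosome_spec(250, 30, 1, 0.3)))
  expect_error(generate_coelomocyte(bad), "endosome 2")
})

test_that("added noise has the stated standard deviation and clips at zero", {
  spec <- scene_spec(image_shape = c(200L, 200L), cell_radius_um = 8,
                     nucleus_radius_um = 2, cytoplasm_intensity = 500,
                     background_intensity = 400, noise_sd = 12, seed = 3L)
  base <- scene_spec(image_shape = c(200L, 200L), cell_radius_um = 8,
                     nucleus_radius_um = 2, cytoplasm_intensity = 500,
                     background_intensity = 400, noise_sd = 0)
  noisy <- generate_coelomocyte(spec)$channels[[1]]$values
  clean <- generate_coelomocyte(base)$channels[[1]]$values
  resid <- (noisy - clean)[clean > 0]  # far from the zero clip
  expect_gt(length(resid), 1e4)
  expect_lt(abs(sd(resid) - 12) / 12, 0.05)
  expect_true(all(noisy >= 0))
})

test_that("FRAP series follows the closed-form recovery in the bleach ROI", {
  # mobile_fraction = 1, tau = one frame interval, no fade, no noise
  spec <- frap_spec(n_frames = 30L, frame_interval_s = 1, bleach_frame = 5L,
                    prebleach_intensity = 200, bleach_depth = 0.8,
                    mobile_fraction = 1, tau_s = 1,
                    acquisition_bleach_rate = 0, noise_sd = 0)
  series <- generate_frap_series(spec)
  curve <- extract_frap_curve(series)
  bg <- spec$background_intensity
  for (k in 0:10) {
    expected <- 200 - 0.8 * 200 * exp(-k)
    expect_equal(curve$bleach_mean[5 + k] - bg, expected, tolerance = 1e-10)
  }
  # closed-form oracle agrees with the generator at arbitrary parameters
  spec2 <- frap_spec(mobile_fraction = 0.6, tau_s = 7, bleach_depth = 0.5,
                     n_frames = 40L)
  c2 <- extract_frap_curve(generate_frap_series(spec2))
  t_after <- (0:5) * spec2$frame_interval_s
  expect_equal(c2$bleach_mean[spec2$bleach_frame + 0:5] - bg,
               oracle_frap_value(200, 0.5, 0.6, 7, t_after),
               tolerance = 1e-10)
})

test_that("immobile FRAP series stays flat and seeded runs are identical", {
  spec <- frap_spec(mobile_fraction = 0, noise_sd = 0,
                    acquisition_bleach_rate = 0.02)
  series <- generate_frap_series(spec)
  curve <- extract_frap_curve(series)
  fade <- (1 - 0.02)^(seq_along(curve$times_s) - 1L)
  corrected <- (curve$bleach_mean - spec$background_intensity) / fade
  post <- spec$bleach_frame:spec$n_frames
  expect_equal(corrected[post], rep(corrected[post[1]], length(post)),
               tolerance = 1e-10)

  noisy <- frap_spec(noise_sd = 3, seed = 12L)
  expect_identical(generate_frap_series(noisy)$frames,
                   generate_frap_series(noisy)$frames)
})

test_that("sequence fixtures plant scannable IWN motifs", {
  spec <- sequence_fixture_spec(n_sequences = 6L, length = 400L,
                                planted_motifs_per_sequence = 3L, seed = 21L)
  fx <- generate_sequence_fixtures(spec)
  expect_length(fx$sequences, 6L)
  for (i in seq_along(fx$sequences)) {
    id <- names(fx$sequences)[i]
    hits <- scan_iwn(as.character(fx$sequences[[i]]))
    planted <- fx$planted$position[fx$planted$seq_id == id]
    expect_gte(nrow(hits), 3L)
    expect_true(all(planted %in% hits$position))
  }
  # determinism
  fx2 <- generate_sequence_fixtures(spec)
  expect_identical(as.character(fx$sequences), as.character(fx2$sequences))
  expect_identical(fx$planted, fx2$planted)

  # tryptophan-free alphabet with no planting -> no motifs anywhere
  aa_no_w <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "W")
  spec0 <- sequence_fixture_spec(
    n_sequences = 4L, length = 300L, planted_motifs_per_sequence = 0L,
    alphabet_frequencies = setNames(rep(1, 19), aa_no_w), seed = 5L)
  fx0 <- generate_sequence_fixtures(spec0)
  for (s in as.character(fx0$sequences))
    expect_equal(nrow(scan_iwn(s)), 0L)

  expect_error(sequence_fixture_spec(length = 10L,
                                     planted_motifs_per_sequence = 5L),
               "too short")
})

test_that("generated BLAST tables carry exactly the planted pass count", {
  for (frac in c(0, 0.4, 1)) {
    bt <- generate_blast_table(100L, frac, seed = 31L)
    expect_equal(nrow(bt$table), 100L)
    expect_equal(bt$n_expected_pass, round(100 * frac))
    expect_equal(nrow(filter_blast(bt$table)), bt$n_expected_pass)
  }
  expect_identical(generate_blast_table(50L, 0.5, seed = 2L)$table,
                   generate_blast_table(50L, 0.5, seed = 2L)$table)
})
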