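# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: plain loops and textbook formulas only.

# masked mean by explicit loop over pixels with a distance test
oracle_disc_mean <- function(values, pixel_size_um, cx, cy, radius_um) {
  acc <- 0; n <- 0L
  r_px <- radius_um / pixel_size_um
  for (row in seq_len(nrow(values))) {
    for (col in seq_len(ncol(values))) {
      x <- col - 1L; y <- row - 1L
      if ((x - cx)^2 + (y - cy)^2 <= r_px^2) {
        acc <- acc + values[row, col]
        n <- n + 1L
      }
    }
  }
  list(mean = acc / n, n = n)
}

# textbook Pearson correlation from sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  sa <- sum(a); sb <- sum(b)
  (n * sum(a * b) - sa * sb) /
    sqrt((n * sum(a^2) - sa^2) * (n * sum(b^2) - sb^2))
}

# exhaustive 4-residue window enumeration for the IWN motif
oracle_scan_iwn <- function(s, hydrophilic = "STNQDEKRH") {
  chars <- strsplit(s, "")[[1]]
  hyd <- strsplit(hydrophilic, "")[[1]]
  hits <- integer(0)
  if (length(chars) >= 4L) {
    for (i in seq_len(length(chars) - 3L)) {
      if (chars[i] %in% c("I", "L", "V") && chars[i + 1L] == "W" &&
          chars[i + 2L] %in% hyd && chars[i + 3L] %in% hyd)
        hits <- c(hits, i)
    }
  }
  hits
}

# exhaustive between-class variance search over a prebinned histogram
oracle_otsu_binned <- function(values, n_bins) {
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best <- -Inf; best_k <- integer(0)
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    bcv <- (w0 / sum(counts)) * (w1 / sum(counts)) * (mu0 - mu1)^2
    if (bcv > best * (1 + 1e-12)) {
      best <- bcv; best_k <- k
    } else if (abs(bcv - best) <= best * 1e-12) {
      best_k <- c(best_k, k)  # tie: variance plateau across empty bins
    }
  }
  # ties resolve to the mean of the maximizing split positions
  mean(breaks[best_k + 1L])
}

# closed-form single-exponential recovery evaluated pointwise
oracle_frap_value <- function(prebleach, depth, mobile, tau, t_after) {
  floor_i <- prebleach * (1 - depth)
  floor_i + (prebleach - floor_i) * mobile * (1 - exp(-t_after / tau))
}

# standard test scene: one cell, three peripheral endosomes with a common
# arc coverage; contrast between ring (150 AU) and arc (400 AU)
make_test_scene_spec <- function(arc_coverage = 0.25, noise_sd = 0,
                                 seed = 1L, n_channels = 1L,
                                 arc_center_deg = c(90, 210, 330)) {
  angles <- c(20, 140, 260) * pi / 180
  endos <- lapply(seq_along(angles), function(i) {
    a <- angles[i]
    endosome_spec(center_x = 127.5 + 70 * cos(a),
                  center_y = 127.5 - 70 * sin(a),
                  radius_um = 1.5, ring_width_um = 0.4,
                  ring_intensity = 150,
                  arc_center_deg = arc_center_deg[i],
                  arc_coverage = arc_coverage, arc_intensity = 400)
  })
  scene_spec(image_shape = c(256L, 256L), pixel_size_um = 0.1,
             cell_radius_um = 12, nucleus_radius_um = 3,
             cytoplasm_intensity = 100, background_intensity = 10,
             endosomes = endos, noise_sd = noise_sd,
             n_channels = n_channels, seed = seed)
}

# paint an image where the interior / peripheral equal-area regions carry
# above-threshold integrated intensity in an exact given proportion
make_interior_peripheral_image <- function(fold_interior, threshold = 10,
                                           radius_px = 60, shape = 160L) {
  img0 <- pixel_image(matrix(0, shape, shape), 0.1)
  cell <- disc_roi((shape - 1) / 2, (shape - 1) / 2, radius_px * 0.1)
  parts <- split_equal_area(cell)
  m_in <- disc_mask(img0, parts$interior)
  m_out <- annulus_mask(img0, parts$peripheral)
  vals <- matrix(0, shape, shape)
  b <- threshold * 10                         # peripheral pixel value
  a <- fold_interior * b * sum(m_out) / sum(m_in)  # interior pixel value
  vals[m_out] <- b
  vals[m_in] <- a
  list(image = pixel_image(vals, 0.1), cell = cell, threshold = threshold)
}
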