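#' Boolean mask of a disc ROI
#'
#' A pixel is inside the disc iff its center lies within `radius_um` of the
#' disc center. Pure pixel-center inclusion, no anti-aliasing: the mask is
#' the unit on which all disc measurements (means, integrated intensities,
#' areas) are computed.
#'
#' @param image a [pixel_image()] (supplies shape and pixel size).
#' @param roi a [disc_roi()].
#' @return Logical matrix with the image's dimensions.
#' @export
disc_mask <- function(image, roi) {
  stopifnot(inherits(image, "pixel_image"), inherits(roi, "disc_roi"))
  nr <- nrow(image$values); nc <- ncol(image$values)
  r_px <- roi$radius_um / image$pixel_size_um
  m <- .dist2_grid(nr, nc, roi$center_x, roi$center_y) <= r_px^2
  if (!any(m))
    stop("disc ROI does not intersect the image")
  m
}

#' Boolean mask of a ring ROI
#'
#' A pixel belongs to the ring iff its center's distance from the ring
#' center differs from the nominal radius by at most half the ring width.
#'
#' @param image a [pixel_image()].
#' @param roi a [ring_roi()].
#' @return Logical matrix with the image's dimensions.
#' @export
ring_mask <- function(image, roi) {
  stopifnot(inherits(image, "pixel_image"), inherits(roi, "ring_roi"))
  nr <- nrow(image$values); nc <- ncol(image$values)
  d <- sqrt(.dist2_grid(nr, nc, roi$center_x, roi$center_y))
  r_px <- roi$radius_um / image$pixel_size_um
  w_px <- roi$width_um / image$pixel_size_um
  abs(d - r_px) <= w_px / 2
}

# bilinear interpolation of image values at fractional (x, y) pixel coords
.bilinear <- function(values, x, y) {
  nr <- nrow(values); nc <- ncol(values)
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 0), nc - 2L)
  y0 <- pmin(pmax(y0, 0), nr - 2L)
  fx <- x - x0; fy <- y - y0
  i00 <- values[cbind(y0 + 1L, x0 + 1L)]
  i01 <- values[cbind(y0 + 1L, x0 + 2L)]
  i10 <- values[cbind(y0 + 2L, x0 + 1L)]
  i11 <- values[cbind(y0 + 2L, x0 + 2L)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

#' Circumferential line scan around an endosome ring
#'
#' Samples the image along the circle of the ring's nominal radius at
#' `n_samples` equally spaced angles (degrees counter-clockwise from the
#' +x axis), by bilinear interpolation. This is the "line scan around the
#' circumference" on which microdomain spread is measured. With
#' `width_average = TRUE` each angular sample is instead the mean of
#' bilinear samples taken across the ring width (the scan-width choice is
#' not standardized in the field; single-pixel is the default).
#'
#' @param image a [pixel_image()].
#' @param roi a [ring_roi()] fully inside the image.
#' @param n_samples number of angular samples (>= 8). Default one sample
#'   per circumference pixel, `ceiling(2 * pi * radius_px)`.
#' @param width_average if `TRUE`, average radially over the ring width at
#'   each angle (5 radial taps).
#' @return An [angular_profile()].
#' @export
circle_profile <- function(image, roi, n_samples = NULL, width_average = FALSE) {
  stopifnot(inherits(image, "pixel_image"), inherits(roi, "ring_roi"))
  r_px <- roi$radius_um / image$pixel_size_um
  w_px <- roi$width_um / image$pixel_size_um
  if (is.null(n_samples)) n_samples <- max(8L, ceiling(2 * pi * r_px))
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) stop("n_samples must be >= 8")
  nr <- nrow(image$values); nc <- ncol(image$values)
  r_out <- r_px + w_px / 2
  if (roi$center_x - r_out < 0 || roi$center_x + r_out > nc - 1 ||
      roi$center_y - r_out < 0 || roi$center_y + r_out > nr - 1)
    stop("ring extends outside the image")
  theta <- (0:(n_samples - 1L)) * 360 / n_samples
  rad <- theta * pi / 180
  sample_at <- function(r) {
    x <- roi$center_x + r * cos(rad)
    y <- roi$center_y - r * sin(rad)   # y axis points down; CCW angles
    .bilinear(image$values, x, y)
  }
  if (width_average) {
    taps <- seq(r_px - w_px / 2, r_px + w_px / 2, length.out = 5L)
    ints <- rowMeans(vapply(taps, sample_at, numeric(n_samples)))
  } else {
    ints <- sample_at(r_px)
  }
  angular_profile(theta, ints)
}

#' Split a cell disc into two equal-area regions
#'
#' Divides the coelomocyte disc into an interior disc and a peripheral
#' annulus of equal geometric area: the interior radius is the cell radius
#' divided by sqrt(2). The two mask regions partition the cell disc mask
#' exactly (every cell pixel is in exactly one region).
#'
#' @param cell a [disc_roi()] describing the whole cell.
#' @return A list with elements `interior` (a [disc_roi()]) and
#'   `peripheral` (a list with class `annulus_roi`: `center_x`, `center_y`,
#'   `inner_radius_um`, `outer_radius_um`).
#' @export
split_equal_area <- function(cell) {
  stopifnot(inherits(cell, "disc_roi"))
  r_in <- cell$radius_um / sqrt(2)
  list(
    interior = disc_roi(cell$center_x, cell$center_y, r_in),
    peripheral = structure(
      list(center_x = cell$center_x, center_y = cell$center_y,
           inner_radius_um = r_in, outer_radius_um = cell$radius_um),
      class = "annulus_roi")
  )
}

#' Boolean mask of an annulus region
#'
#' Inclusion is half-open: `inner < d <= outer`, so that the annulus mask
#' and the interior disc mask (which uses `d <= inner`) partition the cell
#' disc with no shared or dropped pixels.
#'
#' @param image a [pixel_image()].
#' @param roi an `annulus_roi` as returned by [split_equal_area()].
#' @return Logical matrix with the image's dimensions.
#' @export
annulus_mask <- function(image, roi) {
  stopifnot(inherits(image, "pixel_image"), inherits(roi, "annulus_roi"))
  nr <- nrow(image$values); nc <- ncol(image$values)
  d <- sqrt(.dist2_grid(nr, nc, roi$center_x, roi$center_y))
  ri <- roi$inner_radius_um / image$pixel_size_um
  ro <- roi$outer_radius_um / image$pixel_size_um
  d > ri & d <= ro
}

#' Place on-endosome and off-endosome measurement discs
#'
#' Reproduces the paired-disc sampling design for the membrane/cytoplasm
#' ratio: `n_on` discs centered on distinct endosome rings and `n_off`
#' discs of the same diameter placed inside the cell while avoiding every
#' endosome ring and every other disc. Placement of off-discs is rejection
#' sampling, deterministic for a given seed.
#'
#' @param image a [pixel_image()].
#' @param cell a [disc_roi()] for the whole cell; off-discs are kept inside it.
#' @param endosomes list of [ring_roi()].
#' @param n_on number of on-endosome discs (must not exceed the number of
#'   endosomes).
#' @param n_off number of off-endosome discs.
#' @param disc_diameter_um disc diameter in micrometres (default 3, the
#'   standard measurement disc).
#' @param seed integer seed for off-disc placement.
#' @param max_tries rejection-sampling budget per off-disc.
#' @return list with `on_discs` and `off_discs`, each a list of [disc_roi()].
#' @export
place_measurement_discs <- function(image, cell, endosomes, n_on = 3L,
                                    n_off = 3L, disc_diameter_um = 3,
                                    seed = 1L, max_tries = 2000L) {
  stopifnot(inherits(image, "pixel_image"), inherits(cell, "disc_roi"))
  if (n_on > length(endosomes))
    stop(sprintf("requested %d on-discs but only %d endosomes are available",
                 n_on, length(endosomes)))
  px <- image$pixel_size_um
  disc_r_um <- disc_diameter_um / 2
  on_discs <- lapply(endosomes[seq_len(n_on)], function(e)
    disc_roi(e$center_x, e$center_y, disc_r_um))

  off_discs <- list()
  if (n_off > 0L) {
    old <- .switch_seed(seed)
    on.exit(.restore_seed(old), add = TRUE)
    disc_r_px <- disc_r_um / px
    cell_r_px <- cell$radius_um / px
    for (k in seq_len(n_off)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        # uniform in the disc of allowed centers
        u <- stats::runif(1); a <- stats::runif(1, 0, 2 * pi)
        rr <- (cell_r_px - disc_r_px) * sqrt(u)
        cx <- cell$center_x + rr * cos(a)
        cy <- cell$center_y + rr * sin(a)
        ok <- TRUE
        for (e in endosomes) {
          d <- sqrt((cx - e$center_x)^2 + (cy - e$center_y)^2)
          if (d < disc_r_px + (e$radius_um + e$width_um / 2) / px) {
            ok <- FALSE; break
          }
        }
        if (ok) for (d0 in off_discs) {
          d <- sqrt((cx - d0$center_x)^2 + (cy - d0$center_y)^2)
          if (d < 2 * disc_r_px) { ok <- FALSE; break }
        }
        if (ok) {
          off_discs[[k]] <- disc_roi(cx, cy, disc_r_um)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0("could not place off-disc %d of %d after %d tries: ",
                            "no room inside the cell avoiding all endosome ",
                            "rings and previously placed discs"),
                     k, n_off, max_tries))
    }
  }
  list(on_discs = on_discs, off_discs = off_discs)
}

#' Otsu threshold of an image region
#'
#' Maximizes the between-class variance of the masked intensity histogram.
#' Used as the default threshold source when no manual threshold is
#' supplied (acquisition-software thresholds in published workflows are
#' typically manual and unrecorded).
#'
#' @param image a [pixel_image()] or numeric matrix/vector.
#' @param mask optional logical matrix restricting the histogram region.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold (AU): values strictly above it form the foreground class.
#' @export
otsu_threshold <- function(image, mask = NULL, n_bins = 256L) {
  v <- if (inherits(image, "pixel_image")) image$values else image
  v <- as.numeric(v)
  if (!is.null(mask)) v <- v[as.logical(mask)]
  v <- v[is.finite(v)]
  rng <- range(v)
  if (length(v) < 2L || rng[1] == rng[2])
    stop("Otsu threshold undefined: region has fewer than 2 distinct values")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for split after bin k (k = 1..n_bins-1)
  w0k <- w0[-n_bins]; muk <- mu[-n_bins]
  valid <- w0k > 0 & w0k < 1
  bcv <- rep(-Inf, n_bins - 1L)
  bcv[valid] <- (mu_t * w0k[valid] - muk[valid])^2 /
    (w0k[valid] * (1 - w0k[valid]))
  k <- which(bcv == max(bcv))
  # tie-break: mean of maximizing split positions (as in common practice)
  mean(breaks[k + 1L])
}

# Temporarily install a private RNG state; returns the previous .Random.seed
.switch_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
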