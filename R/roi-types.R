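#' Single-channel fluorescence image with physical pixel size
#'
#' A `pixel_image` is the carrier for every measurement in the package: a
#' rectangular grid of non-negative intensities (arbitrary fluorescence
#' units, AU) together with the physical size of one pixel in micrometres.
#' Pixel coordinates are 0-based and pixel-centered; the row index is the y
#' axis and increases downward, the column index is the x axis.
#'
#' @param values numeric matrix of intensities (AU); must be non-negative.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @return An object of class `pixel_image` with elements `values` and
#'   `pixel_size_um`.
#' @examples
#' img <- pixel_image(matrix(100, 64, 64), pixel_size_um = 0.1)
#' dim(img$values)
#' @export
pixel_image <- function(values, pixel_size_um) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || any(values < 0))
    stop("image intensities must be non-negative and finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %d x %d px, %.4g um/px, range [%.4g, %.4g] AU\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Circular disc region of interest
#'
#' Discs are the measurement regions of the membrane/cytoplasm ratio
#' (3 um diameter by default) and the interior half of the equal-area
#' cell split. Center is in 0-based pixel coordinates `(x, y)`; the radius
#' is physical (micrometres).
#'
#' @param center_x,center_y center in pixel coordinates (0-based,
#'   pixel-centered; y increases downward).
#' @param radius_um disc radius in micrometres, > 0.
#' @return An object of class `disc_roi`.
#' @export
disc_roi <- function(center_x, center_y, radius_um) {
  stopifnot(is.finite(center_x), is.finite(center_y))
  if (!is.finite(radius_um) || radius_um <= 0)
    stop("disc radius_um must be > 0")
  structure(list(center_x = as.numeric(center_x),
                 center_y = as.numeric(center_y),
                 radius_um = as.numeric(radius_um)),
            class = "disc_roi")
}

#' @export
print.disc_roi <- function(x, ...) {
  cat(sprintf("<disc_roi> center (%.2f, %.2f) px, radius %.3g um\n",
              x$center_x, x$center_y, x$radius_um))
  invisible(x)
}

#' Annular (ring) region of interest
#'
#' Rings model the limiting membrane of an endosome: the circumference at
#' `radius_um` with a radial extent of `width_um`. All line-scan metrics
#' operate on rings.
#'
#' @inheritParams disc_roi
#' @param radius_um nominal (mid-line) ring radius in micrometres.
#' @param width_um radial width of the ring in micrometres; must satisfy
#'   `radius_um > width_um / 2 > 0`.
#' @return An object of class `ring_roi`.
#' @export
ring_roi <- function(center_x, center_y, radius_um, width_um) {
  stopifnot(is.finite(center_x), is.finite(center_y))
  if (!is.finite(width_um) || width_um <= 0)
    stop("ring width_um must be > 0")
  if (!is.finite(radius_um) || radius_um <= width_um / 2)
    stop("ring radius_um must exceed width_um / 2")
  structure(list(center_x = as.numeric(center_x),
                 center_y = as.numeric(center_y),
                 radius_um = as.numeric(radius_um),
                 width_um = as.numeric(width_um)),
            class = "ring_roi")
}

#' @export
print.ring_roi <- function(x, ...) {
  cat(sprintf("<ring_roi> center (%.2f, %.2f) px, radius %.3g um, width %.3g um\n",
              x$center_x, x$center_y, x$radius_um, x$width_um))
  invisible(x)
}

#' Circumferential intensity profile
#'
#' The result of a circular line scan: intensities sampled at equally
#' spaced angles covering `[0, 360)` degrees, counter-clockwise from the
#' +x image axis.
#'
#' @param angles_deg numeric vector of sample angles in degrees, equally
#'   spaced over `[0, 360)`.
#' @param intensities numeric vector of sampled intensities (AU), same
#'   length as `angles_deg`.
#' @return An object of class `angular_profile`.
#' @export
angular_profile <- function(angles_deg, intensities) {
  if (length(angles_deg) != length(intensities))
    stop("angles and intensities must have the same length")
  if (length(angles_deg) < 1L) stop("profile must be non-empty")
  d <- diff(angles_deg)
  if (length(d) > 0L && (any(d <= 0) || max(abs(d - d[1])) > 1e-9))
    stop("angles must be strictly increasing and equally spaced")
  structure(list(angles_deg = as.numeric(angles_deg),
                 intensities = as.numeric(intensities)),
            class = "angular_profile")
}

#' @export
print.angular_profile <- function(x, ...) {
  cat(sprintf("<angular_profile> %d samples, intensity range [%.4g, %.4g] AU\n",
              length(x$angles_deg), min(x$intensities), max(x$intensities)))
  invisible(x)
}

# squared pixel distances from an (x, y) point for every pixel center
.dist2_grid <- function(nr, nc, cx, cy) {
  xs <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
  (xs - cx)^2 + (ys - cy)^2
}

# pixel angle grid, degrees CCW from +x with y increasing downward, in [0, 360)
.angle_grid <- function(nr, nc, cx, cy) {
  xs <- matrix(rep(0:(nc - 1L), each = nr), nr, nc)
  ys <- matrix(rep(0:(nr - 1L), times = nc), nr, nc)
  a <- atan2(-(ys - cy), xs - cx) * 180 / pi
  (a %% 360)
}
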