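#' Specification of a synthetic FRAP time series
#'
#' Parameters of a photobleaching experiment on a fluorescent structure:
#' a bleach region whose mean intensity drops by `bleach_depth` at the
#' bleach frame and recovers as a single exponential with time constant
#' `tau_s` toward a plateau set by `mobile_fraction`, an unbleached
#' reference region, and a non-fluorescent background region. Whole-frame
#' acquisition fade (`acquisition_bleach_rate` per frame, applied
#' multiplicatively to fluorescence above background) models progressive
#' photobleaching during imaging; the double normalization must cancel it
#' exactly.
#'
#' @param n_frames total number of frames.
#' @param frame_interval_s time between frames (s).
#' @param bleach_frame 1-based index of the first post-bleach frame; at
#'   least 3 so two pre-bleach frames exist.
#' @param prebleach_intensity fluorescence of the structures before the
#'   bleach (AU).
#' @param bleach_depth fraction of bleach-region fluorescence removed by
#'   the bleach pulse, in `(0, 1]`.
#' @param mobile_fraction fraction of the bleached pool that recovers, in
#'   `[0, 1]`.
#' @param tau_s recovery time constant (s), > 0.
#' @param acquisition_bleach_rate per-frame fractional fade of all
#'   fluorescence (0 disables fade).
#' @param background_intensity camera background level (AU).
#' @param noise_sd per-pixel Gaussian noise SD (AU), clipped at 0.
#' @param seed integer seed.
#' @return An object of class `frap_spec`.
#' @export
frap_spec <- function(n_frames = 60L, frame_interval_s = 1,
                      bleach_frame = 6L, prebleach_intensity = 200,
                      bleach_depth = 0.8, mobile_fraction = 0.7,
                      tau_s = 10, acquisition_bleach_rate = 0,
                      background_intensity = 5, noise_sd = 0, seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (bleach_frame <= 2L || bleach_frame >= n_frames)
    stop("bleach_frame must lie strictly inside the series with >= 2 pre-bleach frames")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must lie in (0, 1]")
  if (acquisition_bleach_rate < 0 || acquisition_bleach_rate >= 1)
    stop("acquisition_bleach_rate must lie in [0, 1)")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_s = frame_interval_s,
                 bleach_frame = as.integer(bleach_frame),
                 prebleach_intensity = prebleach_intensity,
                 bleach_depth = bleach_depth,
                 mobile_fraction = mobile_fraction, tau_s = tau_s,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 background_intensity = background_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frap_spec")
}

#' Generate a synthetic FRAP image series with measurement ROIs
#'
#' Renders each frame as a small image containing two fluorescent discs —
#' the bleach target and an unbleached reference — on camera background.
#' The bleach-region fluorescence follows
#' `floor + (prebleach - floor) * mobile_fraction * (1 - exp(-t / tau))`
#' after the bleach (with `floor = prebleach * (1 - bleach_depth)` and `t`
#' measured from the bleach frame), the whole frame's fluorescence is
#' scaled by the per-frame acquisition fade, and seeded Gaussian noise is
#' added last.
#'
#' @param spec a [frap_spec()].
#' @return list with `frames` (list of [pixel_image()]), `times_s`,
#'   `bleach_frame`, and `rois` (list of three [disc_roi()]: `bleach`,
#'   `reference`, `background`).
#' @export
generate_frap_series <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  nr <- 40L; nc <- 120L; px <- 0.1
  centers <- list(bleach = c(20, 20), reference = c(60, 20),
                  background = c(100, 20))
  struct_r_px <- 12; roi_r_px <- 9

  bg <- spec$background_intensity
  t_post <- (seq_len(spec$n_frames) - spec$bleach_frame) * spec$frame_interval_s
  floor_i <- spec$prebleach_intensity * (1 - spec$bleach_depth)
  span <- spec$prebleach_intensity - floor_i
  bleach_f <- ifelse(
    seq_len(spec$n_frames) < spec$bleach_frame,
    spec$prebleach_intensity,
    floor_i + span * spec$mobile_fraction * (1 - exp(-t_post / spec$tau_s)))
  fade <- (1 - spec$acquisition_bleach_rate)^(seq_len(spec$n_frames) - 1L)

  d_b <- sqrt(.dist2_grid(nr, nc, centers$bleach[1], centers$bleach[2]))
  d_r <- sqrt(.dist2_grid(nr, nc, centers$reference[1], centers$reference[2]))
  in_b <- d_b <= struct_r_px
  in_r <- d_r <= struct_r_px

  old <- .switch_seed(spec$seed)
  on.exit(.restore_seed(old), add = TRUE)
  frames <- vector("list", spec$n_frames)
  for (k in seq_len(spec$n_frames)) {
    img <- matrix(bg, nr, nc)
    img[in_r] <- bg + (spec$prebleach_intensity - bg * 0) * fade[k]
    img[in_b] <- bg + bleach_f[k] * fade[k]
    if (spec$noise_sd > 0)
      img <- pmax(img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc), 0)
    frames[[k]] <- pixel_image(img, px)
  }
  rois <- list(
    bleach = disc_roi(centers$bleach[1], centers$bleach[2], roi_r_px * px),
    reference = disc_roi(centers$reference[1], centers$reference[2],
                         roi_r_px * px),
    background = disc_roi(centers$background[1], centers$background[2],
                          roi_r_px * px))
  list(frames = frames,
       times_s = (seq_len(spec$n_frames) - 1L) * spec$frame_interval_s,
       bleach_frame = spec$bleach_frame, rois = rois)
}
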