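#' FRAP measurement curve
#'
#' Frame-wise mean intensities of the bleach, reference, and background
#' regions of a FRAP series, with the bleach-frame index. This is the
#' input to normalization and fitting.
#'
#' @param times_s strictly increasing acquisition times (s).
#' @param bleach_mean,reference_mean,background_mean per-frame region
#'   means (AU), same length as `times_s`.
#' @param bleach_frame 1-based index of the first post-bleach frame.
#' @return An object of class `frap_curve`.
#' @export
frap_curve <- function(times_s, bleach_mean, reference_mean, background_mean,
                       bleach_frame) {
  n <- length(times_s)
  if (any(lengths(list(bleach_mean, reference_mean, background_mean)) != n))
    stop("all series must have the same length as times_s")
  if (any(diff(times_s) <= 0)) stop("times must be strictly increasing")
  if (bleach_frame <= 2L || bleach_frame > n)
    stop("bleach_frame must leave >= 2 pre-bleach frames")
  structure(list(times_s = as.numeric(times_s),
                 bleach_mean = as.numeric(bleach_mean),
                 reference_mean = as.numeric(reference_mean),
                 background_mean = as.numeric(background_mean),
                 bleach_frame = as.integer(bleach_frame)),
            class = "frap_curve")
}

#' Extract a FRAP curve from an image series and ROIs
#'
#' @param series a list as returned by [generate_frap_series()] (elements
#'   `frames`, `times_s`, `bleach_frame`, `rois`).
#' @return A [frap_curve()].
#' @export
extract_frap_curve <- function(series) {
  roi_means <- function(roi) vapply(series$frames, function(f)
    mean(f$values[disc_mask(f, roi)]), 0)
  frap_curve(series$times_s,
             bleach_mean = roi_means(series$rois$bleach),
             reference_mean = roi_means(series$rois$reference),
             background_mean = roi_means(series$rois$background),
             bleach_frame = series$bleach_frame)
}

#' Double-normalize a FRAP curve
#'
#' Background-subtracted, reference-corrected double normalization:
#' `F(t) = ((B(t) - bg(t)) / (R(t) - bg(t)))` divided by the mean of the
#' same quantity over the pre-bleach frames. The reference correction
#' cancels whole-frame acquisition fade exactly, and the pre-bleach mean
#' of the normalized curve is 1 by construction. With
#' `reference_correct = FALSE` a single normalization (background
#' subtraction and pre-bleach scaling only) is used instead.
#'
#' @param curve a [frap_curve()].
#' @param reference_correct apply the reference-region correction
#'   (default `TRUE`).
#' @return list of class `frap_normalized`: `times_s`, `f` (normalized
#'   series), `bleach_frame`, `prebleach_level` (1 by construction).
#' @export
normalize_frap <- function(curve, reference_correct = TRUE) {
  stopifnot(inherits(curve, "frap_curve"))
  b <- curve$bleach_mean - curve$background_mean
  if (reference_correct) {
    r <- curve$reference_mean - curve$background_mean
    if (any(r <= 0))
      stop("reference intensity at or below background; cannot normalize")
    q <- b / r
  } else {
    q <- b
  }
  pre <- seq_len(curve$bleach_frame - 1L)
  q0 <- mean(q[pre])
  if (q0 <= 0) stop("pre-bleach signal at or below background")
  structure(list(times_s = curve$times_s, f = q / q0,
                 bleach_frame = curve$bleach_frame, prebleach_level = 1),
            class = "frap_normalized")
}

#' Fit a single-exponential FRAP recovery
#'
#' Least-squares fit of `F(t) = F0 + (plateau - F0) * (1 - exp(-t / tau))`
#' to the post-bleach portion of a normalized curve, with `F0` fixed to
#' the first post-bleach value and `t` measured from the bleach frame.
#' The amplitude is profiled out analytically (it enters linearly), so the
#' optimization is a guarded one-dimensional search over `tau`. The
#' mobile fraction is `(plateau - F0) / (prebleach_level - F0)`.
#'
#' @param normalized a `frap_normalized` object from [normalize_frap()],
#'   or a numeric vector of post-bleach values (first element at the
#'   bleach frame) together with `times_s`.
#' @param times_s post-bleach times starting at 0 (only when `normalized`
#'   is a bare vector).
#' @param prebleach_level the pre-bleach plateau the recovery is measured
#'   against (1 after double normalization).
#' @return list of class `frap_fit`: `mobile_fraction`, `tau_s`,
#'   `plateau`, `f0`, `residual_sse`, `converged`. Non-convergence and
#'   pathological fits (mobile fraction outside `[0, 1.5]`, `tau` at the
#'   search boundary) are flagged, not raised.
#' @export
fit_recovery <- function(normalized, times_s = NULL, prebleach_level = 1) {
  if (inherits(normalized, "frap_normalized")) {
    post <- normalized$bleach_frame:length(normalized$f)
    y <- normalized$f[post]
    t <- normalized$times_s[post] - normalized$times_s[post[1]]
    prebleach_level <- normalized$prebleach_level
  } else {
    y <- as.numeric(normalized)
    t <- as.numeric(times_s)
  }
  if (length(y) < 4L) stop("need >= 4 post-bleach points to fit")
  f0 <- y[1]
  dy <- y - f0
  sse_at <- function(tau) {
    g <- 1 - exp(-t / tau)
    s2 <- sum(g^2)
    a <- if (s2 > 0) sum(g * dy) / s2 else 0
    sum((dy - a * g)^2)
  }
  span <- max(t)
  lo <- max(span / 1e4, min(t[t > 0]) / 50)
  hi <- span * 50
  # coarse log-spaced scan to bracket the minimum, then refine
  grid <- exp(seq(log(lo), log(hi), length.out = 60L))
  sses <- vapply(grid, sse_at, 0)
  k <- which.min(sses)
  bl <- grid[max(1L, k - 1L)]; bu <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(sse_at, interval = c(bl, bu), tol = 1e-12)
  tau <- opt$minimum
  g <- 1 - exp(-t / tau)
  s2 <- sum(g^2)
  amp <- if (s2 > 0) sum(g * dy) / s2 else 0
  plateau <- f0 + amp
  denom <- prebleach_level - f0
  mobile <- if (abs(denom) < .Machine$double.eps) NA_real_ else amp / denom
  at_boundary <- tau <= lo * 1.01 || tau >= hi * 0.99
  flat <- abs(amp) < 1e-12   # no recovery: tau unidentifiable, mobile = 0
  if (flat) mobile <- 0
  converged <- !is.na(mobile) && mobile >= 0 && mobile <= 1.5 &&
    (flat || !at_boundary)
  structure(list(mobile_fraction = mobile, tau_s = tau, plateau = plateau,
                 f0 = f0, residual_sse = opt$objective,
                 converged = converged),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile fraction %.4f, tau %.4g s, SSE %.3g%s\n",
              x$mobile_fraction, x$tau_s, x$residual_sse,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}
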