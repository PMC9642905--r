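#' @title Microdomain image statistics
#' @description The quantification statistics computed on coelomocyte
#'   micrographs: membrane/cytoplasm ratio from paired measurement discs,
#'   microdomain spread from circumferential line scans, the equal-area
#'   interior/peripheral log2 intensity ratio, thresholded Pearson
#'   colocalization, thresholded mean intensity, cell area, and
#'   skeleton-based fiber length. "Above threshold" is strict (`>`)
#'   throughout.
#' @name microdomain-metrics
NULL

.ratio_result <- function(num, den, n_regions) {
  structure(list(ratio = num / den, log2_ratio = log2(num / den),
                 numerator_mean = num, denominator_mean = den,
                 n_regions_used = n_regions),
            class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat(sprintf("<ratio_result> ratio %.4g (log2 %.4g), num %.4g, den %.4g, n = %d\n",
              x$ratio, x$log2_ratio, x$numerator_mean, x$denominator_mean,
              x$n_regions_used))
  invisible(x)
}

#' Membrane-to-cytoplasm intensity ratio
#'
#' Mean of the per-disc mean intensities over the on-endosome discs,
#' divided by the same over the off-endosome (cytoplasmic) discs. The
#' standard design uses three 3-um-diameter discs of each kind per
#' coelomocyte, one coelomocyte per animal. Reported on both linear and
#' log2 scales.
#'
#' @param image a [pixel_image()].
#' @param on_discs list of [disc_roi()] centered on endosomes.
#' @param off_discs list of [disc_roi()] on non-endosomal cytoplasm.
#' @return A `ratio_result` with `ratio`, `log2_ratio`, the two pooled
#'   means, and `n_regions_used`.
#' @export
membrane_cytoplasm_ratio <- function(image, on_discs, off_discs) {
  stopifnot(inherits(image, "pixel_image"))
  if (length(on_discs) < 1L || length(off_discs) < 1L)
    stop("need at least one on-disc and one off-disc")
  disc_mean <- function(d) mean(image$values[disc_mask(image, d)])
  num <- mean(vapply(on_discs, disc_mean, 0))
  den <- mean(vapply(off_discs, disc_mean, 0))
  if (den == 0) stop("off-disc mean intensity is zero; ratio undefined")
  .ratio_result(num, den, length(on_discs) + length(off_discs))
}

#' Microdomain spread from circumferential profiles
#'
#' For each endosome line scan, the fraction of samples whose intensity is
#' strictly above the threshold; the result is the mean over the supplied
#' profiles (one coelomocyte's endosomes, at least three in the standard
#' design). This fraction is the relative angular size of the microdomain
#' on the endosome membrane.
#'
#' @param profiles list of [angular_profile()] (a single profile is
#'   also accepted).
#' @param threshold intensity threshold (AU); strictly-above comparison.
#' @return list of class `spread_result`: `fraction_above`, `threshold`,
#'   `n_samples` (per profile), `n_endosomes_averaged`.
#' @export
microdomain_spread <- function(profiles, threshold) {
  if (inherits(profiles, "angular_profile")) profiles <- list(profiles)
  if (length(profiles) < 1L) stop("need at least one profile")
  fr <- vapply(profiles, function(p) {
    if (length(p$intensities) == 0L) stop("empty profile")
    mean(p$intensities > threshold)
  }, 0)
  structure(list(fraction_above = mean(fr), threshold = threshold,
                 n_samples = vapply(profiles, function(p)
                   length(p$intensities), 0L),
                 n_endosomes_averaged = length(profiles),
                 per_endosome = fr),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result> fraction above threshold %.4g (threshold %.4g AU, %d endosomes)\n",
              x$fraction_above, x$threshold, x$n_endosomes_averaged))
  invisible(x)
}

#' Interior/peripheral log2 intensity ratio
#'
#' Splits the cell disc into two equal-area regions (interior disc and
#' peripheral annulus), integrates the intensity of strictly-above-threshold
#' pixels in each, and reports interior / peripheral on linear and log2
#' scales. On the log2 scale, 0.0 means equal intensity in the two
#' regions, +1.0 a two-fold interior excess, and -1.0 a two-fold
#' peripheral excess.
#'
#' @param image a [pixel_image()].
#' @param cell a [disc_roi()] for the whole cell.
#' @param threshold intensity threshold (AU).
#' @param statistic `"sum"` (default) integrates above-threshold
#'   intensity; `"mean"` averages it instead.
#' @return A `ratio_result` (numerator = interior, denominator =
#'   peripheral).
#' @export
interior_peripheral_ratio <- function(image, cell, threshold,
                                      statistic = c("sum", "mean")) {
  stopifnot(inherits(image, "pixel_image"), inherits(cell, "disc_roi"))
  statistic <- match.arg(statistic)
  parts <- split_equal_area(cell)
  m_in <- disc_mask(image, parts$interior)
  m_out <- annulus_mask(image, parts$peripheral)
  agg <- function(m) {
    v <- image$values[m]
    v <- v[v > threshold]
    if (length(v) == 0L) return(0)
    if (statistic == "sum") sum(v) else mean(v)
  }
  num <- agg(m_in); den <- agg(m_out)
  if (num == 0 || den == 0)
    stop("no above-threshold intensity in the interior and/or peripheral region; ratio undefined")
  .ratio_result(num, den, 2L)
}

#' Thresholded Pearson colocalization
#'
#' Pearson correlation of the two channels over pixels inside `region`
#' that pass the per-channel thresholds. The inclusion rule is
#' configurable because acquisition-software conventions differ:
#' `"union"` (default) keeps pixels strictly above threshold in either
#' channel, `"intersection"` requires both, `"all"` ignores thresholds.
#'
#' @param ch1,ch2 [pixel_image()]s of identical shape.
#' @param region logical matrix restricting the analysis (default: whole
#'   image).
#' @param t1,t2 per-channel thresholds (AU); default Otsu on the region.
#' @param include pixel inclusion rule.
#' @return list of class `coloc_result`: `pearson_r`, `n_pixels`,
#'   `threshold_ch1`, `threshold_ch2`, `include`.
#' @export
thresholded_pearson <- function(ch1, ch2, region = NULL, t1 = NULL, t2 = NULL,
                                include = c("union", "intersection", "all")) {
  stopifnot(inherits(ch1, "pixel_image"), inherits(ch2, "pixel_image"))
  include <- match.arg(include)
  if (!identical(dim(ch1$values), dim(ch2$values)))
    stop("channel images must have identical shape")
  if (is.null(region)) region <- matrix(TRUE, nrow(ch1$values), ncol(ch1$values))
  region <- as.logical(region)
  if (is.null(t1)) t1 <- otsu_threshold(ch1, region)
  if (is.null(t2)) t2 <- otsu_threshold(ch2, region)
  v1 <- ch1$values[region]; v2 <- ch2$values[region]
  keep <- switch(include,
                 union = v1 > t1 | v2 > t2,
                 intersection = v1 > t1 & v2 > t2,
                 all = rep(TRUE, length(v1)))
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 2L)
    stop("fewer than 2 pixels pass the threshold inclusion rule")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero variance among included pixels; correlation undefined")
  structure(list(pearson_r = stats::cor(v1, v2), n_pixels = length(v1),
                 threshold_ch1 = t1, threshold_ch2 = t2, include = include),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> Pearson r = %.4f over %d pixels (%s rule; thresholds %.4g / %.4g AU)\n",
              x$pearson_r, x$n_pixels, x$include,
              x$threshold_ch1, x$threshold_ch2))
  invisible(x)
}

#' Mean intensity of above-threshold pixels in a region
#'
#' @param image a [pixel_image()].
#' @param region logical matrix; must contain at least one pixel.
#' @param threshold intensity threshold (AU), strict comparison.
#' @return list with `mean` (AU, `NA` when no pixel passes), `n_pixels`,
#'   and `empty` flag. An empty result is a valid outcome, not an error.
#' @export
mean_intensity_above_threshold <- function(image, region, threshold) {
  stopifnot(inherits(image, "pixel_image"))
  region <- as.logical(region)
  if (!any(region)) stop("region is empty")
  v <- image$values[region]
  v <- v[v > threshold]
  if (length(v) == 0L)
    return(list(mean = NA_real_, n_pixels = 0L, empty = TRUE))
  list(mean = mean(v), n_pixels = length(v), empty = FALSE)
}

#' Cell area from a boolean mask
#'
#' @param mask logical matrix (e.g., a thresholded coelomocyte mask).
#' @param pixel_size_um physical pixel size (um).
#' @return area in square micrometres: true-pixel count times
#'   `pixel_size_um^2`.
#' @export
cell_area <- function(mask, pixel_size_um) {
  sum(as.logical(mask), na.rm = TRUE) * pixel_size_um^2
}
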