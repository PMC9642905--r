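#' @title Image and ROI input/output
#' @description Readers and writers for the package's exchange formats.
#'   Images travel in a self-describing plain-text format (a two-line
#'   header carrying pixel size and shape, then `%.17g`-formatted values,
#'   lossless on round trip); ROIs, hit tables, and results travel as
#'   CSV/TSV; sequences as FASTA. No proprietary microscope formats.
#' @name endodomain-io
NULL

#' Write one or more image channels to a text image file
#'
#' @param channels a [pixel_image()] or list of them (all same shape and
#'   pixel size).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image <- function(channels, path) {
  if (inherits(channels, "pixel_image")) channels <- list(channels)
  stopifnot(length(channels) >= 1L,
            all(vapply(channels, inherits, TRUE, "pixel_image")))
  nr <- nrow(channels[[1]]$values); nc <- ncol(channels[[1]]$values)
  px <- channels[[1]]$pixel_size_um
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("endodomain-image v1",
               sprintf("pixel_size_um %.17g channels %d rows %d cols %d",
                       px, length(channels), nr, nc)), con)
  for (ch in channels) {
    if (!identical(dim(ch$values), c(nr, nc)) || ch$pixel_size_um != px)
      stop("all channels must share shape and pixel size")
    # row-major, one image row per line
    writeLines(apply(ch$values, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a text image file
#'
#' @param path file written by [write_image()].
#' @param pixel_size_um override for the stored pixel size (rarely
#'   needed; the format always stores one).
#' @return list of [pixel_image()] channels.
#' @export
read_image <- function(path, pixel_size_um = NULL) {
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "endodomain-image v1")
    stop(sprintf("'%s' is not an endodomain text image", path))
  hdr <- strsplit(lines[2], " +")[[1]]
  getv <- function(key) {
    i <- match(key, hdr)
    if (is.na(i) || i == length(hdr)) stop("corrupt image header")
    as.numeric(hdr[i + 1L])
  }
  px <- if (is.null(pixel_size_um)) getv("pixel_size_um") else pixel_size_um
  n_ch <- as.integer(getv("channels"))
  nr <- as.integer(getv("rows")); nc <- as.integer(getv("cols"))
  if (length(lines) != 2L + n_ch * nr) stop("corrupt image body")
  out <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    block <- lines[2L + ((ch - 1L) * nr + 1L):(ch * nr)]
    vals <- t(vapply(strsplit(block, " "), as.numeric, numeric(nc)))
    out[[ch]] <- pixel_image(matrix(vals, nr, nc), px)
  }
  out
}

#' Write ROIs to CSV
#'
#' Dialect: columns `kind` (`disc` or `ring`), `center_x_px`,
#' `center_y_px`, `radius_um`, `width_um` (blank for discs).
#'
#' @param rois list of [disc_roi()] / [ring_roi()] objects.
#' @param path output CSV.
#' @export
write_roi_csv <- function(rois, path) {
  rows <- lapply(rois, function(r) {
    if (inherits(r, "disc_roi"))
      data.frame(kind = "disc", center_x_px = r$center_x,
                 center_y_px = r$center_y, radius_um = r$radius_um,
                 width_um = NA_real_)
    else if (inherits(r, "ring_roi"))
      data.frame(kind = "ring", center_x_px = r$center_x,
                 center_y_px = r$center_y, radius_um = r$radius_um,
                 width_um = r$width_um)
    else stop("unsupported ROI class")
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read ROIs from CSV
#'
#' @param path CSV in the dialect of [write_roi_csv()].
#' @return list of ROI objects.
#' @export
read_roi_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("kind", "center_x_px", "center_y_px", "radius_um")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("ROI CSV lacks column(s): ", paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$kind[i]
    if (k == "disc")
      disc_roi(tab$center_x_px[i], tab$center_y_px[i], tab$radius_um[i])
    else if (k == "ring")
      ring_roi(tab$center_x_px[i], tab$center_y_px[i], tab$radius_um[i],
               tab$width_um[i])
    else stop(sprintf("ROI CSV row %d: unknown kind '%s'", i, k))
  })
}

.config_defaults <- function() {
  list(threshold_ch1 = "otsu", threshold_ch2 = "otsu",
       disc_diameter_um = 3, n_on_discs = 3L, n_off_discs = 3L,
       n_profile_samples = NULL, coloc_include = "union",
       interior_statistic = "sum", seed = 1L)
}

#' Build a validated run configuration
#'
#' Defaults reproduce the standard measurement design: six 3-um-diameter
#' measurement discs (three on endosomes, three off), Otsu thresholds
#' when none are given, union inclusion for colocalization,
#' integrated-intensity interior/peripheral statistic.
#'
#' @param ... configuration overrides; unknown keys are an error.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!cfg$coloc_include %in% c("union", "intersection", "all"))
    stop("coloc_include must be union, intersection or all")
  for (k in c("threshold_ch1", "threshold_ch2"))
    if (!identical(cfg[[k]], "otsu") && !is.numeric(cfg[[k]]))
      stop(k, " must be a number or \"otsu\"")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(run_config, vals)
}

# order-stable FNV-1a hash of the serialized config, for provenance
.config_hash <- function(cfg) {
  x <- unclass(cfg)
  x <- x[order(names(x))]
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.resolve_threshold <- function(setting, image, mask = NULL) {
  if (identical(setting, "otsu")) otsu_threshold(image, mask)
  else as.numeric(setting)
}

#' Run the full simulate-and-measure pipeline on a synthetic scene
#'
#' Generates a scene from its spec, then computes every standard metric:
#' microdomain spread (per-endosome line scans, averaged), the
#' membrane/cytoplasm ratio from placed measurement discs, the
#' interior/peripheral log2 ratio, thresholded Pearson colocalization
#' (when at least two channels exist), and cell area. Results are
#' returned as a data frame (and optionally written as CSV with a log);
#' every row carries the configuration hash for traceability. The run is
#' fully deterministic given (spec, config).
#'
#' @param spec a [scene_spec()].
#' @param config a [run_config()].
#' @param out_csv optional path for the results CSV.
#' @param log_path optional path for a plain-text run log.
#' @return data frame with columns `metric`, `value`, `log2_value`,
#'   `n_endosomes`, `threshold_ch1`, `threshold_ch2`, `config_hash`.
#' @export
run_pipeline <- function(spec, config = run_config(), out_csv = NULL,
                         log_path = NULL) {
  stopifnot(inherits(spec, "scene_spec"), inherits(config, "run_config"))
  hash <- .config_hash(config)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, sprintf(...))
  say("endodomain run_pipeline | config %s | scene seed %d", hash, spec$seed)

  stage <- "simulate"
  res <- tryCatch({
    scene <- generate_coelomocyte(spec)
    ch1 <- scene$channels[[1]]
    cellmask <- disc_mask(ch1, scene$truth$cell)
    t1 <- .resolve_threshold(config$threshold_ch1, ch1, cellmask)
    t2 <- if (length(scene$channels) >= 2L)
      .resolve_threshold(config$threshold_ch2, scene$channels[[2]], cellmask)
    else NA_real_
    say("thresholds: ch1 %.6g, ch2 %s", t1,
        if (is.na(t2)) "n/a" else sprintf("%.6g", t2))

    rows <- list()
    add <- function(metric, value, log2_value = NA_real_,
                    n_endosomes = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        metric = metric, value = value, log2_value = log2_value,
        n_endosomes = n_endosomes, threshold_ch1 = t1, threshold_ch2 = t2,
        config_hash = hash)
    }

    n_endo <- length(scene$truth$endosome_rois)
    if (n_endo > 0L) {
      stage <- "spread"
      profs <- lapply(scene$truth$endosome_rois, function(r)
        circle_profile(ch1, r, n_samples = config$n_profile_samples))
      sp <- microdomain_spread(profs, t1)
      add("spread", sp$fraction_above, n_endosomes = n_endo)

      stage <- "membrane_cytoplasm_ratio"
      discs <- place_measurement_discs(
        ch1, scene$truth$cell, scene$truth$endosome_rois,
        n_on = min(config$n_on_discs, n_endo), n_off = config$n_off_discs,
        disc_diameter_um = config$disc_diameter_um, seed = config$seed)
      mcr <- membrane_cytoplasm_ratio(ch1, discs$on_discs, discs$off_discs)
      add("membrane_cytoplasm_ratio", mcr$ratio, mcr$log2_ratio, n_endo)
    }

    stage <- "interior_peripheral_ratio"
    ipr <- interior_peripheral_ratio(ch1, scene$truth$cell, t1,
                                     statistic = config$interior_statistic)
    add("interior_peripheral_ratio", ipr$ratio, ipr$log2_ratio)

    if (length(scene$channels) >= 2L) {
      stage <- "colocalization"
      cc <- thresholded_pearson(ch1, scene$channels[[2]], cellmask, t1, t2,
                                include = config$coloc_include)
      add("pearson_colocalization", cc$pearson_r)
    }

    stage <- "cell_area"
    add("cell_area_um2", cell_area(cellmask, ch1$pixel_size_um))

    do.call(rbind, rows)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed (scene seed %d): %s",
                 stage, spec$seed, conditionMessage(e)), call. = FALSE)
  })

  say("metrics computed: %s", paste(res$metric, collapse = ", "))
  if (!is.null(out_csv)) utils::write.csv(res, out_csv, row.names = FALSE)
  if (!is.null(log_path)) writeLines(logline, log_path)
  res
}
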