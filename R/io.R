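#' @title File formats, configuration and the end-to-end pipeline
#' @description Two-channel TIFF reading/writing, scene serialization with
#'   JSON manifests, ROI and YAML configuration files, and
#'   [run_pipeline()], which ties segmentation, quantification and group
#'   statistics together with a full provenance log.
#' @name cli_io
NULL

.tiff_scale <- function(bit_depth) 2^bit_depth - 1

#' Read a registered two-channel image pair
#'
#' Accepts a multi-page TIFF (page 1 transmitted light, page 2 bead
#' fluorescence) or two single-page TIFF paths. Channels must share
#' dimensions; the sample bit depth is recorded.
#'
#' @param path One path (multi-page) or a character vector of two paths.
#' @return List of class `image_pair`: `brightfield`, `fluorescence`
#'   (integer-valued matrices in raw camera units), `bit_depth`, `source`.
#' @export
read_image_pair <- function(path) {
  if (length(path) == 1L) {
    if (!file.exists(path)) stop("cannot read image: ", path)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (length(pages) < 2L) {
      stop("expected a two-channel (two-page) TIFF, found ",
           length(pages), " page(s): ", path)
    }
    bf <- pages[[1]]; fl <- pages[[2]]
  } else if (length(path) == 2L) {
    for (p in path) if (!file.exists(p)) stop("cannot read image: ", p)
    bf <- tiff::readTIFF(path[1], as.is = TRUE, info = TRUE)
    fl <- tiff::readTIFF(path[2], as.is = TRUE, info = TRUE)
  } else {
    stop("path must be one multi-page TIFF or two single-page TIFFs")
  }
  bits <- attr(bf, "bits.per.sample")
  if (is.null(bits)) bits <- NA_integer_
  bf_m <- .strip_attrs(bf); fl_m <- .strip_attrs(fl)
  if (!all(dim(bf_m) == dim(fl_m))) {
    stop("channel dimensions differ: ",
         paste(dim(bf_m), collapse = "x"), " vs ",
         paste(dim(fl_m), collapse = "x"))
  }
  structure(list(brightfield = bf_m, fluorescence = fl_m,
                 bit_depth = as.integer(bits),
                 source = path),
            class = "image_pair")
}

.strip_attrs <- function(x) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}

#' Write a two-channel image pair as a multi-page TIFF
#'
#' @param brightfield,fluorescence Integer-valued matrices in raw units.
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image_pair <- function(brightfield, fluorescence, path,
                             bit_depth = 16) {
  stopifnot(bit_depth %in% c(8, 16))
  sc <- .tiff_scale(bit_depth)
  if (max(brightfield) > sc || max(fluorescence) > sc ||
      min(brightfield) < 0 || min(fluorescence) < 0) {
    stop("intensities are not representable at bit depth ", bit_depth)
  }
  tiff::writeTIFF(list(brightfield / sc, fluorescence / sc), path,
                  bits.per.sample = bit_depth)
  invisible(path)
}

#' Write a synthetic scene to disk
#'
#' Emits the two-channel image TIFF, ground-truth masks as single-page
#' TIFFs (worm mask and bead mask as 0/255 8-bit, per-worm labels 16-bit),
#' and a JSON manifest holding every scene parameter and the derived truth
#' values.
#'
#' @param scene A `synthetic_scene` from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param basename File stem (default `"scene"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- scene$params
  paths <- c(
    images = file.path(dir, paste0(basename, "_images.tif")),
    worm_mask = file.path(dir, paste0(basename, "_worm_mask.tif")),
    bead_mask = file.path(dir, paste0(basename, "_bead_mask.tif")),
    labels = file.path(dir, paste0(basename, "_labels.tif")),
    manifest = file.path(dir, paste0(basename, "_manifest.json"))
  )
  write_image_pair(scene$images$brightfield, scene$images$fluorescence,
                   paths[["images"]], p$bit_depth)
  tiff::writeTIFF(scene$truth$worm_mask * 1, paths[["worm_mask"]],
                  bits.per.sample = 8)
  tiff::writeTIFF(scene$truth$bead_mask * 1, paths[["bead_mask"]],
                  bits.per.sample = 8)
  tiff::writeTIFF(scene$truth$per_worm_labels / .tiff_scale(16),
                  paths[["labels"]], bits.per.sample = 16)
  manifest <- c(unclass(p),
                list(expected_Aw = scene$truth$expected_Aw,
                     expected_bead_sum = scene$truth$expected_bead_sum,
                     expected_bead_sum_raw = scene$truth$expected_bead_sum_raw,
                     expected_ratio = scene$truth$expected_ratio,
                     responders = scene$truth$responders))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Read exclusion ROIs from a JSON file
#'
#' Expected layout: a JSON array of objects with fields `id` (optional),
#' `x` and `y` (vertex arrays in pixel coordinates, x = column, y = row).
#'
#' @param path JSON file path.
#' @return List of two-column vertex matrices with `id` attributes,
#'   suitable for [apply_exclusions()].
#' @export
read_rois <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(seq_along(raw), function(k) {
    r <- raw[[k]]
    x <- unlist(r$x); y <- unlist(r$y)
    if (length(x) != length(y) || length(x) < 3) {
      stop("ROI ", k, " in ", path, " needs matching x/y arrays (>= 3 vertices)")
    }
    poly <- cbind(x = as.numeric(x), y = as.numeric(y))
    rid <- r$id
    attr(poly, "id") <- if (!is.null(rid) && length(rid) == 1 && !is.na(rid)) {
      as.character(rid)
    } else {
      paste0("roi", k)
    }
    poly
  })
}

#' Assemble a pipeline run configuration
#'
#' @param metadata Path to the per-image metadata CSV with columns
#'   `image` (TIFF path, relative paths resolved against the CSV's
#'   directory), `condition`, `solvent`, and optionally `rois` (path to a
#'   ROI JSON) and `concentration` (mM, enables the dose-response fit).
#' @param worm_width,typical_worm_area,tophat_radius,gaussian_sigma,polarity
#'   Segmentation parameters, see [seg_config()].
#' @param profile Instrument profile name (`"confocal"` or
#'   `"stereomicroscope"`) or an [instrument_profile()].
#' @param bead_threshold Optional explicit threshold overriding the
#'   profile default.
#' @param control_condition Positive-control condition defining 100%.
#' @param reference_condition Optional negative-control condition for the
#'   group comparisons; when `NULL` no comparison table is produced.
#' @param alpha Family-wise level for Holm decisions.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the provenance log.
#' @param dose_order Polynomial degree for the optional dose-response fit.
#' @return Object of class `run_config`.
#' @export
run_config <- function(metadata, worm_width, typical_worm_area,
                       tophat_radius = worm_width,
                       gaussian_sigma = 2 * worm_width,
                       polarity = "dark_worms",
                       profile = "confocal", bead_threshold = NULL,
                       control_condition, reference_condition = NULL,
                       alpha = 0.05, out_dir = ".", seed = 1,
                       dose_order = 3) {
  if (!file.exists(metadata)) stop("metadata table not found: ", metadata)
  if (inherits(profile, "instrument_profile")) {
    prof <- profile
  } else {
    prof <- instrument_profile(profile, bead_threshold)
  }
  structure(list(
    metadata = metadata,
    segmentation = seg_config(worm_width, typical_worm_area,
                              tophat_radius, gaussian_sigma, polarity),
    profile = prof,
    control_condition = control_condition,
    reference_condition = reference_condition,
    alpha = alpha,
    out_dir = out_dir,
    seed = as.integer(seed),
    dose_order = dose_order
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]. Relative
#' `metadata` paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return Object of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$metadata) && !file.exists(y$metadata)) {
    cand <- file.path(dirname(path), y$metadata)
    if (file.exists(cand)) y$metadata <- cand
  }
  do.call(run_config, y)
}

#' Run the full bead-ingestion analysis pipeline
#'
#' For every image in the metadata table: read the two channels, segment
#' worms (applying any per-image exclusion ROIs), threshold the bead
#' channel, and measure the activity ratio. Ratios are then normalized to
#' the positive control, groups compared against the reference condition
#' (when given), and a dose-response curve fitted when the metadata
#' carries a `concentration` column. All tables are written as CSV, the
#' optional fit as JSON, and every parameter (thresholds, radii, seed,
#' chosen control solvent) is logged for provenance.
#'
#' @param config A [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return List of class `pipeline_result` with `measurements`,
#'   `normalized`, `comparisons` (or `NULL`), `dose_fit` (or `NULL`),
#'   `log`, and `paths` of the written files.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  meta <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  req <- c("image", "condition")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (!"solvent" %in% names(meta)) meta$solvent <- "none"
  if (!config$control_condition %in% meta$condition) {
    stop("control condition '", config$control_condition,
         "' absent from metadata; refusing to run")
  }
  meta_dir <- dirname(config$metadata)
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    img_path <- meta$image[i]
    if (!file.exists(img_path)) {
      cand <- file.path(meta_dir, img_path)
      if (file.exists(cand)) img_path <- cand
    }
    pair <- read_image_pair(img_path)
    rois <- list()
    if ("rois" %in% names(meta) && !is.na(meta$rois[i]) &&
        nzchar(meta$rois[i])) {
      roi_path <- meta$rois[i]
      if (!file.exists(roi_path)) roi_path <- file.path(meta_dir, meta$rois[i])
      rois <- read_rois(roi_path)
    }
    wm <- segment_worms(pair$brightfield, config$segmentation, rois)
    bm <- bead_mask(pair$fluorescence, config$profile)
    m <- measure_activity(wm, bm, pair$fluorescence,
                          image_id = basename(img_path),
                          condition = meta$condition[i],
                          solvent = meta$solvent[i],
                          bit_depth = if (is.na(pair$bit_depth)) NULL
                                      else pair$bit_depth)
    rows[[i]] <- as.data.frame(m)
  }
  measurements <- do.call(rbind, rows)
  if ("concentration" %in% names(meta)) {
    measurements$concentration <- meta$concentration
  }
  normalized <- normalize_activity(measurements, config$control_condition)
  comparisons <- NULL
  if (!is.null(config$reference_condition)) {
    comparisons <- compare_groups(normalized, config$reference_condition,
                                  config$alpha)
  }
  dose_fit <- NULL
  if ("concentration" %in% names(normalized)) {
    ok <- !is.na(normalized$concentration)
    if (sum(ok) >= config$dose_order + 2 &&
        length(unique(normalized$concentration[ok])) >= config$dose_order + 1) {
      dose_fit <- fit_dose_response(normalized$concentration[ok],
                                    normalized$pct[ok],
                                    order = config$dose_order)
    }
  }
  log <- list(
    package_version = as.character(utils::packageVersion("wormbeads")),
    n_images = nrow(measurements),
    segmentation = unclass(config$segmentation),
    bead_threshold = config$profile$bead_threshold,
    instrument_profile = config$profile$name,
    control_condition = config$control_condition,
    control_solvent = attr(normalized, "control_solvent"),
    control_mean_ratio = attr(normalized, "control_mean"),
    reference_condition = config$reference_condition,
    alpha = config$alpha,
    dose_order = config$dose_order,
    seed = config$seed
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(measurements = file.path(config$out_dir, "measurements.csv"),
             normalized = file.path(config$out_dir, "normalized.csv"),
             log = file.path(config$out_dir, "run_log.json"))
  utils::write.csv(measurements, paths[["measurements"]], row.names = FALSE)
  utils::write.csv(normalized, paths[["normalized"]], row.names = FALSE)
  if (!is.null(comparisons)) {
    paths[["comparisons"]] <- file.path(config$out_dir, "comparisons.csv")
    utils::write.csv(comparisons, paths[["comparisons"]], row.names = FALSE)
  }
  if (!is.null(dose_fit)) {
    paths[["dose_fit"]] <- file.path(config$out_dir, "dose_fit.json")
    jsonlite::write_json(
      list(order = dose_fit$order,
           concentrations = dose_fit$concentrations,
           responses = dose_fit$responses,
           fitted = dose_fit$fitted,
           lower = dose_fit$lower, upper = dose_fit$upper,
           df_residual = dose_fit$df_residual, sigma = dose_fit$sigma,
           level = dose_fit$level),
      paths[["dose_fit"]], auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(log, paths[["log"]], auto_unbox = TRUE, digits = NA)
  structure(list(measurements = measurements, normalized = normalized,
                 comparisons = comparisons, dose_fit = dose_fit,
                 log = log, paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result> %d image(s); control '%s' in '%s' ",
                     "(mean ratio %.6g = 100%%)\n"),
              x$log$n_images, x$log$control_condition, x$log$control_solvent,
              x$log$control_mean_ratio))
  if (!is.null(x$comparisons)) {
    cat("comparisons vs '", x$log$reference_condition, "':\n", sep = "")
    print(x$comparisons)
  }
  invisible(x)
}
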