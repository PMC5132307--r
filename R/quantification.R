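#' @title Bead-signal quantification
#' @description Thresholds the fluorescence channel into a microsphere
#'   mask, intersects it with the worm mask to exclude beads outside the
#'   worms' guts, and computes the per-image ingestion statistic: the sum
#'   of in-worm bead intensity (an estimate of the mean-intensity x area
#'   product Im*Am) divided by the worm area Aw.
#' @name quantification
NULL

#' Instrument profile with its bead threshold
#'
#' The fluorescence threshold is chosen once per imaging set-up so that
#' background noise and worm autofluorescence fall below it: 1000 raw units
#' for the confocal set-up, 50 for the stereomicroscope set-up used for
#' HPLC-fraction screening.
#'
#' @param name `"confocal"`, `"stereomicroscope"`, or any label when an
#'   explicit `bead_threshold` is supplied.
#' @param bead_threshold Raw-intensity threshold (> 0); defaults to the
#'   registered value for the named profile.
#' @return Object of class `instrument_profile`.
#' @export
instrument_profile <- function(name = c("confocal", "stereomicroscope"),
                               bead_threshold = NULL) {
  defaults <- c(confocal = 1000, stereomicroscope = 50)
  if (is.null(bead_threshold)) {
    name <- match.arg(name)
    bead_threshold <- defaults[[name]]
  } else {
    name <- if (length(name) == 1L) name else name[1]
  }
  if (!is.numeric(bead_threshold) || bead_threshold <= 0) {
    stop("bead_threshold must be > 0")
  }
  structure(list(name = name, bead_threshold = bead_threshold),
            class = "instrument_profile")
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf("<instrument_profile> %s, bead threshold %g\n",
              x$name, x$bead_threshold))
  invisible(x)
}

#' Microsphere mask from the fluorescence channel
#'
#' Pixels at or above the profile's bead threshold are foreground. The
#' threshold is applied to the raw channel without any filtering; the
#' comparison is inclusive (`>=`).
#'
#' @param fluor Raw fluorescence intensity matrix.
#' @param profile An [instrument_profile()] (or a single positive number,
#'   taken as the threshold).
#' @return Logical matrix.
#' @export
bead_mask <- function(fluor, profile = instrument_profile("confocal")) {
  .check_grid(fluor, "fluor")
  if (is.numeric(profile) && length(profile) == 1L) {
    profile <- instrument_profile("custom", bead_threshold = profile)
  }
  stopifnot(inherits(profile, "instrument_profile"))
  fluor >= profile$bead_threshold
}

#' Measure per-image ingestion activity
#'
#' Intersects the worm and bead masks, sums raw fluorescence intensity
#' over the intersection (the Im*Am estimate), and divides by the worm
#' area Aw. Beads outside the worm mask — unwashed microspheres scattered
#' around the worms — are excluded by the intersection. A field of view
#' with `Aw = 0` yields an invalid measurement with no ratio.
#'
#' @param worm_mask A `worm_mask` object from [segment_worms()] /
#'   [apply_exclusions()], or a logical matrix.
#' @param beads Logical microsphere mask (see [bead_mask()]).
#' @param fluor Raw fluorescence intensity matrix (same dimensions).
#' @param image_id,condition,solvent Optional labels carried into results.
#' @param bit_depth Optional; when given, the fraction of fluorescence
#'   pixels at the saturation value is recorded (acquisition gain is meant
#'   to avoid bead-signal saturation).
#' @return Object of class `activity_measurement` with fields `image_id`,
#'   `Aw`, `Am`, `bead_sum`, `ratio`, `valid`, `condition`, `solvent`,
#'   `saturation_fraction`.
#' @examples
#' wm <- matrix(FALSE, 4, 4); wm[2:3, 1:4] <- TRUE
#' fl <- matrix(0, 4, 4); fl[2, 2] <- 1200; fl[3, 3] <- 1500; fl[1, 4] <- 2000
#' m <- measure_activity(wm, bead_mask(fl), fl)
#' m$ratio  # 2700 / 8
#' @export
measure_activity <- function(worm_mask, beads, fluor,
                             image_id = NA_character_,
                             condition = NA_character_,
                             solvent = NA_character_,
                             bit_depth = NULL) {
  if (inherits(worm_mask, "worm_mask")) worm_mask <- worm_mask$mask
  worm_mask <- .as_mask(worm_mask)
  beads <- .as_mask(beads)
  .check_grid(fluor, "fluor")
  if (!all(dim(worm_mask) == dim(fluor)) || !all(dim(beads) == dim(fluor))) {
    stop("worm mask, bead mask and fluorescence channel must share dimensions")
  }
  inter <- worm_mask & beads
  Aw <- sum(worm_mask)
  Am <- sum(inter)
  bead_sum <- sum(fluor[inter])
  valid <- Aw > 0
  sat <- NA_real_
  if (!is.null(bit_depth)) sat <- mean(fluor >= 2^bit_depth - 1)
  structure(list(image_id = image_id,
                 Aw = Aw, Am = Am, bead_sum = bead_sum,
                 ratio = if (valid) bead_sum / Aw else NA_real_,
                 valid = valid,
                 condition = condition, solvent = solvent,
                 saturation_fraction = sat),
            class = "activity_measurement")
}

#' @export
print.activity_measurement <- function(x, ...) {
  cat(sprintf("<activity_measurement> %s: Aw %d, Am %d, sum %.6g, ratio %s%s\n",
              x$image_id, x$Aw, x$Am, x$bead_sum,
              if (x$valid) sprintf("%.6g", x$ratio) else "invalid (Aw = 0)",
              if (!is.na(x$condition)) paste0(" [", x$condition, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.activity_measurement <- function(x, ...) {
  data.frame(image_id = x$image_id, condition = x$condition,
             solvent = x$solvent, Aw = x$Aw, Am = x$Am,
             bead_sum = x$bead_sum, ratio = x$ratio, valid = x$valid,
             saturation_fraction = x$saturation_fraction,
             stringsAsFactors = FALSE)
}
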