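#' @title Synthetic two-channel micrograph generator
#' @description Renders bright-field/fluorescence image pairs that emulate
#'   the dauer-recovery bead-feeding assay — dark curvilinear worms over a
#'   slowly varying illumination background, punctate high-intensity bead
#'   signal in the gut region of responding worms, occasional stray beads
#'   outside worms, sub-threshold autofluorescence, and sensor noise —
#'   together with exact ground-truth masks, so the whole analysis pipeline
#'   can be validated without real micrographs.
#' @name synthgen
NULL

#' Scene parameters for the synthetic generator
#'
#' Defaults emulate a 10x confocal field of anesthetized dauer larvae:
#' 1024 x 1024 pixels at 0.83 um/pixel (~850 um field of view), worms about
#' 25 um (30 px) wide and 370-540 um long, mostly lying in clumps as
#' anesthetized dauers do, 0.5 um fluorescent microspheres rendered at
#' 16-bit depth with bead intensities well above the confocal bead
#' threshold of 1000.
#'
#' @param image_height,image_width Image size in pixels.
#' @param n_worms Number of worms rendered.
#' @param worm_width Worm width in pixels (>= 3).
#' @param worm_length_range Min/max worm length in pixels.
#' @param responder_fraction Fraction of worms carrying ingested beads, in
#'   `[0, 1]`.
#' @param bead_intensity_range Min/max per-bead fluorescence intensity in
#'   raw camera units.
#' @param beads_per_responder_range Min/max bead count per responding worm.
#' @param stray_bead_rate Expected number of beads outside worms per image
#'   (Poisson).
#' @param background_amplitude Amplitude of the slowly varying bright-field
#'   illumination field, raw units.
#' @param noise_sd Additive Gaussian sensor noise standard deviation, raw
#'   units (both channels).
#' @param bit_depth 8 or 16.
#' @param pixel_size Micrometers per pixel.
#' @param bead_diameter_um Microsphere diameter in micrometers (0.5 um
#'   polychromatic microspheres by default; rendered at minimum 1 px).
#' @param bf_level Mean bright-field background level, raw units.
#' @param worm_contrast Fractional bright-field attenuation of worm bodies
#'   (0.45 means worms are 45% darker than the local background).
#' @param autofluorescence_level Diffuse worm-body fluorescence level, raw
#'   units; must stay below the bead threshold in use.
#' @param clump_fraction Fraction of worms placed into clumps rather than
#'   scattered singly.
#' @param seed Integer seed; scenes are bit-reproducible given identical
#'   parameters.
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(image_height = 1024, image_width = 1024,
                         n_worms = 10, worm_width = 30,
                         worm_length_range = c(450, 650),
                         responder_fraction = 0.5,
                         bead_intensity_range = c(1200, 4000),
                         beads_per_responder_range = c(15, 50),
                         stray_bead_rate = 2,
                         background_amplitude = 2000,
                         noise_sd = 50,
                         bit_depth = 16,
                         pixel_size = 0.83,
                         bead_diameter_um = 0.5,
                         bf_level = 20000,
                         worm_contrast = 0.45,
                         autofluorescence_level = 200,
                         clump_fraction = 0.7,
                         seed = 1) {
  p <- list(image_height = as.integer(image_height),
            image_width = as.integer(image_width),
            n_worms = as.integer(n_worms),
            worm_width = worm_width,
            worm_length_range = as.numeric(worm_length_range),
            responder_fraction = responder_fraction,
            bead_intensity_range = as.numeric(bead_intensity_range),
            beads_per_responder_range = as.numeric(beads_per_responder_range),
            stray_bead_rate = stray_bead_rate,
            background_amplitude = background_amplitude,
            noise_sd = noise_sd,
            bit_depth = as.integer(bit_depth),
            pixel_size = pixel_size,
            bead_diameter_um = bead_diameter_um,
            bf_level = bf_level,
            worm_contrast = worm_contrast,
            autofluorescence_level = autofluorescence_level,
            clump_fraction = clump_fraction,
            seed = as.integer(seed))
  .validate_scene_params(p)
  structure(p, class = "scene_params")
}

.validate_scene_params <- function(p) {
  if (p$responder_fraction < 0 || p$responder_fraction > 1) {
    stop("responder_fraction must lie in [0, 1]")
  }
  if (p$worm_width < 3) stop("worm_width must be >= 3 px")
  if (!p$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  maxval <- 2^p$bit_depth - 1
  if (max(p$bead_intensity_range) > maxval ||
      p$bf_level + p$background_amplitude > maxval ||
      p$autofluorescence_level > maxval) {
    stop("configured intensities are not representable at bit depth ",
         p$bit_depth, " (maximum ", maxval, ")")
  }
  if (min(p$bead_intensity_range) <= 0 || p$bf_level <= 0) {
    stop("intensities must be positive")
  }
  if (p$n_worms < 0 || p$stray_bead_rate < 0 || p$noise_sd < 0 ||
      p$background_amplitude < 0) {
    stop("counts, rates, noise and background amplitude must be nonnegative")
  }
  if (p$worm_contrast <= 0 || p$worm_contrast >= 1) {
    stop("worm_contrast must lie in (0, 1)")
  }
  invisible(p)
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf(paste0("<scene_params> %d x %d px (%.2f um/px), %d worms ",
                     "(width %g px), responders %.0f%%, %d-bit, seed %d\n"),
              x$image_height, x$image_width, x$pixel_size, x$n_worms,
              x$worm_width, 100 * x$responder_fraction, x$bit_depth, x$seed))
  invisible(x)
}

# smooth random centerline: heading random walk sampled every ~3 px
.worm_centerline <- function(x0, y0, theta0, length, wobble = 0.05) {
  n <- max(10L, as.integer(round(length / 3)))
  step <- length / n
  th <- theta0 + cumsum(c(0, stats::rnorm(n - 1, 0, wobble)))
  list(x = x0 + cumsum(c(0, cos(th[-1]) * step)),
       y = y0 + cumsum(c(0, sin(th[-1]) * step)))
}

# paint a tube of the given width along a centerline into an integer label
# grid (label wins over previous content); returns the updated grid
.paint_tube <- function(labels, cl, width, label) {
  nr <- nrow(labels); nc <- ncol(labels)
  r <- width / 2
  for (i in seq_along(cl$x)) {
    cx <- cl$x[i]; cy <- cl$y[i]
    x1 <- max(1, floor(cx - r)); x2 <- min(nc, ceiling(cx + r))
    y1 <- max(1, floor(cy - r)); y2 <- min(nr, ceiling(cy + r))
    if (x1 > x2 || y1 > y2) next
    xs <- x1:x2; ys <- y1:y2
    inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r^2
    block <- labels[ys, xs, drop = FALSE]
    block[inside] <- label
    labels[ys, xs] <- block
  }
  labels
}

# paint a disk into a numeric grid with value = max(existing, value)
.paint_disk <- function(img, cx, cy, radius, value) {
  nr <- nrow(img); nc <- ncol(img)
  if (radius <= 0.5) {
    yy <- round(cy); xx <- round(cx)
    if (yy >= 1 && yy <= nr && xx >= 1 && xx <= nc) {
      img[yy, xx] <- max(img[yy, xx], value)
    }
    return(img)
  }
  x1 <- max(1, floor(cx - radius)); x2 <- min(nc, ceiling(cx + radius))
  y1 <- max(1, floor(cy - radius)); y2 <- min(nr, ceiling(cy + radius))
  if (x1 > x2 || y1 > y2) return(img)
  xs <- x1:x2; ys <- y1:y2
  inside <- outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2
  block <- img[ys, xs, drop = FALSE]
  block[inside] <- pmax(block[inside], value)
  img[ys, xs] <- block
  img
}

# slowly varying illumination: sum of two low-frequency cosine waves with
# random orientation and phase, scale >> worm width
.illumination_field <- function(nr, nc, amplitude) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  y <- seq_len(nr); x <- seq_len(nc)
  field <- matrix(0, nr, nc)
  for (k in 1:2) {
    wavelength <- stats::runif(1, 0.7, 1.6) * max(nr, nc)
    th <- stats::runif(1, 0, pi)
    ph <- stats::runif(1, 0, 2 * pi)
    fx <- cos(th) / wavelength; fy <- sin(th) / wavelength
    field <- field + outer(y, x, function(yy, xx) {
      cos(2 * pi * (fx * xx + fy * yy) + ph)
    })
  }
  amplitude * field / 2
}

.quantize <- function(img, bit_depth) {
  maxval <- 2^bit_depth - 1
  img <- round(img)
  img[img < 0] <- 0
  img[img > maxval] <- maxval
  img
}

#' Generate a synthetic two-channel scene with ground truth
#'
#' Renders the bright-field and fluorescence channels described by a
#' [scene_params()] object and returns them with exact ground truth: the
#' worm mask, per-worm labels, bead mask, and the expected worm area `Aw`,
#' in-worm bead intensity sum, and activity ratio computed from the
#' noiseless quantized render. The caller's RNG state is left untouched;
#' identical parameters (seed included) give bit-identical output.
#'
#' @param params A [scene_params()] object.
#' @return List of class `synthetic_scene` with elements `params`,
#'   `images` (`brightfield`, `fluorescence` matrices in raw integer
#'   units), and `truth` (`worm_mask`, `bead_mask`, `per_worm_labels`,
#'   `responders`, `expected_Aw`, `expected_bead_sum`,
#'   `expected_bead_sum_raw`, `expected_ratio`).
#' @examples
#' sc <- generate_scene(scene_params(image_height = 128, image_width = 128,
#'                                   n_worms = 2, worm_width = 8,
#'                                   worm_length_range = c(40, 60), seed = 3))
#' sc$truth$expected_ratio
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  .validate_scene_params(params)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(params$seed)
  nr <- params$image_height; nc <- params$image_width
  w <- params$worm_width
  maxval <- 2^params$bit_depth - 1

  ## ---- worm geometry -------------------------------------------------
  labels <- matrix(0L, nr, nc)
  centerlines <- vector("list", params$n_worms)
  if (params$n_worms > 0) {
    n_clumps <- max(1L, ceiling(params$n_worms / 6))
    clumps <- cbind(stats::runif(n_clumps, 0.25 * nc, 0.75 * nc),
                    stats::runif(n_clumps, 0.25 * nr, 0.75 * nr))
    for (i in seq_len(params$n_worms)) {
      L <- stats::runif(1, params$worm_length_range[1],
                        params$worm_length_range[2])
      th <- stats::runif(1, 0, 2 * pi)
      if (stats::runif(1) < params$clump_fraction) {
        ci <- clumps[1L + (i %% n_clumps), , drop = TRUE]
        x0 <- ci[1] + stats::rnorm(1, 0, 1.5 * w)
        y0 <- ci[2] + stats::rnorm(1, 0, 1.5 * w)
      } else {
        x0 <- stats::runif(1, 0.1 * nc, 0.9 * nc)
        y0 <- stats::runif(1, 0.1 * nr, 0.9 * nr)
      }
      # start half a length back so the worm roughly straddles its anchor
      x0 <- x0 - cos(th) * L / 2
      y0 <- y0 - sin(th) * L / 2
      cl <- .worm_centerline(x0, y0, th, L)
      centerlines[[i]] <- cl
      labels <- .paint_tube(labels, cl, w, i)
    }
  }
  worm_mask <- labels > 0L

  ## ---- fluorescence channel (noiseless) ------------------------------
  fluor <- matrix(0, nr, nc)
  fluor[worm_mask] <- params$autofluorescence_level
  bead_radius <- max(1, round(params$bead_diameter_um / params$pixel_size)) / 2
  bead_mask <- matrix(FALSE, nr, nc)
  n_resp <- round(params$responder_fraction * params$n_worms)
  responders <- if (n_resp > 0) {
    sort(sample(seq_len(params$n_worms), n_resp))
  } else integer(0)
  bead_marker <- matrix(0, nr, nc)  # bead intensity layer only
  for (i in responders) {
    cl <- centerlines[[i]]
    npts <- length(cl$x)
    gut <- seq(from = ceiling(0.2 * npts), to = floor(0.8 * npts))
    n_beads <- as.integer(round(stats::runif(
      1, params$beads_per_responder_range[1],
      params$beads_per_responder_range[2])))
    for (b in seq_len(n_beads)) {
      j <- sample(gut, 1)
      # keep the whole bead inside the tube cross-section
      maxoff <- max(0, w / 2 - bead_radius - 1)
      off <- stats::runif(1, -maxoff, maxoff)
      # perpendicular direction from local tangent
      j2 <- min(j + 1L, npts)
      dx <- cl$x[j2] - cl$x[max(1L, j - 1L)]
      dy <- cl$y[j2] - cl$y[max(1L, j - 1L)]
      nv <- sqrt(dx^2 + dy^2); if (nv == 0) { dx <- 1; dy <- 0; nv <- 1 }
      bx <- cl$x[j] - dy / nv * off
      by <- cl$y[j] + dx / nv * off
      val <- stats::runif(1, params$bead_intensity_range[1],
                          params$bead_intensity_range[2])
      bead_marker <- .paint_disk(bead_marker, bx, by, bead_radius, val)
    }
  }
  ## stray beads outside worms
  n_stray <- stats::rpois(1, params$stray_bead_rate)
  placed <- 0L
  tries <- 0L
  while (placed < n_stray && tries < 50L * max(1L, n_stray)) {
    tries <- tries + 1L
    bx <- stats::runif(1, 1, nc); by <- stats::runif(1, 1, nr)
    # keep strays fully outside worms: probe the disk's pixel window
    x1 <- max(1, floor(bx - bead_radius)); x2 <- min(nc, ceiling(bx + bead_radius))
    y1 <- max(1, floor(by - bead_radius)); y2 <- min(nr, ceiling(by + bead_radius))
    if (any(worm_mask[y1:y2, x1:x2])) next
    val <- stats::runif(1, params$bead_intensity_range[1],
                        params$bead_intensity_range[2])
    bead_marker <- .paint_disk(bead_marker, bx, by, bead_radius, val)
    placed <- placed + 1L
  }
  bead_mask <- bead_marker > 0
  fluor <- pmax(fluor, bead_marker)
  fluor_raw <- fluor                        # pre-quantization
  fluor_q <- .quantize(fluor, params$bit_depth)

  ## ---- bright-field channel (noiseless) ------------------------------
  bg <- params$bf_level + .illumination_field(nr, nc,
                                              params$background_amplitude)
  bf <- bg
  bf[worm_mask] <- bg[worm_mask] * (1 - params$worm_contrast)
  bf_q <- .quantize(bf, params$bit_depth)

  ## ---- ground truth from the noiseless quantized render --------------
  in_worm_beads <- bead_mask & worm_mask
  expected_Aw <- sum(worm_mask)
  expected_bead_sum <- sum(fluor_q[in_worm_beads])
  expected_bead_sum_raw <- sum(fluor_raw[in_worm_beads])
  expected_ratio <- if (expected_Aw > 0) expected_bead_sum / expected_Aw else NA_real_

  ## ---- sensor noise --------------------------------------------------
  if (params$noise_sd > 0) {
    bf_out <- .quantize(bf + stats::rnorm(nr * nc, 0, params$noise_sd),
                        params$bit_depth)
    fl_out <- .quantize(fluor + stats::rnorm(nr * nc, 0, params$noise_sd),
                        params$bit_depth)
  } else {
    bf_out <- bf_q
    fl_out <- fluor_q
  }

  structure(list(
    params = params,
    images = list(brightfield = bf_out, fluorescence = fl_out),
    truth = list(worm_mask = worm_mask,
                 bead_mask = bead_mask,
                 per_worm_labels = labels,
                 responders = responders,
                 expected_Aw = expected_Aw,
                 expected_bead_sum = expected_bead_sum,
                 expected_bead_sum_raw = expected_bead_sum_raw,
                 expected_ratio = expected_ratio)
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_scene> %d x %d, %d worms (%d responders), ",
                     "Aw = %d px, expected ratio %.4f\n"),
              nrow(x$images$brightfield), ncol(x$images$brightfield),
              x$params$n_worms, length(x$truth$responders),
              x$truth$expected_Aw,
              if (is.na(x$truth$expected_ratio)) NA else
                x$truth$expected_ratio))
  invisible(x)
}
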