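#' @title Worm segmentation from the transmitted-light channel
#' @description Four-step morphological segmentation: top-hat background
#'   removal at the worm-width scale, Gaussian smoothing at twice the worm
#'   width, mean-intensity thresholding, and small-region filtering, with
#'   optional manual exclusion polygons.
#' @name segmentation
NULL

# coerce EBImage::Image results back to plain matrices
.as_matrix <- function(x) {
  if (methods::is(x, "Image")) x <- EBImage::imageData(x)
  m <- as.matrix(x)
  dimnames(m) <- NULL
  m
}

.check_grid <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0) {
    stop(arg, " must be a nonempty numeric matrix")
  }
  if (any(!is.finite(image))) stop(arg, " contains non-finite values")
  invisible(image)
}

#' Segmentation configuration
#'
#' Captures the two image-derived scale parameters the pipeline needs
#' (worm width in pixels and a typical single-worm area in pixels^2) and
#' the derived filter scales: the top-hat structuring-disk radius defaults
#' to the worm width and the Gaussian standard deviation to twice the worm
#' width. `polarity` states whether worms are darker or brighter than the
#' background in the transmitted-light channel.
#'
#' @param worm_width Worm width in pixels (>= 3).
#' @param typical_worm_area Typical area of one worm in pixels^2 (>= 1).
#' @param tophat_radius Structuring-disk radius in pixels; default
#'   `worm_width`.
#' @param gaussian_sigma Smoothing standard deviation in pixels; default
#'   `2 * worm_width`.
#' @param polarity `"dark_worms"` (default, standard transmitted-light
#'   appearance) or `"bright_worms"`.
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(worm_width, typical_worm_area,
                       tophat_radius = worm_width,
                       gaussian_sigma = 2 * worm_width,
                       polarity = c("dark_worms", "bright_worms")) {
  polarity <- match.arg(polarity)
  stopifnot(worm_width >= 3, typical_worm_area >= 1,
            tophat_radius >= 1, gaussian_sigma > 0)
  structure(list(worm_width = worm_width,
                 typical_worm_area = typical_worm_area,
                 tophat_radius = tophat_radius,
                 gaussian_sigma = gaussian_sigma,
                 polarity = polarity),
            class = "seg_config")
}

#' @export
print.seg_config <- function(x, ...) {
  cat(sprintf(paste0("<seg_config> worm_width %g px, typical area %g px^2, ",
                     "top-hat radius %g, sigma %g, %s\n"),
              x$worm_width, x$typical_worm_area, x$tophat_radius,
              x$gaussian_sigma, x$polarity))
  invisible(x)
}

#' Top-hat filter for background removal
#'
#' Subtracts the morphological opening (disk structuring element) from the
#' image, keeping features up to the disk radius in scale and suppressing
#' the slowly varying illumination background. For `dark_worms` the image
#' is first inverted (`max(image) - image`) so that worms become the bright
#' features the white top-hat retains.
#'
#' @param image Numeric intensity matrix.
#' @param radius Disk radius in pixels (>= 1, smaller than the image's
#'   shorter side).
#' @param polarity `"dark_worms"` or `"bright_worms"`.
#' @return Nonnegative intensity matrix of the same size.
#' @export
tophat_filter <- function(image, radius,
                          polarity = c("dark_worms", "bright_worms")) {
  polarity <- match.arg(polarity)
  .check_grid(image)
  radius <- as.integer(round(radius))
  if (radius < 1) stop("radius must be >= 1")
  if (radius >= min(dim(image))) {
    stop("top-hat radius (", radius, ") must be smaller than the image's ",
         "shorter side (", min(dim(image)), ")")
  }
  if (polarity == "dark_worms") image <- max(image) - image
  kern <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  # EBImage grayscale morphology operates on the [0, 1] range; min/max
  # filters commute with affine rescaling, so normalize and scale back
  lo <- min(image); rng <- max(image) - lo
  if (rng == 0) return(image * 0)
  scaled <- (image - lo) / rng
  opened <- .as_matrix(EBImage::opening(scaled, kern)) * rng + lo
  pmax(image - opened, 0)
}

#' Gaussian smoothing with reflective boundaries
#'
#' Convolves with a normalized Gaussian kernel after mirror-padding the
#' image, so border pixels are not dimmed (which would bias the subsequent
#' mean threshold). Total intensity of interior content is conserved.
#'
#' @param image Numeric intensity matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same size.
#' @export
smooth_gaussian <- function(image, sigma) {
  .check_grid(image)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  r <- as.integer(ceiling(3 * sigma))
  size <- 2L * r + 1L
  kern <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  padded <- .mirror_pad(image, r)
  sm <- .as_matrix(EBImage::filter2(padded, kern, boundary = "circular"))
  sm[(r + 1):(r + nrow(image)), (r + 1):(r + ncol(image)), drop = FALSE]
}

# mirror-pad a matrix by p pixels on every side; reflection is about the
# pixel centers (abcb-style) and works for p larger than the image
.mirror_pad <- function(m, p) {
  ri <- .reflect_index(seq_len(nrow(m) + 2L * p) - p, nrow(m))
  ci <- .reflect_index(seq_len(ncol(m) + 2L * p) - p, ncol(m))
  m[ri, ci, drop = FALSE]
}

# map arbitrary integer coordinates onto 1..n by mirror reflection
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  per <- 2L * (n - 1L)
  j <- (i - 1L) %% per
  ifelse(j < n, j + 1L, per - j + 1L)
}

#' Mean-intensity threshold
#'
#' Marks pixels strictly greater than the grand mean of the image as
#' foreground. On a constant image no pixel exceeds the mean, so the mask
#' is empty — a deterministic degenerate case.
#'
#' @param image Numeric intensity matrix.
#' @return Logical matrix.
#' @export
threshold_mean <- function(image) {
  .check_grid(image)
  image > mean(image)
}

#' Label connected components (8-connectivity)
#'
#' Integer labelling of a binary mask where pixels touching horizontally,
#' vertically or diagonally belong to the same component.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix; 0 is background, components numbered from 1.
#' @export
label_components <- function(mask) {
  mask <- .as_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- .as_matrix(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  # bwlabel is 4-connected; merge labels that touch diagonally
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- NULL
  if (nr > 1L && nc > 1L) {
    a <- lab[-nr, -nc]; b <- lab[-1, -1]        # down-right neighbours
    sel <- a > 0L & b > 0L & a != b
    p1 <- cbind(a[sel], b[sel])
    a <- lab[-1, -nc]; b <- lab[-nr, -1]        # up-right neighbours
    sel <- a > 0L & b > 0L & a != b
    pairs <- rbind(p1, cbind(a[sel], b[sel]))
  }
  nlab <- max(lab)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_len(nlab)
  }
  # renumber components consecutively
  memb <- as.integer(factor(memb))
  out <- matrix(0L, nr, nc)
  out[lab > 0L] <- memb[lab[lab > 0L]]
  out
}

.as_mask <- function(mask) {
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix")
  }
  mask
}

#' Remove small connected components
#'
#' Drops 8-connected components whose area is smaller than a typical worm
#' area; larger components are untouched. Idempotent.
#'
#' @param mask Logical matrix.
#' @param typical_worm_area Minimum component area in pixels^2 (>= 1).
#' @return Logical matrix.
#' @export
filter_small_regions <- function(mask, typical_worm_area) {
  mask <- .as_mask(mask)
  stopifnot(typical_worm_area >= 1)
  if (!any(mask)) return(mask)
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= typical_worm_area
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  out
}

#' Apply manual exclusion polygons to a worm mask
#'
#' Pixels whose centers fall inside any region-of-interest polygon
#' (even-odd fill rule, 1-based pixel-center coordinates) are set to
#' background, emulating manual removal of unwanted regions before the
#' worm area is measured. Self-intersecting polygons are rejected; the
#' offending ROI is named.
#'
#' @param mask Logical matrix.
#' @param rois List of polygons, each a two-column matrix or data.frame of
#'   `(x, y)` vertices (x = column, y = row); an optional `id` attribute or
#'   list name is recorded for provenance. Vertices outside the image are
#'   clipped implicitly (outside pixels simply do not exist).
#' @param typical_worm_area Used only to recount components consistently;
#'   not re-applied as a filter.
#' @return Object of class `worm_mask`: `mask`, `area_Aw`, `n_components`,
#'   `exclusions_applied`.
#' @export
apply_exclusions <- function(mask, rois = list(), typical_worm_area = NULL) {
  mask <- .as_mask(mask)
  ids <- character(0)
  if (length(rois) > 0) {
    nm <- names(rois)
    for (k in seq_along(rois)) {
      poly <- rois[[k]]
      id <- if (!is.null(attr(poly, "id"))) attr(poly, "id")
            else if (!is.null(nm) && nzchar(nm[k])) nm[k]
            else paste0("roi", k)
      poly <- as.matrix(as.data.frame(poly)[, 1:2])
      if (nrow(poly) < 3) stop("ROI '", id, "' has fewer than 3 vertices")
      if (.polygon_self_intersects(poly)) {
        stop("ROI '", id, "' is self-intersecting")
      }
      inside <- .rasterize_polygon(poly, nrow(mask), ncol(mask))
      mask[inside] <- FALSE
      ids <- c(ids, id)
    }
  }
  lab <- label_components(mask)
  structure(list(mask = mask,
                 area_Aw = sum(mask),
                 n_components = max(lab),
                 exclusions_applied = ids),
            class = "worm_mask")
}

#' @export
print.worm_mask <- function(x, ...) {
  cat(sprintf("<worm_mask> %d x %d, Aw = %d px, %d component(s)%s\n",
              nrow(x$mask), ncol(x$mask), x$area_Aw, x$n_components,
              if (length(x$exclusions_applied))
                paste0(", exclusions: ",
                       paste(x$exclusions_applied, collapse = ", "))
              else ""))
  invisible(x)
}

# even-odd (crossing number) polygon rasterization on pixel centers;
# returns a logical matrix
.rasterize_polygon <- function(poly, nr, nc) {
  px <- poly[, 1]; py <- poly[, 2]
  xr <- max(1L, floor(min(px))):min(nc, ceiling(max(px)))
  yr <- max(1L, floor(min(py))):min(nr, ceiling(max(py)))
  out <- matrix(FALSE, nr, nc)
  if (length(xr) == 0 || length(yr) == 0 ||
      min(px) > nc || max(px) < 1 || min(py) > nr || max(py) < 1) {
    return(out)
  }
  n <- nrow(poly)
  jx <- px[c(2:n, 1)]; jy <- py[c(2:n, 1)]
  for (yy in yr) {
    # edges crossing the horizontal line y = yy
    cr <- (py > yy) != (jy > yy)
    if (!any(cr)) next
    xint <- px[cr] + (yy - py[cr]) / (jy[cr] - py[cr]) * (jx[cr] - px[cr])
    crossings <- vapply(xr, function(xx) sum(xint > xx), integer(1))
    out[yy, xr[crossings %% 2L == 1L]] <- TRUE
  }
  out
}

# do any two non-adjacent edges properly intersect?
.polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  orient <- function(ax, ay, bx, by, cx, cy) {
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  }
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # shared vertex with closing edge
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- orient(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- orient(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- orient(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- orient(b[1], b[2], b[3], b[4], a[3], a[4])
      if (d1 != d2 && d3 != d4 && d1 != 0 && d2 != 0 && d3 != 0 && d4 != 0) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Segment worms from a transmitted-light image
#'
#' Runs the four-step detection in order: top-hat filtering at the
#' worm-width radius, Gaussian smoothing at `gaussian_sigma`, mean-intensity
#' thresholding, and small-region filtering, followed by any manual
#' exclusion polygons. The mask area is the worm-area estimate `Aw`.
#'
#' @param image Transmitted-light intensity matrix.
#' @param config A [seg_config()].
#' @param rois Optional list of exclusion polygons (see
#'   [apply_exclusions()]).
#' @return Object of class `worm_mask`.
#' @examples
#' sc <- generate_scene(scene_params(image_height = 256, image_width = 256,
#'                                   n_worms = 3, seed = 7))
#' wm <- segment_worms(sc$images$brightfield,
#'                     seg_config(worm_width = sc$params$worm_width,
#'                                typical_worm_area = 0.5 *
#'                                  sc$params$worm_width *
#'                                  min(sc$params$worm_length_range)))
#' wm$area_Aw
#' @export
segment_worms <- function(image, config, rois = list()) {
  stopifnot(inherits(config, "seg_config"))
  th <- tophat_filter(image, config$tophat_radius, config$polarity)
  sm <- smooth_gaussian(th, config$gaussian_sigma)
  mask <- threshold_mean(sm)
  mask <- filter_small_regions(mask, config$typical_worm_area)
  apply_exclusions(mask, rois)
}
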