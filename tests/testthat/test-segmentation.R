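test_that("top-hat of a constant image is zero and invalid radii are rejected", {
  img <- matrix(7, 12, 12)
  expect_equal(tophat_filter(img, 3), matrix(0, 12, 12))
  expect_error(tophat_filter(img, 12), "shorter side")
  expect_error(tophat_filter(img, 0), ">= 1")
})

test_that("top-hat keeps an isolated bright pixel intact (radius 1)", {
  img <- matrix(0, 7, 7); img[4, 4] <- 10
  expect_equal(tophat_filter(img, 1, polarity = "bright_worms"), img)
  # brute-force oracle agrees
  se <- EBImage::makeBrush(3, "disc")
  expect_equal(tophat_filter(img, 1, polarity = "bright_worms"),
               oracle_tophat(img, se))
})

test_that("top-hat agrees with the brute-force erosion/dilation oracle", {
  set.seed(21)
  for (k in 1:15) {
    n <- sample(6:16, 1); m <- sample(6:16, 1); r <- sample(1:2, 1)
    img <- matrix(round(runif(n * m, 0, 5000)), n, m)
    se <- EBImage::makeBrush(2 * r + 1, "disc")
    expect_equal(tophat_filter(img, r, polarity = "bright_worms"),
                 oracle_tophat(img, se), tolerance = 1e-9)
    # dark-worm polarity equals bright-polarity top-hat of the inverted image
    expect_equal(tophat_filter(img, r, polarity = "dark_worms"),
                 oracle_tophat(max(img) - img, se), tolerance = 1e-9)
  }
})

test_that("top-hat suppresses a ramp background but keeps a thin tube", {
  nr <- 40; nc <- 60
  ramp <- matrix(rep(seq(0, 2000, length.out = nc), each = nr), nr, nc)
  img <- ramp
  img[18:22, 10:50] <- img[18:22, 10:50] + 3000  # tube of width 5
  th <- tophat_filter(img, 5, polarity = "bright_worms")
  tube <- th[18:22, 15:45]
  # evaluate ramp suppression away from the lateral image borders, where
  # the opening necessarily deviates over one structuring-element radius
  outside <- th[c(1:10, 30:40), 8:52]
  expect_gt(min(tube), 0.9 * 3000)       # tube contrast preserved within 10%
  expect_lt(max(outside), 0.05 * 2000)   # ramp suppressed below 5% amplitude
})

test_that("Gaussian smoothing conserves mass and fixes constants", {
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- smooth_gaussian(imp, 2)
  expect_equal(sum(sm), 1, tolerance = 1e-3)       # impulse response sums to 1
  expect_equal(which.max(sm), which.max(imp))      # centered
  cst <- matrix(4.2, 9, 13)
  expect_equal(smooth_gaussian(cst, 3), cst, tolerance = 1e-9)
  expect_error(smooth_gaussian(cst, 0), "sigma")
})

test_that("mean threshold is strict and deterministic on degenerate input", {
  expect_false(any(threshold_mean(matrix(5, 8, 8))))
  half <- matrix(c(rep(0, 32), rep(100, 32)), 8, 8)
  expect_equal(threshold_mean(half), half > 50)
  one <- matrix(0, 10, 10); one[3, 7] <- 9
  expect_equal(sum(threshold_mean(one)), 1)
})

test_that("small-region filtering drops sub-worm components and is idempotent", {
  mask <- matrix(FALSE, 40, 40)
  mask[2:11, 2:6] <- TRUE        # 50 px
  mask[15:39, 10:29] <- TRUE     # 500 px
  f <- filter_small_regions(mask, 100)
  expect_equal(sum(f), 500)
  expect_equal(filter_small_regions(f, 100), f)   # idempotent
  expect_equal(filter_small_regions(mask, 1), mask)
  empty <- matrix(FALSE, 5, 5)
  expect_equal(filter_small_regions(empty, 10), empty)
})

test_that("component labelling uses 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  m[5, 5] <- TRUE                                    # separate
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_true(lab[5, 5] != lab[1, 1])
  # diagonal component survives an area filter as one region
  expect_equal(sum(filter_small_regions(m, 3)), 3)
})

test_that("exclusion ROIs carve pixels out and record provenance", {
  mask <- matrix(TRUE, 20, 20)
  wm <- apply_exclusions(mask, list())
  expect_equal(wm$area_Aw, 400)
  expect_equal(wm$exclusions_applied, character(0))
  # whole-image ROI empties the mask
  all_roi <- cbind(x = c(0, 21, 21, 0), y = c(0, 0, 21, 21))
  expect_equal(apply_exclusions(mask, list(all_roi))$area_Aw, 0)
  # a 5x5 box removes exactly 25 pixel centers
  box <- cbind(x = c(2.5, 7.5, 7.5, 2.5), y = c(2.5, 2.5, 7.5, 7.5))
  attr(box, "id") <- "lint"
  wm2 <- apply_exclusions(mask, list(box))
  expect_equal(wm2$area_Aw, 400 - 25)
  expect_equal(wm2$exclusions_applied, "lint")
  # self-intersecting bow-tie is rejected by name
  bow <- cbind(x = c(1, 10, 1, 10), y = c(1, 10, 10, 1))
  attr(bow, "id") <- "bowtie"
  expect_error(apply_exclusions(mask, list(bow)), "bowtie")
})

test_that("excluding one worm removes exactly its ground-truth area", {
  p <- scene_params(image_height = 200, image_width = 200, n_worms = 2,
                    worm_width = 8, worm_length_range = c(50, 70),
                    clump_fraction = 0, noise_sd = 0,
                    background_amplitude = 0, stray_bead_rate = 0, seed = 3)
  sc <- generate_scene(p)
  labs <- sc$truth$per_worm_labels
  # worm 1 pixels (not overlapped by worm 2)
  target <- labs == 1L
  expect_gt(sum(target), 0)
  idx <- which(target, arr.ind = TRUE)
  roi <- cbind(x = c(min(idx[, 2]) - 1, max(idx[, 2]) + 1,
                     max(idx[, 2]) + 1, min(idx[, 2]) - 1),
               y = c(min(idx[, 1]) - 1, min(idx[, 1]) - 1,
                     max(idx[, 1]) + 1, max(idx[, 1]) + 1))
  # ROI is worm 1's bounding box; require the worms not to overlap there
  other <- labs == 2L
  in_roi <- matrix(FALSE, 200, 200)
  in_roi[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2])] <- TRUE
  expect_false(any(other & in_roi))  # this draw keeps the worms apart
  wm <- apply_exclusions(sc$truth$worm_mask, list(roi))
  expect_equal(wm$area_Aw, sc$truth$expected_Aw - sum(target))
})

test_that("segment_worms composes the four steps in the documented order", {
  p <- small_scene_params(seed = 9, noise_sd = 0)
  sc <- generate_scene(p)
  cfg <- small_seg_config(p)
  wm <- segment_worms(sc$images$brightfield, cfg)
  manual <- tophat_filter(sc$images$brightfield, cfg$tophat_radius,
                          cfg$polarity)
  manual <- smooth_gaussian(manual, cfg$gaussian_sigma)
  manual <- threshold_mean(manual)
  manual <- filter_small_regions(manual, cfg$typical_worm_area)
  expect_equal(wm$mask, manual)
  expect_equal(wm$area_Aw, sum(manual))
})

test_that("a permuted pipeline order gives a different answer on salt noise", {
  set.seed(33)
  img <- matrix(20000, 120, 120)
  img[40:80, 30:40] <- 9000                  # one worm-scale dark bar
  specks <- sample(120 * 120, 40)
  img[specks] <- 6000                        # salt: isolated dark pixels
  cfg <- seg_config(worm_width = 9, typical_worm_area = 200)
  wm <- segment_worms(img, cfg)
  expect_equal(wm$n_components, 1)           # specks filtered out
  # permuted order: smooth before top-hat
  perm <- smooth_gaussian(img, cfg$gaussian_sigma)
  perm <- tophat_filter(perm, cfg$tophat_radius, cfg$polarity)
  perm_mask <- filter_small_regions(threshold_mean(perm),
                                    cfg$typical_worm_area)
  expect_false(isTRUE(all.equal(wm$mask, perm_mask)))
})

test_that("blank fields segment to zero worm area", {
  wm <- segment_worms(matrix(1000, 64, 64), seg_config(5, 50))
  expect_equal(wm$area_Aw, 0)
  expect_equal(wm$n_components, 0)
})

test_that("adding a worm-sized object increases the worm area", {
  p <- small_scene_params(seed = 14)
  sc <- generate_scene(p)
  cfg <- small_seg_config(p)
  base <- segment_worms(sc$images$brightfield, cfg)$area_Aw
  img2 <- sc$images$brightfield
  img2[20:90, 140:147] <- 9000   # extra dark tube in a free corner
  more <- segment_worms(img2, cfg)$area_Aw
  expect_gt(more, base)
})
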