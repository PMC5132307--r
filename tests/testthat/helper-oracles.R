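# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: morphology is a literal min/max
# scan, quantification a double pixel loop, the Mann-Whitney p-value a full
# enumeration of labelings, and the Holm decision the textbook step-down.

oracle_erode <- function(img, se) {
  r <- (nrow(se) - 1) / 2
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    best <- Inf
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img)) {
        best <- min(best, img[ii, jj])
      }
    }
    out[i, j] <- best
  }
  out
}

oracle_dilate <- function(img, se) {
  r <- (nrow(se) - 1) / 2
  out <- img
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    best <- -Inf
    for (di in -r:r) for (dj in -r:r) {
      if (se[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(img) && jj >= 1 && jj <= ncol(img)) {
        best <- max(best, img[ii, jj])
      }
    }
    out[i, j] <- best
  }
  out
}

# white top-hat by brute force: image minus (erosion then dilation)
oracle_tophat <- function(img, se) {
  pmax(img - oracle_dilate(oracle_erode(img, se), se), 0)
}

# naive double-loop quantification
oracle_measure <- function(worm, beads, fluor) {
  Aw <- 0L; Am <- 0L; s <- 0
  for (i in seq_len(nrow(fluor))) for (j in seq_len(ncol(fluor))) {
    if (worm[i, j]) Aw <- Aw + 1L
    if (worm[i, j] && beads[i, j]) {
      Am <- Am + 1L
      s <- s + fluor[i, j]
    }
  }
  list(Aw = Aw, Am = Am, bead_sum = s,
       ratio = if (Aw > 0) s / Aw else NA_real_)
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a); n <- length(pooled)
  u_of <- function(idx) {
    aa <- pooled[idx]; bb <- pooled[-idx]
    sum(outer(aa, bb, ">")) + 0.5 * sum(outer(aa, bb, "=="))
  }
  u_obs <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# textbook step-down Holm decisions, original order
oracle_holm <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (k in seq_len(m)) {
    if (p[ord[k]] <= alpha / (m - k + 1)) {
      reject[ord[k]] <- TRUE
    } else {
      break
    }
  }
  reject
}

# small fast scene for tests that need a full synthetic field of view
small_scene_params <- function(seed, ...) {
  defaults <- list(image_height = 160, image_width = 160, n_worms = 4,
                   worm_width = 8, worm_length_range = c(50, 80),
                   beads_per_responder_range = c(8, 16),
                   stray_bead_rate = 1, background_amplitude = 1500,
                   bf_level = 20000, noise_sd = 50, seed = seed)
  do.call(scene_params, utils::modifyList(defaults, list(...)))
}

small_seg_config <- function(p) {
  seg_config(worm_width = p$worm_width,
             typical_worm_area = 0.5 * p$worm_width *
               min(p$worm_length_range))
}
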