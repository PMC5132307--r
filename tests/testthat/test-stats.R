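test_that("control group normalizes to exactly 100% on average", {
  df <- data.frame(condition = c("BE", "BE", "X"), solvent = "water",
                   ratio = c(2, 4, 6))
  nz <- normalize_activity(df, "BE")
  expect_equal(mean(nz$pct[nz$condition == "BE"]), 100)
  expect_equal(nz$pct[3], 200)   # 6 / mean(2,4) * 100
  expect_equal(attr(nz, "control_mean"), 3)
})

test_that("the maximum-effect solvent is chosen for normalization", {
  df <- data.frame(
    condition = c("BE", "BE", "BE", "BE", "X", "X"),
    solvent = c("water", "water", "NaOH", "NaOH", "water", "water"),
    ratio = c(70, 90, 110, 130, 60, 60))
  nz <- normalize_activity(df, "BE")
  expect_equal(attr(nz, "control_solvent"), "NaOH")
  expect_equal(attr(nz, "control_mean"), 120)
  expect_equal(mean(nz$pct[nz$condition == "BE" & nz$solvent == "NaOH"]), 100)
  expect_equal(nz$pct[5], 50)
})

test_that("normalization is invariant to a global gain rescaling", {
  set.seed(2)
  df <- data.frame(condition = rep(c("BE", "A", "B"), each = 6),
                   solvent = "borate",
                   ratio = runif(18, 0.5, 8))
  nz1 <- normalize_activity(df, "BE")
  df2 <- df; df2$ratio <- df2$ratio * 37.5
  nz2 <- normalize_activity(df2, "BE")
  expect_equal(nz1$pct, nz2$pct, tolerance = 1e-9)
})

test_that("missing or degenerate controls are rejected", {
  df <- data.frame(condition = "X", solvent = "w", ratio = 1)
  expect_error(normalize_activity(df, "BE"), "control")
  zero <- data.frame(condition = "BE", solvent = "w", ratio = c(0, 0))
  expect_error(normalize_activity(zero, "BE"), "zero")
  # invalid measurements (Aw = 0 fields) are dropped before normalizing
  df3 <- data.frame(condition = c("BE", "BE"), solvent = "w",
                    ratio = c(4, NA), valid = c(TRUE, FALSE))
  expect_equal(nrow(normalize_activity(df3, "BE")), 1)
})

test_that("exact Mann-Whitney p matches full enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p, 1 / 3, tolerance = 1e-12)
  expect_equal(mw$p, oracle_mw_exact(c(1, 2), c(3, 4)), tolerance = 1e-12)
  # random tie-free samples
  set.seed(3)
  for (k in 1:10) {
    a <- sample(1:100, sample(2:6, 1))
    b <- sample(101:200, sample(2:6, 1)) - runif(1)
    expect_equal(mann_whitney(a, b)$p, oracle_mw_exact(a, b),
                 tolerance = 1e-10)
  }
})

test_that("Mann-Whitney is symmetric and falls back to the tie-corrected
           normal approximation", {
  a <- c(1, 5, 7, 9); b <- c(2, 3, 8, 11)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(b, a)$p)
  tied <- mann_whitney(c(0, 0, 0, 1), c(0, 0, 2, 3))
  expect_equal(tied$method, "normal_approximation")
  expect_true(tied$p > 0 && tied$p <= 1)
  big <- mann_whitney(rnorm(20), rnorm(20))
  expect_equal(big$method, "normal_approximation")
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("exact and approximate p-values agree within 0.05 on small samples", {
  set.seed(8)
  for (k in 1:40) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- rnorm(n1); b <- rnorm(n2, mean = runif(1, -1, 1))
    p_exact <- mann_whitney(a, b)$p
    p_approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(p_exact - p_approx), 0.05)
  }
})

test_that("Holm decisions match the step-down definition", {
  expect_equal(holm_adjust(0.04, 0.05), TRUE)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_equal(holm_adjust(rep(1, 5), 0.05), rep(FALSE, 5))
  set.seed(19)
  for (k in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    expect_equal(holm_adjust(p, 0.05), oracle_holm(p, 0.05))
  }
})

test_that("Holm sits between per-test alpha and Bonferroni", {
  set.seed(27)
  for (k in 1:100) {
    m <- sample(2:10, 1)
    p <- runif(m)^2
    holm <- holm_adjust(p, 0.05)
    bonf <- p <= 0.05 / m
    unadj <- p <= 0.05
    expect_true(all(holm[bonf]))      # never stricter than Bonferroni
    expect_true(all(unadj[holm]))     # never more permissive than raw alpha
  }
})

test_that("significance tiers follow the figure thresholds", {
  expect_equal(significance_tier(5e-4, TRUE), "*")
  expect_equal(significance_tier(1e-4, TRUE), "**")
  expect_equal(significance_tier(9e-6, TRUE), "***")
  expect_equal(significance_tier(0.004, TRUE), "(*)")
  expect_equal(significance_tier(0.004, FALSE), "ns")
  expect_equal(significance_tier(0.5, FALSE), "ns")
})

test_that("compare_groups assembles the comparison family correctly", {
  set.seed(41)
  df <- data.frame(
    condition = rep(c("water", "NAD", "BE"), each = 8),
    pct = c(rnorm(8, 5, 2), rnorm(8, 80, 10), rnorm(8, 100, 10)))
  out <- compare_groups(df, "water")
  expect_equal(nrow(out), 2)
  expect_true(all(out$reference == "water"))
  expect_true(all(out$holm_reject))
  expect_true(all(out$tier != "ns"))
  expect_error(compare_groups(df, "absent"), "not present")
})

test_that("a noiseless cubic is interpolated by the dose-response fit", {
  x <- c(0, 0.5, 1, 2, 3, 5, 7.5, 10)
  y <- 2 + 3 * x - 1.5 * x^2 + 0.25 * x^3
  fit <- fit_dose_response(x, y)
  expect_lt(max(abs(fit$fitted - y)), 1e-8)
  # residual variance ~ 0 so the confidence band collapses
  expect_lt(max(fit$upper - fit$lower), 1e-6)
  expect_true(all(fit$lower <= fit$fitted + 1e-12))
  expect_true(all(fit$fitted <= fit$upper + 1e-12))
})

test_that("orthogonal basis columns are orthogonal on the design points", {
  x <- c(0, 0.1, 0.3, 1, 3, 10, 10, 3)   # repeated doses allowed
  fit <- fit_dose_response(x, rnorm(length(x)))
  g <- crossprod(fit$basis)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-10)
})

test_that("orthogonal fit equals a raw-power cubic least squares fit", {
  set.seed(55)
  for (k in 1:10) {
    x <- sort(runif(9, 0, 10))
    y <- rnorm(9, 50, 20)
    fit <- fit_dose_response(x, y)
    raw <- lm(y ~ x + I(x^2) + I(x^3))
    expect_lt(max(abs(fit$fitted - fitted(raw))), 1e-8)
  }
})

test_that("under-determined dose designs are rejected", {
  expect_error(fit_dose_response(c(1, 2, 3, 4), c(1, 2, 3, 4)),
               "order \\+ 2")
  expect_error(fit_dose_response(c(1, 1, 2, 2, 3, 3), rnorm(6)),
               "distinct")
})

test_that("dose-response prediction reproduces the design-point band", {
  set.seed(60)
  x <- rep(c(0, 1, 3, 10, 30), each = 3)
  y <- 100 / (1 + exp(-(x - 5))) + rnorm(15, 0, 4)
  fit <- fit_dose_response(x, y)
  pr <- predict(fit)
  expect_equal(pr$fit, fit$fitted, tolerance = 1e-10)
  expect_equal(pr$lwr, fit$lower, tolerance = 1e-10)
  fine <- predict(fit, newdata = seq(0, 30, length.out = 7))
  expect_true(all(fine$lwr <= fine$fit & fine$fit <= fine$upr))
})
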