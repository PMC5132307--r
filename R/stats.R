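#' @title Group statistics for the bead-feeding bioassay
#' @description Normalization of per-image activity ratios to the positive
#'   control (bacterial extract in its most effective solvent, defined as
#'   100%), two-sided Mann-Whitney comparisons with Bonferroni-Holm
#'   correction and figure-style significance tiers, and orthogonal-
#'   polynomial dose-response fits with pointwise confidence bands.
#' @name assaystats
NULL

#' Normalize activity ratios to the positive control
#'
#' Each per-image ratio is expressed as a percentage of the mean ratio of
#' the positive-control group, which is defined as 100%. When the control
#' condition was run in several solvents, the solvent in which the control
#' shows the maximum mean ratio is used for normalization (the
#' maximum-effect rule). The experimental unit is the image.
#'
#' @param measurements `data.frame` with at least columns `condition`,
#'   `solvent`, `ratio` (one row per image), e.g. built by
#'   `rbind`-ing [as.data.frame.activity_measurement()] rows.
#' @param control_condition Label of the positive-control condition
#'   (e.g. `"BE"`).
#' @return The input `data.frame` with a `pct` column appended, plus
#'   attributes `control_condition`, `control_solvent`, `control_mean`
#'   (arithmetic mean of the control group's raw ratios).
#' @examples
#' df <- data.frame(condition = c("BE", "BE", "X", "X"),
#'                  solvent = "water", ratio = c(2, 4, 6, 3))
#' normalize_activity(df, "BE")$pct  # control mean 3 -> 66.7 133.3 200 100
#' @export
normalize_activity <- function(measurements, control_condition) {
  req <- c("condition", "ratio")
  if (!all(req %in% names(measurements))) {
    stop("measurements must have columns: ", paste(req, collapse = ", "))
  }
  if (!"solvent" %in% names(measurements)) measurements$solvent <- "none"
  if ("valid" %in% names(measurements)) {
    measurements <- measurements[measurements$valid %in% TRUE, , drop = FALSE]
  }
  ctrl <- measurements[measurements$condition == control_condition, ,
                       drop = FALSE]
  if (nrow(ctrl) == 0) {
    stop("control condition '", control_condition, "' has no valid measurements")
  }
  means <- tapply(ctrl$ratio, ctrl$solvent, mean)
  control_solvent <- names(means)[which.max(means)]
  control_mean <- means[[control_solvent]]
  if (control_mean == 0) {
    stop("control group mean ratio is zero; normalization undefined")
  }
  measurements$pct <- 100 * measurements$ratio / control_mean
  attr(measurements, "control_condition") <- control_condition
  attr(measurements, "control_solvent") <- control_solvent
  attr(measurements, "control_mean") <- control_mean
  measurements
}

#' Two-sided Mann-Whitney test
#'
#' Computes the Mann-Whitney U statistic for the first sample and a
#' two-sided p-value: from the exact null distribution when both samples
#' have at most 12 observations and no ties are present, otherwise from
#' the normal approximation with midranks, tie-corrected variance and
#' continuity correction. The method used is recorded.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @return List with `U`, `p`, `method` (`"exact"` or
#'   `"normal_approximation"`), `n1`, `n2`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 12 && length(b) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approximation",
       n1 = length(a), n2 = length(b))
}

#' Bonferroni-Holm rejection decisions
#'
#' Step-down Holm procedure at family-wise level `alpha`: p-values are
#' sorted ascending and p(k) is rejected while p(k) <= alpha / (m - k + 1),
#' stopping at the first failure. Decisions are returned in the original
#' order. Never more permissive than the per-test level and never stricter
#' than Bonferroni.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level (default 0.05).
#' @return Logical vector of rejection decisions.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  if (length(p) == 0) return(logical(0))
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Significance tier label
#'
#' Figure-style tiers: `"*"` for p <= 0.001, `"**"` for p <= 1e-4,
#' `"***"` for p <= 1e-5; `"(*)"` marks comparisons that are significant
#' under the Bonferroni-Holm correction without reaching the starred
#' thresholds; `"ns"` otherwise.
#'
#' @param p_raw Raw p-value(s).
#' @param holm_reject Logical Holm decision(s), same length.
#' @return Character vector of tier labels.
#' @export
significance_tier <- function(p_raw, holm_reject) {
  stopifnot(length(p_raw) == length(holm_reject))
  ifelse(p_raw <= 1e-5, "***",
    ifelse(p_raw <= 1e-4, "**",
      ifelse(p_raw <= 1e-3, "*",
        ifelse(holm_reject, "(*)", "ns"))))
}

#' Compare condition groups against a reference
#'
#' Runs a two-sided Mann-Whitney test of every non-reference condition
#' against the reference (typically the negative control of one figure
#' panel), applies the Bonferroni-Holm correction across that family, and
#' attaches significance tiers.
#'
#' @param normalized `data.frame` with columns `condition` and `pct`
#'   (see [normalize_activity()]); any other value column can be selected
#'   with `value`.
#' @param reference Condition label to test against.
#' @param alpha Family-wise level for the Holm decisions (default 0.05).
#' @param value Name of the value column (default `"pct"`).
#' @return `data.frame` with one row per comparison: `condition`,
#'   `reference`, `n1`, `n2`, `U`, `p_raw`, `method`, `holm_reject`,
#'   `tier`.
#' @export
compare_groups <- function(normalized, reference, alpha = 0.05,
                           value = "pct") {
  stopifnot(value %in% names(normalized),
            "condition" %in% names(normalized))
  if (!reference %in% normalized$condition) {
    stop("reference condition '", reference, "' not present")
  }
  ref_vals <- normalized[[value]][normalized$condition == reference]
  conds <- setdiff(unique(normalized$condition), reference)
  rows <- lapply(conds, function(cc) {
    v <- normalized[[value]][normalized$condition == cc]
    mw <- mann_whitney(v, ref_vals)
    data.frame(condition = cc, reference = reference,
               n1 = mw$n1, n2 = mw$n2, U = mw$U, p_raw = mw$p,
               method = mw$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$holm_reject <- holm_adjust(out$p_raw, alpha)
  out$tier <- significance_tier(out$p_raw, out$holm_reject)
  rownames(out) <- NULL
  out
}

#' Orthogonal-polynomial dose-response fit
#'
#' Linear least-squares fit of normalized response against concentration
#' in an orthogonal polynomial basis built on the design points (degree 3
#' by default), with a pointwise confidence band from the t distribution
#' on the residual degrees of freedom. The fitted values are identical to
#' those of a raw-power polynomial fit of the same degree; the orthogonal
#' basis only conditions the solve.
#'
#' @param concentrations Numeric dose values (mM).
#' @param responses Normalized activities (percent), same length.
#' @param order Polynomial degree (default 3).
#' @param level Confidence level for the band (default 0.95).
#' @return Object of class `dose_response_fit`: `concentrations`,
#'   `responses`, `order`, `coefficients` (orthogonal basis), `basis`,
#'   `fitted`, `lower`, `upper`, `df_residual`, `sigma`, `level`.
#' @export
fit_dose_response <- function(concentrations, responses, order = 3,
                              level = 0.95) {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(x) != length(y)) stop("concentrations and responses differ in length")
  n_distinct <- length(unique(x))
  if (length(x) < order + 2) {
    stop("need at least order + 2 = ", order + 2, " points, got ", length(x))
  }
  if (n_distinct < order + 1) {
    stop("need at least order + 1 = ", order + 1,
         " distinct concentrations, got ", n_distinct)
  }
  basis <- stats::poly(x, degree = order)
  fit <- stats::lm(y ~ basis)
  pred <- stats::predict(fit, interval = "confidence", level = level)
  structure(list(concentrations = x,
                 responses = y,
                 order = order,
                 coefficients = stats::coef(fit),
                 basis = unclass(basis),
                 fitted = unname(pred[, "fit"]),
                 lower = unname(pred[, "lwr"]),
                 upper = unname(pred[, "upr"]),
                 df_residual = fit$df.residual,
                 # a perfect (interpolating) fit is legitimate here; silence
                 # summary.lm's warning about it
                 sigma = suppressWarnings(summary(fit)$sigma),
                 level = level),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("<dose_response_fit> degree %d on %d points ",
                     "(%d distinct doses), residual df %d, sigma %.4g\n"),
              x$order, length(x$concentrations),
              length(unique(x$concentrations)), x$df_residual, x$sigma))
  invisible(x)
}

#' Predict from a dose-response fit at new doses
#'
#' @param object A `dose_response_fit`.
#' @param newdata Optional numeric vector of concentrations; defaults to
#'   the design points.
#' @param ... Unused.
#' @return `data.frame` with `concentration`, `fit`, `lwr`, `upr`.
#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- object$concentrations
  if (is.null(newdata)) newdata <- x
  basis <- stats::poly(x, degree = object$order)
  nb <- stats::predict(basis, as.numeric(newdata))
  fit <- stats::lm(object$responses ~ basis)
  pred <- stats::predict(fit, newdata = list(basis = nb),
                         interval = "confidence", level = object$level)
  data.frame(concentration = as.numeric(newdata),
             fit = unname(pred[, "fit"]),
             lwr = unname(pred[, "lwr"]),
             upr = unname(pred[, "upr"]))
}
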