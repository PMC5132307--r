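#' @title Monoisotopic mass and fragment-matching toolkit
#' @description Helpers for the arithmetic behind high-resolution MS
#'   identification: elemental formulas, monoisotopic masses, ion m/z with
#'   electron-mass correction, and ppm-tolerance matching of observed peaks
#'   against candidate ions.
#' @name massid
NULL

# Monoisotopic masses (Da) of the most abundant isotope, IUPAC values.
.MONOISOTOPIC <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

.ELECTRON_MASS <- 0.00054857990  # Da

#' Parse an elemental formula
#'
#' Converts a Hill-style formula string such as `"C21H28N7O14P2"` into a
#' named integer vector of element counts. Already-parsed named numeric
#' vectors are validated and passed through.
#'
#' @param x Formula string, or a named numeric vector of element counts.
#' @return Named integer vector (element -> count), zero counts dropped.
#' @examples
#' parse_formula("H2O")
#' parse_formula("C6H6N2O")  # nicotinamide
#' @export
parse_formula <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
  } else if (is.character(x) && length(x) == 1L) {
    if (!nzchar(x)) return(integer(0))
    m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
    parts <- regmatches(x, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x)) {
      stop("cannot parse formula: '", x, "'")
    }
    el <- sub("[0-9]+$", "", parts)
    n <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
    counts <- tapply(n, el, sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    stop("formula must be a string or a named numeric vector")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be nonnegative integers")
  }
  counts <- counts[counts > 0]
  stats::setNames(as.integer(counts), names(counts))
}

#' Add or subtract elemental formulas
#'
#' `formula_add()` sums element counts; `formula_subtract()` removes a
#' neutral loss and fails if any element count would become negative.
#'
#' @param a,b Formulas (strings or named count vectors).
#' @return Named integer vector of element counts.
#' @export
formula_add <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out[out > 0]
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- parse_formula(a); b <- parse_formula(b)
  els <- union(names(a), names(b))
  out <- stats::setNames(integer(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] - b
  if (any(out < 0)) {
    stop("neutral loss leaves negative count for: ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  out[out > 0]
}

#' Monoisotopic mass of an elemental formula
#'
#' Sum over elements of count times the mass of the most abundant isotope.
#'
#' @param formula Formula string or named count vector.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.010565
#' monoisotopic_mass("C6H6N2O")    # nicotinamide, 122.048013
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(.MONOISOTOPIC))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  sum(.MONOISOTOPIC[names(f)] * f)
}

#' Construct an ion specification
#'
#' The formula is that of the intact ion (protons included for protonated
#' adducts); the charge carries the sign of the ionization mode.
#'
#' @param formula Formula of the intact ion.
#' @param charge Signed integer charge; must be nonzero.
#' @param label Human-readable ion label, e.g. `"[NAD+H]+"`.
#' @return Object of class `ion_spec`.
#' @export
ion <- function(formula, charge = 1L, label = NULL) {
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge == 0L) {
    stop("charge must be a nonzero integer")
  }
  f <- parse_formula(formula)
  if (is.null(label)) {
    label <- paste0(paste0(names(f), ifelse(f > 1, f, "")), collapse = "")
  }
  structure(list(formula = f, charge = charge, label = label),
            class = "ion_spec")
}

#' @export
print.ion_spec <- function(x, ...) {
  cat(sprintf("<ion_spec> %s  charge %+d  m/z %.4f\n",
              x$label, x$charge, ion_mz(x)))
  invisible(x)
}

#' Theoretical m/z of an ion
#'
#' `(monoisotopic mass - charge * electron mass) / |charge|`. The electron
#' mass correction (0.00054858 Da) shifts m/z by about 0.8 ppm at m/z 664,
#' material at Orbitrap-level mass accuracy.
#'
#' @param x An `ion_spec` from [ion()].
#' @return m/z value.
#' @examples
#' ion_mz(ion("H", charge = 1))  # proton, 1.007276
#' @export
ion_mz <- function(x) {
  stopifnot(inherits(x, "ion_spec"))
  (monoisotopic_mass(x$formula) - x$charge * .ELECTRON_MASS) / abs(x$charge)
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  1e6 * (observed - theoretical) / theoretical
}

#' Built-in NAD+ fragment ion series
#'
#' Candidate ions for the protonated NAD+ precursor and its main positive-
#' mode fragments, assembled by neutral-loss arithmetic from the NAD+
#' formula C21H27N7O14P2: loss of nicotinamide (C6H6N2O), further loss of
#' water, the protonated ADP fragment, adenosine after loss of two waters,
#' and protonated adenine.
#'
#' @return List of `ion_spec` objects with human-readable labels.
#' @examples
#' sapply(nad_fragment_series(), ion_mz)
#' @export
nad_fragment_series <- function() {
  nad_h <- formula_add("C21H27N7O14P2", "H")     # [NAD+H]+
  nicotinamide <- "C6H6N2O"
  list(
    ion(nad_h, 1L, "[NAD+H]+"),
    ion(formula_subtract(nad_h, nicotinamide), 1L, "[NAD+H-nicotinamide]+"),
    ion(formula_subtract(formula_subtract(nad_h, nicotinamide), "H2O"),
        1L, "[NAD+H-nicotinamide-H2O]+"),
    ion(formula_add("C10H15N5O10P2", "H"), 1L, "[ADP+H]+"),
    ion(formula_subtract(formula_add("C10H13N5O4", "H"), "H4O2"),
        1L, "[adenosine+H-2H2O]+"),
    ion(formula_add("C5H5N5", "H"), 1L, "[adenine+H]+")
  )
}

#' Match observed m/z values against candidate ions
#'
#' Every observed value is compared with every candidate; pairs within the
#' ppm tolerance are reported as matches, and observed values matching no
#' candidate appear with `NA` candidate columns so nothing is silently
#' dropped.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param candidates List of `ion_spec` objects (e.g.
#'   [nad_fragment_series()]).
#' @param tol_ppm Matching tolerance in ppm (default 5, Orbitrap-class).
#' @return `data.frame` with columns `observed_mz`, `label`, `formula`,
#'   `charge`, `theoretical_mz`, `error_ppm`, `matched`.
#' @export
match_fragments <- function(observed, candidates = nad_fragment_series(),
                            tol_ppm = 5) {
  stopifnot(is.numeric(observed), tol_ppm > 0)
  if (length(candidates) > 0 &&
      !all(vapply(candidates, inherits, logical(1), "ion_spec"))) {
    stop("candidates must be a list of ion_spec objects")
  }
  theo <- vapply(candidates, ion_mz, numeric(1))
  rows <- lapply(observed, function(mz) {
    if (length(candidates) > 0) {
      err <- ppm_error(mz, theo)
      hit <- which(abs(err) <= tol_ppm)
    } else {
      hit <- integer(0)
    }
    if (length(hit) == 0) {
      return(data.frame(observed_mz = mz, label = NA_character_,
                        formula = NA_character_, charge = NA_integer_,
                        theoretical_mz = NA_real_, error_ppm = NA_real_,
                        matched = FALSE, stringsAsFactors = FALSE))
    }
    data.frame(
      observed_mz = mz,
      label = vapply(candidates[hit], function(i) i$label, character(1)),
      formula = vapply(candidates[hit], function(i)
        paste0(paste0(names(i$formula),
                      ifelse(i$formula > 1, i$formula, "")), collapse = ""),
        character(1)),
      charge = vapply(candidates[hit], function(i) i$charge, integer(1)),
      theoretical_mz = theo[hit],
      error_ppm = err[hit],
      matched = TRUE,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a peak list from CSV
#'
#' Expects at least an `mz` column; an `intensity` column is carried along
#' if present.
#'
#' @param path Path to a two-column CSV (m/z, intensity).
#' @return `data.frame` with columns `mz` and, when available, `intensity`.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!"mz" %in% names(df)) {
    # fall back to positional interpretation of a plain two-column file
    if (ncol(df) >= 1) names(df)[1] <- "mz"
    if (ncol(df) >= 2) names(df)[2] <- "intensity"
  }
  if (!is.numeric(df$mz)) stop("peak list must have a numeric m/z column: ", path)
  df
}

#' Annotate a peak list against the NAD+ series
#'
#' Convenience wrapper: reads a peak CSV, matches against candidates, and
#' optionally writes the annotation table.
#'
#' @param peaks_csv Input peak list (see [read_peaks()]).
#' @param out Optional output path; `.json` writes JSON, anything else CSV.
#' @inheritParams match_fragments
#' @return The annotation `data.frame`, invisibly when `out` is given.
#' @export
annotate_peaks <- function(peaks_csv, candidates = nad_fragment_series(),
                           tol_ppm = 5, out = NULL) {
  peaks <- read_peaks(peaks_csv)
  ann <- match_fragments(peaks$mz, candidates, tol_ppm)
  if (!is.null(out)) {
    if (grepl("\\.json$", out, ignore.case = TRUE)) {
      jsonlite::write_json(ann, out, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null")
    } else {
      utils::write.csv(format(ann, digits = 10, trim = TRUE), out,
                       row.names = FALSE)
    }
    return(invisible(ann))
  }
  ann
}
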