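#' Parse a Hill-style molecular formula
#'
#' Converts a plain molecular formula string such as `"C5H9NO4"` into a
#' named integer vector of element counts.  Symbols are one uppercase
#' letter plus an optional lowercase letter, each followed by an optional
#' integer count (absent count means 1); repeated symbols accumulate.
#'
#' Formulas containing parentheses, charges, dots or generic R-groups
#' (as found in parts of the ModelSEED dump) are rejected with an
#' `unsupported_formula` condition so callers can skip and log them;
#' an element symbol outside the supported table raises a
#' `formula_parse_error` naming the symbol.
#'
#' @param text Single non-empty formula string.
#' @return Named integer vector of counts, names ordered as first seen.
#' @examples
#' parseFormula("C5H9NO4")
#' parseFormula("H2O")
#' @seealso [formatFormula()], [monoisotopicMass()]
#' @export
parseFormula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  # parenthesized, charged, dotted or R-group notation (present in parts
  # of ModelSEED) is deliberately not interpreted
  if (grepl("[^A-Za-z0-9]", text))
    stop(unsupportedFormula(text))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(text))
    stop(formulaParseError(text, text))
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Z][a-z]?", "", toks)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  bad <- setdiff(sym, names(MONOISOTOPIC_MASS))
  if (any(c("R", "Ra", "X") %in% bad))
    stop(unsupportedFormula(text))
  if (length(bad))
    stop(formulaParseError(text, bad[1]))
  if (any(cnt == 0L))
    stop(formulaParseError(text, sym[cnt == 0L][1]))
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  storage.mode(counts) <- "integer"
  c(counts)
}

formulaParseError <- function(text, symbol) {
  structure(
    class = c("formula_parse_error", "error", "condition"),
    list(message = sprintf("cannot parse formula '%s': unknown or invalid element '%s'",
                           text, symbol),
         call = NULL, formula = text, symbol = symbol))
}

unsupportedFormula <- function(text) {
  structure(
    class = c("unsupported_formula", "error", "condition"),
    list(message = sprintf(
      "unsupported formula '%s' (parentheses, charge or R-group notation)", text),
      call = NULL, formula = text))
}

#' Format element counts as a Hill-ordered formula string
#'
#' Hill convention: carbon first, then hydrogen, then all other elements
#' alphabetically (all alphabetical when no carbon).  Inverse of
#' [parseFormula()] on canonical input.
#'
#' @param counts Named integer vector of element counts.
#' @return Single formula string.
#' @export
formatFormula <- function(counts) {
  counts <- asCounts(counts)
  sym <- names(counts)
  if ("C" %in% sym) {
    ord <- c(intersect(c("C", "H"), sym), sort(setdiff(sym, c("C", "H"))))
  } else {
    ord <- sort(sym)
  }
  counts <- counts[ord]
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

# accept either a formula string or a pre-parsed named count vector
asCounts <- function(f) {
  if (is.character(f)) return(parseFormula(f))
  if (is.null(names(f)) || length(f) == 0L)
    stop("expected a formula string or a named count vector")
  bad <- setdiff(names(f), names(MONOISOTOPIC_MASS))
  if (length(bad)) stop(formulaParseError(paste(names(f), collapse = ""), bad[1]))
  if (any(f < 1)) stop("element counts must be >= 1")
  storage.mode(f) <- "integer"
  f
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times the mass of each element's most abundant
#' isotope ([MONOISOTOPIC_MASS]).
#'
#' @param f Formula string or named count vector from [parseFormula()].
#' @return Mass in Da.
#' @examples
#' monoisotopicMass("C5H9NO4")  # glutamic acid, 147.05316
#' @export
monoisotopicMass <- function(f) {
  counts <- asCounts(f)
  sum(counts * MONOISOTOPIC_MASS[names(counts)])
}

#' Predict the M+1 isotope ratio of a formula
#'
#' Expected intensity of the M+1 isotopologue peak relative to the
#' monoisotopic peak, from the per-atom abundance ratios of the +1 Da
#' isotopes (13C, 2H, 15N, 17O, 33S, ...).  This linear per-atom sum is
#' what a QTOF M+1/M measurement captures and equals the +1 coefficient
#' ratio of the exact isotopologue expansion.
#'
#' @param f Formula string or named count vector.
#' @return List with `m1_ratio` (dimensionless fraction) and
#'   `m1_spacing` (Da; the 13C-12C offset, the dominant M+1 channel for
#'   organic molecules).
#' @examples
#' predictM1Ratio("C6H12O6")$m1_ratio  # ~0.0686
#' @export
predictM1Ratio <- function(f) {
  counts <- asCounts(f)
  r <- ISOTOPE_M1_RATIO[names(counts)]
  r[is.na(r)] <- 0
  list(m1_ratio = sum(counts * r), m1_spacing = C13_SPACING)
}

#' Signed relative mass deviation in parts per million
#'
#' @param observed,theoretical m/z values, both positive.
#' @return `1e6 * (observed - theoretical) / theoretical`; vectorized.
#' @export
ppmError <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
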