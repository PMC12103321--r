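# Conventional atomic weights (IUPAC 2021 abridged values), g/mol.
# Enough elements for common polymers, carbonates and organic standards.
.atomic_weights <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Ni = 58.693, Cu = 63.546, Zn = 65.38, Br = 79.904, I = 126.904,
  Ba = 137.327, Au = 196.967
)

#' Tabulated conventional atomic weights
#'
#' @return Named numeric vector of atomic weights (g/mol) keyed by element
#'   symbol.
#' @export
atomic_weights <- function() .atomic_weights

#' Parse an empirical formula in Hill notation
#'
#' Splits a formula such as `"C8H5KO4"` into an element -> count map. Counts
#' default to 1 when omitted. Element symbols must carry a tabulated atomic
#' weight (see [atomic_weights()]).
#'
#' @param text Single non-empty string, e.g. `"C8H8"`, `"Na2CO3"`.
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C8H8")     # polystyrene repeat unit
#' parse_formula("C8H5KO4")  # potassium hydrogen phthalate
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("'text' must be a single non-empty string")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    token <- regmatches(rest, regexpr("^([A-Z][a-z]?)([0-9]*)", rest))
    if (length(token) == 0L || !nzchar(token))
      stop(sprintf("malformed formula '%s': unexpected character at position %d",
                   text, pos))
    sym <- sub("[0-9]*$", "", token)
    # Fall back to the one-letter symbol when the greedy two-letter read is
    # not a known element (defensive; [a-z] cannot actually absorb capitals).
    if (nchar(sym) == 2L && !(sym %in% names(.atomic_weights)) &&
        substr(sym, 1L, 1L) %in% names(.atomic_weights)) {
      sym <- substr(sym, 1L, 1L)
      token <- regmatches(rest, regexpr("^([A-Z])([0-9]*)", rest))
    }
    if (!(sym %in% names(.atomic_weights)))
      stop(sprintf("unknown element symbol '%s' at position %d in '%s'",
                   sym, pos, text))
    digits <- substr(token, nchar(sym) + 1L, nchar(token))
    k <- if (nzchar(digits)) as.integer(digits) else 1L
    if (is.na(k) || k < 1L)
      stop(sprintf("invalid count for element '%s' at position %d", sym, pos))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + k
    pos <- pos + nchar(token)
  }
  counts
}

#' Molar mass of an empirical formula
#'
#' @param formula Either a formula string or a named count vector as returned
#'   by [parse_formula()].
#' @return Molar mass in g/mol.
#' @export
molar_mass <- function(formula) {
  f <- .as_formula_counts(formula)
  sum(.atomic_weights[names(f)] * f)
}

#' Carbon mass fraction of a compound or polymer repeat unit
#'
#' Mass of carbon over total molar mass. For a homopolymer the repeat-unit
#' formula gives the same fraction as the full chain.
#'
#' @inheritParams molar_mass
#' @return Mass fraction of carbon in (0, 1].
#' @examples
#' carbon_mass_fraction("C8H8")    # 0.9226 (PS)
#' carbon_mass_fraction("C8H5KO4") # 0.4705 (KHP)
#' @export
carbon_mass_fraction <- function(formula) {
  f <- .as_formula_counts(formula)
  if (!("C" %in% names(f)))
    stop("formula contains no carbon; carbon mass fraction undefined")
  unname(.atomic_weights[["C"]] * f[["C"]] / molar_mass(f))
}

.as_formula_counts <- function(formula) {
  if (is.character(formula)) return(parse_formula(formula))
  if (is.numeric(formula) && !is.null(names(formula))) {
    if (any(formula < 1) || any(formula != round(formula)))
      stop("element counts must be positive integers")
    bad <- setdiff(names(formula), names(.atomic_weights))
    if (length(bad))
      stop("no tabulated atomic weight for element(s): ",
           paste(bad, collapse = ", "))
    return(formula)
  }
  stop("'formula' must be a string or a named count vector")
}
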