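# Chemical formula arithmetic on element -> count maps.
#
# Masses use the 2021 IUPAC abridged standard atomic weights; the table is
# replaceable per call so other conventions can be swapped in.

#' Standard atomic weights (2021 IUPAC abridged values)
#'
#' Named numeric vector of standard atomic weights in g/mol, used as the
#' default mass table by [molar_mass()].
#'
#' @return Named numeric vector, element symbol -> g/mol.
#' @export
#' @examples
#' atomic_weights()[["O"]]
atomic_weights <- function() {
  c(
    H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
    N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990,
    Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
    Cl = 35.45, Ar = 39.95, K = 39.098, Ca = 40.078, Mn = 54.938,
    Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
    Br = 79.904, I = 126.904
  )
}

# Bondi van der Waals radii (angstrom); generic fallback 1.7.
vdw_radii <- function() {
  c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
    Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, K = 2.75, Mg = 1.73,
    Ca = 2.31, Fe = 2.00, Zn = 2.10
  )
}

default_radius <- function(element) {
  r <- vdw_radii()[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

#' Parse a chemical formula string
#'
#' Accepts Hill or free element order, e.g. `"C21H26O5"` or `"H2O"`.
#' Implicit counts are 1. Unknown element symbols are rejected with the
#' offending token named.
#'
#' @param text Formula string.
#' @return A `chem_formula` object: named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C21H26O5")
#' parse_formula("H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop_gf("empty formula string", "gelforge_parse_error")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop_gf(sprintf("formula '%s' does not match the element-count grammar", text),
            "gelforge_parse_error")
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  known <- names(atomic_weights())
  bad <- setdiff(unique(elements), known)
  if (length(bad)) {
    stop_gf(sprintf("unknown element symbol(s): %s", paste(bad, collapse = ", ")),
            "gelforge_parse_error")
  }
  comp <- tapply(counts, elements, sum)
  out <- as.integer(comp)
  names(out) <- names(comp)
  structure(out[order(match(names(out), c("C", "H", setdiff(sort(names(out)), c("C", "H")))))],
            class = "chem_formula")
}

#' @export
format.chem_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula>", format(x), "\n")
  invisible(x)
}

#' Merge two formulas (disjoint-part union)
#'
#' Element counts add; mass is therefore additive across merges.
#'
#' @param a,b `chem_formula` objects.
#' @return Combined `chem_formula`.
#' @export
formula_add <- function(a, b) {
  elements <- union(names(a), names(b))
  counts <- vapply(elements, function(e) {
    sum(c(unclass(a)[e], unclass(b)[e]), na.rm = TRUE)
  }, integer(1))
  parse_formula(paste0(elements, counts, collapse = ""))
}

#' Molar mass of a formula
#'
#' Count-weighted sum of standard atomic weights.
#'
#' @param formula `chem_formula` (or string, parsed on the fly).
#' @param weights Named weight table in g/mol; defaults to [atomic_weights()].
#' @return Mass in g/mol.
#' @export
#' @examples
#' molar_mass("C21H26O5")  # 358.434
#' molar_mass("H2O")       # 18.015
molar_mass <- function(formula, weights = atomic_weights()) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) stop_gf("empty formula has no mass", "gelforge_parse_error")
  w <- weights[names(formula)]
  if (anyNA(w)) {
    stop_gf(sprintf("no atomic weight for: %s",
                    paste(names(formula)[is.na(w)], collapse = ", ")),
            "gelforge_parse_error")
  }
  sum(unclass(formula) * w)
}
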