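#' Monoisotopic element masses
#'
#' Masses of the most abundant natural isotope of each supported element, in
#' daltons. The table is the single authority for all mass arithmetic in the
#' package; stored masses in containers are always recomputed from formulas
#' against it.
#'
#' @format Named numeric vector, element symbol to mass in Da.
#' @export
MONOISOTOPIC_MASS <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Se = 79.9165213
)

#' Monoisotopic mass of a formula
#'
#' Sums most-abundant-isotope masses over the element counts of a formula.
#'
#' @param formula A `chem_formula`, or a formula string such as `"C2H2O"`.
#' @return Mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C2H2O")   # acetylation delta, 42.010565 Da
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(formula) {
  f <- as_chem_formula(formula)
  if (length(f) == 0L) return(0)
  unknown <- setdiff(names(f), names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0L) {
    stop("no monoisotopic mass known for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(MONOISOTOPIC_MASS[names(f)] * as.numeric(f))
}
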