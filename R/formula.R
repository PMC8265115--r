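#' @title Molecular formulas
#'
#' @description A `chem_formula` is a named integer vector mapping element
#' symbols to positive counts, kept in Hill order (C first, H second, then
#' alphabetical; without carbon, all elements alphabetical). Zero counts are
#' never stored, so two formulas are equal iff their vectors are identical.
#'
#' @param x A formula string (e.g. `"C6H13NO2"`), a named count vector, or an
#'   existing `chem_formula`.
#' @return A `chem_formula` object.
#' @examples
#' as_chem_formula("C6H13NO2")
#' formula_subtract("C6H13NO2", "H2O")  # isoleucine residue, C6H11NO
#' @export
as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    return(parse_formula(x))
  }
  if (is.numeric(x)) {
    if (length(x) > 0L && is.null(names(x)))
      stop("numeric formula input must be named by element", call. = FALSE)
    return(.new_formula(x))
  }
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a formula", call. = FALSE)
}

# canonicalize a named count vector: merge duplicates, drop zeros, Hill order
.new_formula <- function(counts) {
  counts <- round(counts)
  if (any(counts < 0)) {
    stop("negative element count for: ",
         paste(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
  }
  counts <- tapply(as.integer(counts), names(counts), sum)
  counts <- counts[counts > 0L]
  structure(counts[.hill_order(names(counts))], class = "chem_formula")
}

.hill_order <- function(elements) {
  if ("C" %in% elements) {
    first <- intersect(c("C", "H"), elements)
    c(first, sort(setdiff(elements, first)))
  } else {
    sort(elements)
  }
}

#' Parse a formula string
#'
#' Accepts element symbols with optional multi-digit counts, e.g. `"C4H12N2"`.
#' The empty string parses to the empty formula.
#'
#' @param text Formula string.
#' @return A `chem_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (nchar(text) == 0L) return(.new_formula(integer(0)))
  tokens <- gregexpr("[A-Z][a-z]?\\d*", text)[[1]]
  matched <- regmatches(text, list(tokens))[[1]]
  if (sum(attr(tokens, "match.length")) != nchar(text)) {
    stop("malformed formula string: '", text, "'", call. = FALSE)
  }
  elements <- sub("\\d+$", "", matched)
  counts <- as.integer(sub("^[A-Z][a-z]?", "", matched))
  counts[is.na(counts)] <- 1L
  names(counts) <- elements
  .new_formula(counts)
}

#' Render a formula in Hill order
#'
#' @param formula A `chem_formula` or formula string.
#' @return Single string; `""` for the empty formula. Rendering then parsing
#'   round-trips exactly.
#' @export
formula_to_string <- function(formula) {
  f <- as_chem_formula(formula)
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(f > 1L, f, ""), collapse = "")
}

#' Formula arithmetic
#'
#' Element-wise addition and subtraction of formulas. Subtraction that would
#' drive any element negative is an error (the operand is not contained in
#' the minuend).
#'
#' @param a,b Formulas (`chem_formula` or string).
#' @return A `chem_formula`.
#' @export
formula_add <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  .new_formula(c(unclass(a), unclass(b)))
}

#' @rdname formula_add
#' @export
formula_subtract <- function(a, b) {
  a <- as_chem_formula(a); b <- as_chem_formula(b)
  counts <- c(unclass(a), -unclass(b))
  counts <- tapply(as.integer(counts), names(counts), sum)
  if (any(counts < 0L)) {
    stop("formula subtraction yields negative count for: ",
         paste(names(counts)[counts < 0L], collapse = ", "), call. = FALSE)
  }
  .new_formula(counts)
}

#' Multiply a formula by a non-negative integer
#'
#' @param formula Formula to scale.
#' @param n Non-negative integer multiplier.
#' @return A `chem_formula`.
#' @export
formula_multiply <- function(formula, n) {
  f <- as_chem_formula(formula)
  stopifnot(length(n) == 1L, n >= 0, n == round(n))
  .new_formula(unclass(f) * as.integer(n))
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<formula> ", formula_to_string(x), "  (",
      format(monoisotopic_mass(x), nsmall = 6), " Da)\n", sep = "")
  invisible(x)
}

#' @export
format.chem_formula <- function(x, ...) formula_to_string(x)

#' Test two formulas for equality
#'
#' @param a,b Formulas or formula strings.
#' @return Logical scalar.
#' @export
formula_equal <- function(a, b) {
  identical(formula_to_string(a), formula_to_string(b))
}
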