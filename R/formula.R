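#' @importFrom rlang %||% .data abort warn
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic atomic masses (CODATA/IUPAC 2021), Th per elementary charge.
.ATOMIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

.PROTON_MASS <- 1.007276466879

.ELEMENTS <- names(.ATOMIC_MASS)

#' Create an elemental formula
#'
#' An elemental formula is a named integer vector over the elements
#' C, H, N, O, P (the only elements occurring in glycerophospholipids).
#' Missing elements count as zero.
#'
#' @param C,H,N,O,P Non-negative integer atom counts.
#' @return Named integer vector of length 5 with class `elemental_formula`.
#' @examples
#' elemental_formula(C = 39, H = 76, N = 1, O = 8, P = 1)
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  counts <- c(C = C, H = H, N = N, O = O, P = P)
  if (any(counts < 0)) abort("Elemental formula counts must be non-negative.")
  if (any(counts != round(counts))) abort("Elemental formula counts must be integers.")
  structure(as.integer(round(counts)), names = .ELEMENTS,
            class = "elemental_formula")
}

formula_add <- function(a, b) {
  elemental_formula(C = a[["C"]] + b[["C"]], H = a[["H"]] + b[["H"]],
                    N = a[["N"]] + b[["N"]], O = a[["O"]] + b[["O"]],
                    P = a[["P"]] + b[["P"]])
}

formula_subtract <- function(a, b) {
  elemental_formula(C = a[["C"]] - b[["C"]], H = a[["H"]] - b[["H"]],
                    N = a[["N"]] - b[["N"]], O = a[["O"]] - b[["O"]],
                    P = a[["P"]] - b[["P"]])
}

#' Write a formula as a Hill-order string
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; a
#' count of one is omitted (e.g. `"C39H76NO8P"`).
#'
#' @param formula An [elemental_formula()].
#' @return Character scalar.
#' @export
formula_string <- function(formula) {
  parts <- vapply(.ELEMENTS, function(el) {
    n <- formula[[el]]
    if (n == 0L) "" else if (n == 1L) el else paste0(el, n)
  }, character(1))
  paste0(parts, collapse = "")
}

#' Parse a Hill-order formula string
#'
#' @param x Character scalar such as `"C39H76NO8P"`.
#' @return An [elemental_formula()].
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([CHNOP])([0-9]*)", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x) || length(toks) == 0L) {
    abort(paste0("Cannot parse elemental formula: '", x, "'"))
  }
  counts <- stats::setNames(integer(length(.ELEMENTS)), .ELEMENTS)
  for (tok in toks) {
    el <- substr(tok, 1, 1)
    n <- substr(tok, 2, nchar(tok))
    counts[[el]] <- counts[[el]] + if (nzchar(n)) as.integer(n) else 1L
  }
  do.call(elemental_formula, as.list(counts))
}

#' Monoisotopic m/z of the deprotonated molecule
#'
#' Sums monoisotopic atomic masses and removes one proton, giving the
#' m/z of the singly charged deprotonated ion \eqn{[M-H]^-} observed in
#' negative-mode electrospray.
#'
#' @param formula An [elemental_formula()] or Hill-order string.
#' @return Numeric m/z (Th).
#' @examples
#' monoisotopic_mz(parse_formula("C39H76NO8P")) # PE 34:1, ~716.5236
#' @export
monoisotopic_mz <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (formula[["H"]] < 1L) {
    abort("Formula has no hydrogen: cannot form a deprotonated ion.")
  }
  sum(as.numeric(formula) * .ATOMIC_MASS) - .PROTON_MASS
}

#' Relative intensity of the A+k carbon isotopologue
#'
#' Carbon-only binomial isotope model: the intensity of the peak carrying
#' k heavy carbons, relative to the monoisotopic peak, is
#' \eqn{\binom{n}{k} (p/(1-p))^k} for a molecule with n carbon atoms and
#' a 13C natural abundance p. Contributions of 2H, 15N, 17O and 18O are
#' neglected; they add <0.1% at A+2 for glycerophospholipid formulas.
#'
#' @param formula An [elemental_formula()], Hill string, or a carbon count.
#' @param k Isotopologue index, 0, 1 or 2.
#' @param p 13C natural abundance (default 0.011, i.e. 1.1%).
#' @return Numeric ratio relative to the monoisotopic intensity (k = 0
#'   returns exactly 1).
#' @examples
#' isotope_ratio(parse_formula("C39H76NO8P"), 2)
#' @export
isotope_ratio <- function(formula, k, p = 0.011) {
  if (is.character(formula)) formula <- parse_formula(formula)
  n <- if (length(formula) > 1L) formula[["C"]] else as.integer(formula)
  if (!k %in% 0:2) abort("k must be 0, 1 or 2.")
  if (k > n) abort("k exceeds the number of carbon atoms.")
  choose(n, k) * (p / (1 - p))^k
}
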