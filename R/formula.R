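#' @importFrom stats rnorm rlnorm runif median quantile sd setNames
#' @importFrom utils read.table write.table head combn
NULL

# Monoisotopic atomic masses (u), IUPAC/CODATA: 12C exact, 1H, 14N, 16O, 32S.
ELEMENT_MASSES <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Proton mass (u), including the electron correction, so that
# [M-H]- m/z = neutral monoisotopic mass - PROTON_MASS.
PROTON_MASS <- 1.00727646688

#' Construct a table of CHNOS molecular formulas
#'
#' A formula set is a plain `data.frame` with integer columns `c`, `h`, `n`,
#' `o`, `s` (element counts), one row per formula. All formula-level
#' functions in the package (`monoisotopic_mass()`, `aimod()`,
#' `is_phenolic()`, ...) are vectorized over such tables.
#'
#' @param c,h,n,o,s Non-negative integer element counts, recycled to a
#'   common length.
#' @return A `data.frame` with columns `c`, `h`, `n`, `o`, `s`.
#' @examples
#' catechin <- formula_set(c = 15, h = 14, o = 6)
#' monoisotopic_mass(catechin)
#' @export
formula_set <- function(c = 0L, h = 0L, n = 0L, o = 0L, s = 0L) {
  f <- data.frame(c = as.integer(c), h = as.integer(h), n = as.integer(n),
                  o = as.integer(o), s = as.integer(s))
  if (any(is.na(f)) || any(f < 0L)) {
    stop("element counts must be non-negative integers")
  }
  f
}

.check_formula <- function(f) {
  req <- c("c", "h", "n", "o", "s")
  if (!is.data.frame(f) || !all(req %in% names(f))) {
    stop("expected a formula table with columns c, h, n, o, s")
  }
  if (any(is.na(f[req])) || any(f[req] < 0)) {
    stop("element counts must be non-negative")
  }
  invisible(f)
}

#' Render formulas as Hill-order strings
#'
#' Carbon first, hydrogen second, remaining elements alphabetically; counts
#' of one are implicit; elements with count zero are omitted. The rendering
#' round-trips through [parse_formula()].
#'
#' @param f A formula table (see [formula_set()]).
#' @return Character vector, e.g. `"C15H14O6"`.
#' @export
formula_string <- function(f) {
  .check_formula(f)
  part <- function(sym, cnt) {
    ifelse(cnt == 0L, "", paste0(sym, ifelse(cnt == 1L, "", cnt)))
  }
  paste0(part("C", f$c), part("H", f$h), part("N", f$n),
         part("O", f$o), part("S", f$s))
}

#' Parse Hill-order formula strings
#'
#' @param x Character vector of formulas over the elements C, H, N, O, S
#'   (e.g. `"C15H14O6"`, `"H2O"`).
#' @return A formula table (see [formula_set()]).
#' @export
parse_formula <- function(x) {
  x <- as.character(x)
  out <- formula_set(rep(0L, length(x)))
  for (i in seq_along(x)) {
    str <- x[i]
    if (is.na(str) || !nzchar(str)) next
    toks <- regmatches(str, gregexpr("[A-Z][a-z]?[0-9]*", str))[[1]]
    if (!nzchar(str) || paste(toks, collapse = "") != str) {
      stop(sprintf("cannot parse formula '%s'", str))
    }
    for (tok in toks) {
      sym <- sub("[0-9]*$", "", tok)
      cnt <- sub("^[A-Za-z]+", "", tok)
      cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
      col <- tolower(sym)
      if (!col %in% c("c", "h", "n", "o", "s")) {
        stop(sprintf("unsupported element '%s' in formula '%s'", sym, str))
      }
      out[[col]][i] <- out[[col]][i] + cnt
    }
  }
  out
}

#' Neutral monoisotopic mass of a formula
#'
#' Sum of monoisotopic atomic masses (12C, 1H, 14N, 16O, 32S).
#'
#' @param f A formula table (see [formula_set()]).
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C15H14O6")) # 290.0790
#' @export
monoisotopic_mass <- function(f) {
  .check_formula(f)
  ELEMENT_MASSES[["C"]] * f$c + ELEMENT_MASSES[["H"]] * f$h +
    ELEMENT_MASSES[["N"]] * f$n + ELEMENT_MASSES[["O"]] * f$o +
    ELEMENT_MASSES[["S"]] * f$s
}

#' m/z of the deprotonated molecular ion
#'
#' For negative-mode electrospray the dominant species of phenolic
#' compounds is `[M-H]-`; its m/z is the neutral monoisotopic mass minus
#' the proton mass (1.007276 Da, electron included).
#'
#' @param f A formula table (see [formula_set()]).
#' @param mode Ionization species; only `"[M-H]-"` is supported.
#' @return Numeric vector of m/z values (Th).
#' @examples
#' round(ion_mz(parse_formula("C15H14O6")), 3) # 289.072 (catechin)
#' @export
ion_mz <- function(f, mode = "[M-H]-") {
  mode <- match.arg(mode, "[M-H]-")
  .check_formula(f)
  if (any(f$h < 1L)) {
    stop("deprotonation requires at least one hydrogen")
  }
  monoisotopic_mass(f) - PROTON_MASS
}

# Rings-plus-double-bonds under standard valences (C:4, H:1, N:3, O:2, S:2).
# Integer for any even-electron neutral CHNOS molecule.
rdbe <- function(f) {
  1 + f$c - f$h / 2 + f$n / 2
}
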