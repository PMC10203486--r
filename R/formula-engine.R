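#' Element bounds for formula assignment
#'
#' Allowed element-count ranges for candidate enumeration. Defaults follow
#' the acquisition convention for phenolic extracts in negative-mode ESI:
#' C 1-50, H 1-100, O 1-30, N 0-2, S 0-2.
#'
#' @param c,h,n,o,s Length-2 integer vectors `c(min, max)` per element.
#' @return An object of class `element_bounds` (a named list of ranges).
#' @export
element_bounds <- function(c = base::c(1L, 50L), h = base::c(1L, 100L),
                           o = base::c(1L, 30L), n = base::c(0L, 2L),
                           s = base::c(0L, 2L)) {
  b <- list(c = as.integer(c), h = as.integer(h), n = as.integer(n),
            o = as.integer(o), s = as.integer(s))
  for (el in names(b)) {
    rng <- b[[el]]
    if (length(rng) != 2L || any(is.na(rng)) || rng[1] < 0L || rng[1] > rng[2]) {
      stop(sprintf("invalid bounds for element '%s': need 0 <= min <= max", el))
    }
  }
  structure(b, class = "element_bounds")
}

# Grid of (n, s, c, o) combinations with their partial masses; hydrogen is
# solved from the mass window, which is exhaustively equivalent to the full
# five-element grid (each H count is an isolated ~1.008 Da lattice point,
# far wider than any realistic ppm window).
.partial_grid <- function(bounds) {
  g <- expand.grid(n = bounds$n[1]:bounds$n[2],
                   s = bounds$s[1]:bounds$s[2],
                   c = bounds$c[1]:bounds$c[2],
                   o = bounds$o[1]:bounds$o[2],
                   KEEP.OUT.ATTRS = FALSE)
  g$rest <- ELEMENT_MASSES[["C"]] * g$c + ELEMENT_MASSES[["N"]] * g$n +
    ELEMENT_MASSES[["O"]] * g$o + ELEMENT_MASSES[["S"]] * g$s
  g
}

#' Enumerate candidate formulas for an observed m/z
#'
#' Complete enumeration of CHNOS formulas within the element bounds whose
#' `[M-H]-` m/z lies within `tol_ppm` of the observed value and that pass
#' the chemical validity screen: rings-plus-double-bonds >= 0 under
#' standard valences and integer-valued for a neutral even-electron
#' molecule (H + N even).
#'
#' @param mz Observed m/z (single value, 0 < mz <= 2000).
#' @param tol_ppm Mass tolerance in ppm of the observed m/z (default 10).
#' @param bounds An [element_bounds()] object.
#' @param mode Ionization species; only `"[M-H]-"` is supported.
#' @return A `data.frame` with columns `c`, `h`, `n`, `o`, `s`, `formula`,
#'   `mass` (neutral), `mz` (theoretical ion), `error_ppm`, sorted by
#'   increasing absolute mass error (ties: fewer heteroatoms, then lower
#'   mass). Zero rows when nothing matches.
#' @examples
#' enumerate_candidates(289.0718, tol_ppm = 10)
#' @export
enumerate_candidates <- function(mz, tol_ppm = 10, bounds = element_bounds(),
                                 mode = "[M-H]-") {
  mode <- match.arg(mode, "[M-H]-")
  stopifnot(length(mz) == 1L, is.finite(mz), mz > 0, mz <= 2000, tol_ppm > 0)
  g <- .partial_grid(bounds)
  mH <- ELEMENT_MASSES[["H"]]
  m_lo <- mz * (1 - tol_ppm * 1e-6) + PROTON_MASS
  m_hi <- mz * (1 + tol_ppm * 1e-6) + PROTON_MASS
  h_lo <- pmax(ceiling((m_lo - g$rest) / mH - 1e-9), bounds$h[1])
  h_hi <- pmin(floor((m_hi - g$rest) / mH + 1e-9), bounds$h[2])
  keep <- which(h_hi >= h_lo)
  empty <- data.frame(c = integer(), h = integer(), n = integer(),
                      o = integer(), s = integer(), formula = character(),
                      mass = numeric(), mz = numeric(), error_ppm = numeric())
  if (length(keep) == 0L) return(empty)
  cnt <- h_hi[keep] - h_lo[keep] + 1L
  idx <- rep(keep, cnt)
  h <- rep(h_lo[keep], cnt) + sequence(cnt) - 1L
  f <- formula_set(c = g$c[idx], h = h, n = g$n[idx], o = g$o[idx],
                   s = g$s[idx])
  rd <- rdbe(f)
  mass <- g$rest[idx] + mH * h
  ionmz <- mass - PROTON_MASS
  err <- (ionmz - mz) / mz * 1e6
  ok <- rd >= 0 & (f$h + f$n) %% 2L == 0L & abs(err) <= tol_ppm + 1e-9
  if (!any(ok)) return(empty)
  f <- f[ok, , drop = FALSE]
  out <- data.frame(f, formula = formula_string(f), mass = mass[ok],
                    mz = ionmz[ok], error_ppm = err[ok],
                    stringsAsFactors = FALSE)
  ord <- order(abs(out$error_ppm), out$n + out$s, out$mass)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign molecular formulas to a processed peak list
#'
#' Each peak receives the top-ranked candidate from
#' [enumerate_candidates()] (smallest absolute ppm error; ties broken
#' toward fewer heteroatoms, then lower mass) or no formula when nothing
#' within the bounds matches. The phenolic flag is evaluated on the
#' assigned formula with [is_phenolic()] and is `NA` for unassigned peaks.
#'
#' @param pl A peak list `data.frame` with columns `mz`, `intensity`,
#'   `snr` (see [peaklist()]); normally quality-filtered, blank-subtracted
#'   replicate-consensus peaks.
#' @param tol_ppm Assignment mass tolerance in ppm (default 10).
#' @param bounds An [element_bounds()] object.
#' @param mode Ionization species; only `"[M-H]-"` is supported.
#' @return A `data.frame` of assigned peaks: `mz`, `intensity`, `snr`,
#'   `formula` (`NA` if unassigned), `c`..`s`, `mass_error_ppm`,
#'   `n_candidates`, `is_phenolic`.
#' @export
assign_formulas <- function(pl, tol_ppm = 10, bounds = element_bounds(),
                            mode = "[M-H]-") {
  pl <- as.data.frame(pl)
  stopifnot(all(c("mz", "intensity", "snr") %in% names(pl)))
  n <- nrow(pl)
  out <- data.frame(mz = pl$mz, intensity = pl$intensity, snr = pl$snr,
                    formula = NA_character_, c = NA_integer_, h = NA_integer_,
                    n = NA_integer_, o = NA_integer_, s = NA_integer_,
                    mass_error_ppm = NA_real_, n_candidates = 0L,
                    is_phenolic = NA, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cand <- enumerate_candidates(pl$mz[i], tol_ppm = tol_ppm, bounds = bounds,
                                 mode = mode)
    out$n_candidates[i] <- nrow(cand)
    if (nrow(cand) > 0L) {
      top <- cand[1L, ]
      out$formula[i] <- top$formula
      out[i, c("c", "h", "n", "o", "s")] <- top[c("c", "h", "n", "o", "s")]
      out$mass_error_ppm[i] <- top$error_ppm
      out$is_phenolic[i] <- is_phenolic(top)
    }
  }
  out
}
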