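#' Elemental ratios of a formula
#'
#' O/C, H/C, N/C and S/C ratios, the axes of van Krevelen classification.
#'
#' @param f A formula table (see [formula_set()]); every row must contain
#'   at least one carbon.
#' @return A `data.frame` with columns `oc`, `hc`, `nc`, `sc`.
#' @export
elemental_ratios <- function(f) {
  .check_formula(f)
  if (any(f$c < 1L)) stop("elemental ratios require at least one carbon")
  data.frame(oc = f$o / f$c, hc = f$h / f$c, nc = f$n / f$c, sc = f$s / f$c)
}

#' Double-bond equivalents
#'
#' The default convention is the oxygen/sulfur-corrected variant used
#' throughout this workflow,
#' \deqn{DBE = 1 + C - O - S - (N + H)/2,}
#' which discounts O and S as double-bond sinks and may be negative for
#' highly oxygenated formulas. `convention = "standard"` gives the textbook
#' rings-plus-unsaturations count \eqn{1 + C - H/2 + N/2}.
#'
#' @param f A formula table (see [formula_set()]).
#' @param convention `"os_corrected"` (default) or `"standard"`.
#' @return Numeric vector.
#' @examples
#' dbe(parse_formula("C15H14O6"))                         # 3
#' dbe(parse_formula("C15H14O6"), convention = "standard") # 9
#' @export
dbe <- function(f, convention = c("os_corrected", "standard")) {
  convention <- match.arg(convention)
  .check_formula(f)
  if (convention == "standard") rdbe(f)
  else 1 + f$c - f$o - f$s - (f$n + f$h) / 2
}

#' Modified aromaticity index
#'
#' \deqn{AImod = \frac{1 + C - O/2 - S - (N + H)/2}{C - O/2 - N - S}}
#' accounts for the potential heteroatom (chiefly oxygen) contribution to
#' double bonds. Following common FT-MS practice the index is set to 0 when
#' the denominator is non-positive or the numerator negative.
#'
#' @param f A formula table (see [formula_set()]).
#' @return Numeric vector in `[0, 1]` for chemically sensible formulas.
#' @examples
#' aimod(parse_formula("C15H14O6")) # 0.5
#' @export
aimod <- function(f) {
  .check_formula(f)
  num <- 1 + f$c - f$o / 2 - f$s - (f$n + f$h) / 2
  den <- f$c - f$o / 2 - f$n - f$s
  ifelse(den <= 0 | num < 0, 0, num / den)
}

#' Nominal oxidation state of carbon
#'
#' \deqn{NOSC = 4 - (4C + H - 3N - 2O - 2S)/C,} ranging from -4
#' (methane-like, fully reduced) to +4 (CO2-like, fully oxidized).
#'
#' @param f A formula table (see [formula_set()]); `c >= 1` required.
#' @return Numeric vector.
#' @export
nosc <- function(f) {
  .check_formula(f)
  if (any(f$c < 1L)) stop("NOSC requires at least one carbon")
  4 - (4 * f$c + f$h - 3 * f$n - 2 * f$o - 2 * f$s) / f$c
}

#' All molecular indices of a formula set
#'
#' Convenience wrapper returning elemental ratios, both DBE conventions,
#' AImod and NOSC in one table.
#'
#' @param f A formula table (see [formula_set()]); `c >= 1` required.
#' @return A `data.frame` with columns `oc`, `hc`, `nc`, `sc`, `dbe`,
#'   `dbe_standard`, `aimod`, `nosc`.
#' @export
molecular_indices <- function(f) {
  out <- elemental_ratios(f)
  out$dbe <- dbe(f)
  out$dbe_standard <- dbe(f, convention = "standard")
  out$aimod <- aimod(f)
  out$nosc <- nosc(f)
  out
}

#' Phenolic classification of a formula
#'
#' A formula is classified as a phenolic compound when it falls in the
#' phenolic region of van Krevelen space and is below the aromaticity
#' ceiling: 0.6 < H/C < 1.5, 0.3 < O/C < 0.85 and AImod < 0.67, all
#' inequalities strict. The decision depends only on the formula, never on
#' intensity.
#'
#' @param f A formula table (see [formula_set()]); `c >= 1` required.
#' @param hc_range,oc_range Open intervals for H/C and O/C.
#' @param aimod_max Strict upper bound on AImod.
#' @return Logical vector.
#' @examples
#' is_phenolic(parse_formula("C15H14O6")) # TRUE (catechin)
#' @export
is_phenolic <- function(f, hc_range = c(0.6, 1.5), oc_range = c(0.3, 0.85),
                        aimod_max = 0.67) {
  r <- elemental_ratios(f)
  r$hc > hc_range[1] & r$hc < hc_range[2] &
    r$oc > oc_range[1] & r$oc < oc_range[2] &
    aimod(f) < aimod_max
}

#' Gini-Simpson abundance-based diversity
#'
#' \deqn{D_A = 1 - \sum_i p_i^2} over sum-normalized intensities: the
#' probability that two randomly drawn signal units belong to different
#' formulas. 0 for a single formula; maximal (1 - 1/N) when all N
#' intensities are equal.
#'
#' @param intensities Non-negative intensities, at least one positive.
#' @return A list with elements `da` and `n_formulas`.
#' @examples
#' abundance_diversity(rep(1, 4))$da # 0.75
#' @export
abundance_diversity <- function(intensities) {
  intensities <- as.numeric(intensities)
  if (length(intensities) == 0L || any(!is.finite(intensities)) ||
      any(intensities < 0) || sum(intensities) <= 0) {
    stop("abundance diversity needs at least one positive intensity")
  }
  p <- intensities / sum(intensities)
  list(da = 1 - sum(p^2), n_formulas = length(intensities))
}

#' Intensity-weighted mean
#'
#' @param values Numeric vector.
#' @param weights Non-negative weights of the same length, with positive
#'   total.
#' @return The weighted mean `sum(values * weights) / sum(weights)`.
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) {
    stop("values and weights must have the same length")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive total")
  }
  stats::weighted.mean(values, weights)
}

#' Summarize the phenolic fraction of an assigned peak list
#'
#' Computes, over the phenolic-flagged assigned peaks: the relative
#' intensity of phenolics as a percentage of total signal, the number of
#' distinct phenolic formulas, the intensity-weighted average m/z, the
#' intensity-weighted molecular indices, and the Gini-Simpson diversity of
#' the per-formula summed intensities.
#'
#' @param assigned Output of [assign_formulas()].
#' @param denominator Reference signal for the relative intensity: `"all"`
#'   (default, total intensity of every processed peak, assigned or not)
#'   or `"assigned"` (peaks with a formula only).
#' @return An object of class `phenolic_summary`: a list with
#'   `rel_intensity_pct`, `n_phenolics`, `n_peaks`, `mz_wa`, `weighted`
#'   (named vector of intensity-weighted indices), `da`, `n_formulas_da`,
#'   `total_intensity`.
#' @export
summarize_phenolics <- function(assigned, denominator = c("all", "assigned")) {
  denominator <- match.arg(denominator)
  stopifnot(is.data.frame(assigned), nrow(assigned) >= 1L)
  total <- if (denominator == "all") sum(assigned$intensity)
           else sum(assigned$intensity[!is.na(assigned$formula)])
  phen <- assigned[!is.na(assigned$formula) & !is.na(assigned$is_phenolic) &
                     assigned$is_phenolic, , drop = FALSE]
  idx_cols <- c("oc", "hc", "nc", "sc", "dbe", "dbe_standard", "aimod", "nosc")
  if (nrow(phen) == 0L) {
    warning("no phenolic peaks in the assigned list")
    return(structure(list(
      rel_intensity_pct = 0, n_phenolics = 0L, n_peaks = 0L,
      mz_wa = NA_real_,
      weighted = setNames(rep(NA_real_, length(idx_cols)), idx_cols),
      da = NA_real_, n_formulas_da = 0L, total_intensity = total),
      class = "phenolic_summary"))
  }
  w <- phen$intensity
  ind <- molecular_indices(phen[, c("c", "h", "n", "o", "s")])
  weighted <- vapply(ind, function(v) weighted_mean(v, w), numeric(1))
  by_formula <- tapply(phen$intensity, phen$formula, sum)
  div <- abundance_diversity(as.numeric(by_formula))
  structure(list(
    rel_intensity_pct = 100 * sum(w) / total,
    n_phenolics = length(unique(phen$formula)),
    n_peaks = nrow(phen),
    mz_wa = weighted_mean(phen$mz, w),
    weighted = weighted,
    da = div$da,
    n_formulas_da = div$n_formulas,
    total_intensity = total), class = "phenolic_summary")
}

#' @export
print.phenolic_summary <- function(x, ...) {
  cat("Phenolic summary\n")
  cat(sprintf("  relative intensity: %.3f %% of total signal\n",
              x$rel_intensity_pct))
  cat(sprintf("  distinct phenolic formulas: %d (%d peaks)\n",
              x$n_phenolics, x$n_peaks))
  if (x$n_phenolics > 0L) {
    cat(sprintf("  weighted average m/z: %.2f\n", x$mz_wa))
    cat(sprintf("  diversity DA: %.4f\n", x$da))
    cat("  intensity-weighted indices:\n")
    print(round(x$weighted, 4))
  }
  invisible(x)
}
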