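# Independent oracles used by the property and acceptance tests. These
# deliberately avoid the package's solving strategies: enumeration is done
# over the full five-element grid, network matching by a plain double loop,
# and the rank-sum p-value by complete enumeration of group assignments.

ATOMIC <- c(C = 12.0, H = 1.0078250319, N = 14.0030740052,
            O = 15.9949146221, S = 31.97207069)
PROTON <- 1.00727646688

# Full exhaustive C x H x N x O x S grid for the default bounds, with
# neutral masses and the validity screen, built lazily and cached.
full_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- expand.grid(c = 1:50, h = 1:100, n = 0:2, o = 1:30, s = 0:2,
                       KEEP.OUT.ATTRS = FALSE)
      g$mass <- ATOMIC[["C"]] * g$c + ATOMIC[["H"]] * g$h +
        ATOMIC[["N"]] * g$n + ATOMIC[["O"]] * g$o + ATOMIC[["S"]] * g$s
      g$valid <- (1 + g$c - g$h / 2 + g$n / 2) >= 0 &
        (g$h + g$n) %% 2 == 0
      cache <<- g
    }
    cache
  }
})

# Exhaustive-grid formula enumeration: every in-bounds formula whose
# [M-H]- m/z is within tol_ppm of mz and passes the validity screen.
oracle_enumerate <- function(mz, tol_ppm = 10) {
  g <- full_grid()
  ion <- g$mass - PROTON
  hit <- g[abs(ion - mz) / mz * 1e6 <= tol_ppm + 1e-9 & g$valid, , drop = FALSE]
  sort(sprintf("C%d H%d N%d O%d S%d", hit$c, hit$h, hit$n, hit$o, hit$s))
}

key_of <- function(cand) {
  sort(sprintf("C%d H%d N%d O%d S%d", cand$c, cand$h, cand$n, cand$o, cand$s))
}

# Brute-force pairwise mass-difference matching (tolerance in ppm of the
# larger pair member), one edge record per (pair, transformation) hit.
oracle_network <- function(mzs, tf, tol_ppm = 2) {
  mzs <- sort(unique(mzs))
  out <- character(0)
  for (i in seq_along(mzs)) {
    for (j in seq_along(mzs)) {
      if (j <= i) next
      d <- mzs[j] - mzs[i]
      for (t in seq_len(nrow(tf))) {
        if (abs(d - tf$exact_mass[t]) <= tol_ppm * 1e-6 * mzs[j]) {
          out <- c(out, sprintf("%.6f|%.6f|%s", mzs[i], mzs[j], tf$name[t]))
        }
      }
    }
  }
  sort(out)
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0) return(character(0))
  sort(sprintf("%.6f|%.6f|%s", net$edges$mz_lo, net$edges$mz_hi,
               net$edges$transformation))
}

# Exact two-sided rank-sum p-value by enumerating all group assignments.
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  stats <- apply(idx, 2, function(k) sum(rank(pooled)[k]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Random unconstrained CHNOS formulas for property tests.
random_formulas <- function(n, seed = 42) {
  withr::with_seed(seed, {
    formula_set(c = sample(1:50, n, TRUE), h = sample(1:100, n, TRUE),
                n = sample(0:2, n, TRUE), o = sample(0:30, n, TRUE),
                s = sample(0:2, n, TRUE))
  })
}

# Tiny helper to write a delimited fixture.
write_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
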