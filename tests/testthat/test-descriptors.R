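catechin <- parse_formula("C15H14O6")

test_that("elemental ratios come out as exact rationals", {
  r <- elemental_ratios(catechin)
  expect_equal(unlist(r), c(oc = 0.4, hc = 14 / 15, nc = 0, sc = 0))
  r2 <- elemental_ratios(formula_set(c = 2, h = 2, n = 2, o = 2, s = 2))
  expect_equal(unlist(r2), c(oc = 1, hc = 1, nc = 1, sc = 1))
  expect_identical(elemental_ratios(formula_set(c = 1, h = 4))$hc, 4)
  expect_error(elemental_ratios(formula_set(h = 2, o = 1)), "carbon")
})

test_that("DBE follows the oxygen/sulfur-corrected convention by default", {
  expect_identical(dbe(catechin), 3)                         # 1+15-6-0-7
  expect_identical(dbe(formula_set(c = 1, h = 2)), 1)
  expect_identical(dbe(formula_set(c = 6, h = 6, o = 6)), -2) # may be negative
  expect_identical(dbe(catechin, convention = "standard"), 9)
  expect_identical(dbe(formula_set(c = 1, h = 2), convention = "standard"), 1)
})

test_that("AImod matches direct substitution and its zero convention", {
  expect_identical(aimod(catechin), 0.5)      # (1+15-3-7)/(15-3)
  expect_equal(aimod(formula_set(c = 6, h = 6)), 2 / 3)
  # denominator <= 0 (C - O/2 - N - S <= 0) returns 0
  expect_identical(aimod(formula_set(c = 1, h = 2, o = 4)), 0)
  # negative numerator returns 0
  expect_identical(aimod(formula_set(c = 1, h = 10, o = 1)), 0)
})

test_that("AImod equals an independent one-line evaluation on random formulas", {
  f <- random_formulas(1000, seed = 101)
  direct <- with(f, {
    num <- 1 + c - o / 2 - s - (n + h) / 2
    den <- c - o / 2 - n - s
    ifelse(den <= 0 | num < 0, 0, num / den)
  })
  expect_equal(aimod(f), direct, tolerance = 1e-12)
})

test_that("NOSC spans the fully reduced / fully oxidized limits", {
  expect_identical(nosc(formula_set(c = 1, o = 2)), 4)
  expect_identical(nosc(formula_set(c = 1, h = 4)), -4)
  expect_equal(nosc(catechin), 4 - 62 / 15)
  expect_error(nosc(formula_set(h = 2, o = 1)), "carbon")
})

test_that("phenolic classification uses strict van Krevelen + AImod bounds", {
  expect_true(is_phenolic(catechin))
  # H/C exactly 0.6 fails the strict bound
  expect_false(is_phenolic(formula_set(c = 10, h = 6, o = 4)))
  # O/C = 0.9 outside the window
  expect_false(is_phenolic(formula_set(c = 10, h = 10, o = 9)))
  # depends only on the formula: duplicated rows classify identically
  f <- random_formulas(100, seed = 13)
  expect_identical(is_phenolic(f), is_phenolic(f))
})

test_that("Gini-Simpson diversity has its closed-form values and bounds", {
  expect_identical(abundance_diversity(5)$da, 0)
  expect_identical(abundance_diversity(rep(1, 4))$da, 0.75)
  expect_identical(abundance_diversity(c(3, 1))$da, 0.375)
  expect_error(abundance_diversity(numeric(0)), "positive intensity")
  expect_error(abundance_diversity(c(0, 0)), "positive intensity")
  # DA <= 1 - 1/N with equality iff intensities are equal
  withr::with_seed(5, {
    for (k in 1:20) {
      v <- rlnorm(sample(2:30, 1), 0, 1)
      d <- abundance_diversity(v)
      expect_lte(d$da, 1 - 1 / d$n_formulas + 1e-12)
    }
  })
  expect_equal(abundance_diversity(rep(2.5, 7))$da, 1 - 1 / 7)
})

test_that("weighted mean handles edge weights and errors", {
  expect_identical(weighted_mean(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_identical(weighted_mean(c(10, 99), c(1, 0)), 10)
  expect_identical(weighted_mean(c(300, 500), c(1, 3)), 450)
  expect_error(weighted_mean(1:3, c(0, 0, 0)), "positive total")
  expect_error(weighted_mean(1:3, 1:2), "same length")
})

test_that("phenolic summary computes intensity-weighted quantities", {
  # constructed in increasing m/z order so the peak list keeps it
  lib <- rbind(
    cbind(parse_formula("C5H12O"), is_ph = FALSE),      # m/z ~ 87
    cbind(parse_formula("C15H14O6"), is_ph = TRUE),     # m/z ~ 289
    cbind(parse_formula("C16H16O7"), is_ph = TRUE),     # m/z ~ 319
    cbind(parse_formula("C30H62O2"), is_ph = FALSE))    # m/z ~ 453
  pl <- peaklist(ion_mz(lib[, 1:5]), c(6, 1, 3, 10), rep(50, 4))
  asg <- assign_formulas(pl)
  expect_identical(asg$is_phenolic, c(FALSE, TRUE, TRUE, FALSE))
  s <- summarize_phenolics(asg)
  expect_equal(s$rel_intensity_pct, 100 * 4 / 20)
  expect_identical(s$n_phenolics, 2L)
  expect_equal(s$mz_wa, weighted_mean(asg$mz[2:3], c(1, 3)))
  expect_equal(s$da, abundance_diversity(c(1, 3))$da)
  expect_equal(unname(s$weighted["aimod"]),
               weighted_mean(aimod(lib[2:3, 1:5]), c(1, 3)))

  # all peaks phenolic -> 100% of signal
  s2 <- summarize_phenolics(asg[2:3, ])
  expect_equal(s2$rel_intensity_pct, 100)

  # no phenolics -> flagged, not a crash
  expect_warning(s3 <- summarize_phenolics(asg[c(1, 4), ]), "no phenolic")
  expect_identical(s3$n_phenolics, 0L)
  expect_true(is.na(s3$mz_wa))
})

test_that("summary statistics are invariant to intensity rescaling", {
  truth <- simulate_ground_truth(n_formulas = 30, n_noise = 0, seed = 21,
                                 ppm_sigma = 0, replicate_cv = 0)
  pl <- generate_peaklists(truth, 2)$replicates[[1]]
  asg <- assign_formulas(pl)
  s1 <- summarize_phenolics(asg)
  asg2 <- asg
  asg2$intensity <- asg2$intensity * 137.5
  s2 <- summarize_phenolics(asg2)
  expect_equal(s1$rel_intensity_pct, s2$rel_intensity_pct)
  expect_equal(s1$mz_wa, s2$mz_wa)
  expect_equal(s1$da, s2$da)
  expect_equal(s1$weighted, s2$weighted)
})

test_that("weighted indices of identical formulas equal the single value", {
  f <- parse_formula(rep("C12H16O6", 4))
  pl <- peaklist(ion_mz(f) + c(0, 1e-4, 2e-4, 3e-4), c(1, 2, 3, 4), rep(50, 4))
  asg <- assign_formulas(pl)
  s <- summarize_phenolics(asg)
  expect_equal(unname(s$weighted["dbe"]), dbe(f[1, ]))
  expect_equal(unname(s$weighted["aimod"]), aimod(f[1, ]))
  expect_identical(s$n_phenolics, 1L)
  expect_identical(s$da, 0)  # one formula -> degenerate diversity
})
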