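test_that("formula libraries honor bounds, phenolic counts and validity", {
  one <- generate_formula_library(1, phenolic_fraction = 1, seed = 7)
  r <- elemental_ratios(one[, 1:5])
  expect_true(r$hc > 0.6 && r$hc < 1.5)
  expect_true(r$oc > 0.3 && r$oc < 0.85)
  expect_lt(aimod(one[, 1:5]), 0.67)

  lib <- generate_formula_library(100, phenolic_fraction = 0.5, seed = 1)
  expect_identical(nrow(lib), 100L)
  expect_identical(anyDuplicated(lib$formula), 0L)
  expect_gte(sum(is_phenolic(lib[, 1:5])), 50L)
  expect_identical(lib$is_phenolic, unname(is_phenolic(lib[, 1:5])))
  b <- element_bounds()
  for (el in c("c", "h", "n", "o", "s")) {
    expect_true(all(lib[[el]] >= b[[el]][1] & lib[[el]] <= b[[el]][2]))
  }
  expect_true(all(1 + lib$c - lib$h / 2 + lib$n / 2 >= 0))
  expect_true(all((lib$h + lib$n) %% 2 == 0))
  expect_true(all(lib$mz >= 100 & lib$mz <= 1000))
})

test_that("identical seeds give identical libraries and peak lists", {
  a <- generate_formula_library(100, seed = 1)
  b <- generate_formula_library(100, seed = 1)
  expect_identical(a, b)
  t1 <- simulate_ground_truth(n_formulas = 15, n_noise = 4, seed = 9)
  t2 <- simulate_ground_truth(n_formulas = 15, n_noise = 4, seed = 9)
  expect_identical(t1, t2)
  expect_identical(generate_peaklists(t1, 2), generate_peaklists(t2, 2))
  d1 <- generate_dose_response(2.7, seed = 3)
  expect_identical(d1, generate_dose_response(2.7, seed = 3))
})

test_that("an unsatisfiable library request fails explicitly", {
  # no oxygen available, but the phenolic window needs O/C > 0.3
  b <- element_bounds(o = c(0L, 0L))
  expect_error(generate_formula_library(5, phenolic_fraction = 1, bounds = b),
               "unsatisfiable|could not generate")
})

test_that("replicates carry every true formula plus the shared noise peaks", {
  truth <- simulate_ground_truth(n_formulas = 10, n_noise = 3, seed = 2)
  gen <- generate_peaklists(truth, 2)
  expect_identical(length(gen$replicates), 2L)
  expect_identical(vapply(gen$replicates, nrow, integer(1)), c(13L, 13L))
  expect_identical(nrow(gen$blank), 3L)
  expect_true(all(truth$noise_mz %in% gen$replicates[[1]]$mz))
  expect_identical(gen$blank$mz, truth$noise_mz)
})

test_that("zero noise reproduces theoretical m/z and true intensities", {
  truth <- simulate_ground_truth(n_formulas = 12, n_noise = 2, seed = 4,
                                 ppm_sigma = 0, replicate_cv = 0)
  gen <- generate_peaklists(truth, 2)
  r <- as.data.frame(gen$replicates[[1]])
  true_rows <- r[r$mz %in% truth$formulas$mz, ]
  expect_identical(sort(true_rows$mz), sort(truth$formulas$mz))
  expect_equal(sort(true_rows$intensity), sort(truth$intensity))
})

test_that("true peaks always clear the S/N threshold; some noise does not", {
  truth <- simulate_ground_truth(n_formulas = 20, n_noise = 10, seed = 6,
                                 noise_snr_fail_fraction = 0.5)
  gen <- generate_peaklists(truth, 2)
  r <- as.data.frame(gen$replicates[[1]])
  true_rows <- r[!r$mz %in% truth$noise_mz, ]
  noise_rows <- r[r$mz %in% truth$noise_mz, ]
  expect_true(all(true_rows$snr > 4))
  expect_identical(sum(noise_rows$snr <= 4), 5L)
})

test_that("dose-response generator hits the sigmoid's exact limits", {
  tbl <- generate_dose_response(ec50 = 3, hill = 2, top = 1000, n_doses = 9,
                                noise_cv = 0, seed = 1, n_replicates = 1,
                                dose_span = 3)
  mid <- tbl$response[abs(tbl$dose - 3) < 1e-9]
  expect_equal(mid, 500)
  expect_equal(tbl$response[which.min(tbl$dose)], 1000, tolerance = 2e-3)
  expect_error(generate_dose_response(ec50 = -1), "ec50")
  expect_error(generate_dose_response(ec50 = 1, n_doses = 3), "n_doses")
})

test_that("generator round-trips through the EC50 fit within 15%", {
  tbl <- generate_dose_response(ec50 = 2.7, hill = 2, noise_cv = 0.05,
                                n_doses = 8, seed = 3)
  fit <- fit_ec50(tbl)
  expect_lt(abs(fit$ec50 - 2.7) / 2.7, 0.15)
})

test_that("more mass error never helps formula recovery (on average)", {
  sigmas <- c(0.5, 2, 6)
  n_seeds <- 20
  frac <- sapply(sigmas, function(sg) {
    mean(sapply(seq_len(n_seeds), function(sd) {
      truth <- simulate_ground_truth(n_formulas = 15, n_noise = 0, seed = sd,
                                     ppm_sigma = sg)
      pl <- generate_peaklists(truth, 2)$replicates[[1]]
      asg <- assign_formulas(pl, tol_ppm = 10)
      idx <- vapply(asg$mz, function(m) which.min(abs(truth$formulas$mz - m)),
                    integer(1))
      mean(asg$formula == truth$formulas$formula[idx], na.rm = TRUE)
    }))
  })
  expect_true(all(diff(frac) <= 1e-9))
})

test_that("peak lists and ground truth tables are written as plain text", {
  truth <- simulate_ground_truth(n_formulas = 8, n_noise = 2, seed = 12)
  dir <- file.path(tempdir(), "gt_out")
  paths <- write_ground_truth(truth, dir, prefix = "s1")
  expect_true(all(file.exists(paths)))
  back <- read_peaklist(file.path(dir, "s1_rep1.tsv"))
  expect_identical(nrow(back), 10L)
  tt <- read.delim(file.path(dir, "s1_truth.tsv"))
  expect_identical(nrow(tt), 8L)
  expect_true(all(c("mz_theoretical", "formula", "intensity_true",
                    "is_phenolic") %in% names(tt)))
})
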