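#' Generate a random CHNOS formula library with known phenolic content
#'
#' Draws `n` distinct formulas within the element bounds, of which at
#' least `round(n * phenolic_fraction)` satisfy the phenolic definition of
#' [is_phenolic()] and the remainder are forced non-phenolic. Every
#' formula has a non-negative, integer rings-plus-double-bonds count
#' (even-electron neutral molecule) and an `[M-H]-` m/z inside `mz_range`.
#'
#' @param n Number of formulas (>= 1).
#' @param phenolic_fraction Target fraction of phenolic formulas in
#'   `[0, 1]` (default 0.5).
#' @param bounds An [element_bounds()] object.
#' @param seed Integer seed; identical seeds give identical libraries.
#' @param mz_range Allowed `[M-H]-` m/z window (default `c(100, 1000)`).
#' @return A `data.frame` with columns `c`, `h`, `n`, `o`, `s`, `formula`,
#'   `mass`, `mz`, `is_phenolic`.
#' @export
generate_formula_library <- function(n, phenolic_fraction = 0.5,
                                     bounds = element_bounds(), seed = 1,
                                     mz_range = c(100, 1000)) {
  stopifnot(n >= 1, phenolic_fraction >= 0, phenolic_fraction <= 1)
  withr::with_seed(as.integer(seed), {
    .generate_library_impl(n, phenolic_fraction, bounds, mz_range)
  })
}

.generate_library_impl <- function(n, phenolic_fraction, bounds, mz_range) {
  n_ph <- round(n * phenolic_fraction)
  n_np <- n - n_ph
  seen <- character(0)
  rows <- vector("list", n)
  sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)
  # low heteroatom counts preferred, as in real phenolic formulas
  draw_ns <- function(rng) {
    v <- rng[1]:rng[2]
    if (length(v) == 1L) return(v)
    sample(v, 1L, prob = 0.6^(seq_along(v) - 1L))
  }
  # compositions are drawn in ratio space (H/C, O/C scaled with carbon),
  # emulating real biomolecules rather than uniform points on the element
  # grid, which would be dominated by chemically implausible extremes
  crange <- function(lo, hi) {
    lo <- max(bounds$c[1], lo); hi <- min(bounds$c[2], hi)
    if (lo > hi) bounds$c[1]:bounds$c[2] else lo:hi
  }
  draw_one <- function(want_phenolic) {
    for (iter in seq_len(5000L)) {
      if (want_phenolic) {
        cc <- sample1(crange(7L, 30L))
        hh <- round(cc * runif(1, 0.62, 1.48))
        oo <- round(cc * runif(1, 0.32, 0.83))
      } else {
        cc <- sample1(crange(5L, 40L))
        hh <- round(cc * runif(1, 0.4, 2.0))
        oo <- round(cc * runif(1, 0.02, 1.0))
      }
      nn <- draw_ns(bounds$n)
      ss <- draw_ns(bounds$s)
      if ((hh + nn) %% 2L == 1L) hh <- hh + 1L  # even-electron parity
      if (hh < bounds$h[1] || hh > bounds$h[2]) next
      if (oo < bounds$o[1] || oo > bounds$o[2]) next
      f <- formula_set(c = cc, h = hh, n = nn, o = oo, s = ss)
      if (rdbe(f) < 0) next
      if (f$h < 1L) next
      mz <- monoisotopic_mass(f) - PROTON_MASS
      if (mz < mz_range[1] || mz > mz_range[2]) next
      if (is_phenolic(f) != want_phenolic) next
      key <- formula_string(f)
      if (key %in% seen) next
      seen <<- c(seen, key)
      return(cbind(f, formula = key, mass = monoisotopic_mass(f), mz = mz,
                   is_phenolic = want_phenolic))
    }
    stop(sprintf(
      "could not generate a %s formula under the given bounds (unsatisfiable request?)",
      if (want_phenolic) "phenolic" else "non-phenolic"))
  }
  k <- 0L
  for (i in seq_len(n_ph)) { k <- k + 1L; rows[[k]] <- draw_one(TRUE) }
  for (i in seq_len(n_np)) { k <- k + 1L; rows[[k]] <- draw_one(FALSE) }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a ground-truth peak population
#'
#' Builds the known truth behind one sample: a formula library with
#' lognormal true intensities (optionally rescaled so the phenolic share
#' of total intensity hits an exact planted value), a set of
#' noise/contaminant m/z shared between samples and blank, and the
#' noise-floor model that turns intensities into S/N values.
#'
#' The noise floor is set to one fifth of the weakest true intensity, so
#' every true peak has S/N > 4 by construction, while a configurable
#' fraction of the noise peaks is planted below the S/N threshold.
#'
#' @param n_formulas Number of true formulas.
#' @param phenolic_fraction Fraction of phenolic formulas (by count).
#' @param n_noise Number of noise/contaminant peaks (present identically
#'   in every replicate and in the blank).
#' @param seed Integer seed (bit-identical output for identical seeds).
#' @param ppm_sigma Gaussian mass-error scale in ppm applied to observed
#'   m/z (default 2).
#' @param replicate_cv Fractional intensity coefficient of variation
#'   between replicates (default 0.1).
#' @param phenolic_intensity_fraction Optional planted phenolic share of
#'   total true intensity, in (0, 1); `NULL` leaves the lognormal draws
#'   unscaled.
#' @param intensity_meanlog,intensity_sdlog Lognormal parameters of the
#'   true intensities.
#' @param noise_snr_fail_fraction Fraction of noise peaks planted below
#'   S/N 4 (default 0.3).
#' @param bounds An [element_bounds()] object.
#' @param mz_range Allowed `[M-H]-` m/z window.
#' @return An object of class `ground_truth`: a list with `formulas`
#'   (library table), `intensity`, `noise_mz`, `noise_intensity`,
#'   `noise_floor`, `seed`, `ppm_sigma`, `replicate_cv`.
#' @export
simulate_ground_truth <- function(n_formulas = 60, phenolic_fraction = 0.35,
                                  n_noise = 10, seed = 1, ppm_sigma = 2,
                                  replicate_cv = 0.1,
                                  phenolic_intensity_fraction = NULL,
                                  intensity_meanlog = log(1e5),
                                  intensity_sdlog = 1,
                                  noise_snr_fail_fraction = 0.3,
                                  bounds = element_bounds(),
                                  mz_range = c(100, 1000)) {
  stopifnot(n_formulas >= 1, n_noise >= 0, ppm_sigma >= 0, replicate_cv >= 0)
  withr::with_seed(as.integer(seed), {
    lib <- .generate_library_impl(n_formulas, phenolic_fraction, bounds,
                                  mz_range)
    intensity <- rlnorm(n_formulas, intensity_meanlog, intensity_sdlog)
    if (!is.null(phenolic_intensity_fraction)) {
      f <- phenolic_intensity_fraction
      stopifnot(f > 0, f < 1)
      ph <- lib$is_phenolic
      if (!any(ph) || all(ph)) {
        stop("planting a phenolic intensity share needs both phenolic and non-phenolic formulas")
      }
      alpha <- f * sum(intensity[!ph]) / ((1 - f) * sum(intensity[ph]))
      intensity[ph] <- intensity[ph] * alpha
    }
    # noise m/z kept > 25 ppm from every true ion and from each other, so
    # blank subtraction at the default 5 ppm never touches true peaks
    noise_mz <- numeric(0)
    guard <- 0L
    while (length(noise_mz) < n_noise) {
      guard <- guard + 1L
      if (guard > 10000L) stop("could not place the requested noise peaks")
      cand <- runif(1, mz_range[1], mz_range[2])
      if (min(abs(cand - c(lib$mz, noise_mz)) / cand) * 1e6 > 25) {
        noise_mz <- c(noise_mz, cand)
      }
    }
    noise_mz <- sort(noise_mz)
    noise_floor <- min(intensity) / 5
    n_fail <- round(noise_snr_fail_fraction * n_noise)
    noise_snr <- c(runif(n_fail, 0.5, 3.9),
                   runif(n_noise - n_fail, 4.5, 30))
    noise_snr <- noise_snr[sample.int(length(noise_snr))]
    structure(list(formulas = lib, intensity = intensity,
                   noise_mz = noise_mz,
                   noise_intensity = noise_snr * noise_floor,
                   noise_floor = noise_floor, seed = as.integer(seed),
                   ppm_sigma = ppm_sigma, replicate_cv = replicate_cv),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d formulas (%d phenolic), %d noise peaks, ppm_sigma = %.3g, replicate CV = %.3g\n",
    nrow(x$formulas), sum(x$formulas$is_phenolic), length(x$noise_mz),
    x$ppm_sigma, x$replicate_cv))
  invisible(x)
}

#' Generate replicate peak lists and a blank from a ground truth
#'
#' Each replicate contains every true formula as an `[M-H]-` peak with
#' multiplicative Gaussian ppm-scale mass error and mean-preserving
#' lognormal intensity jitter (CV = `replicate_cv`), plus the noise peaks
#' at their exact shared m/z; the blank contains exactly the noise peaks.
#' S/N is intensity divided by the truth's noise floor.
#'
#' @param truth A [simulate_ground_truth()] object.
#' @param n_replicates Number of technical replicates (>= 2, default 2).
#' @return A list with `replicates` (list of [peaklist()]s) and `blank`
#'   (a [peaklist()]).
#' @export
generate_peaklists <- function(truth, n_replicates = 2) {
  stopifnot(inherits(truth, "ground_truth"), n_replicates >= 2)
  n <- nrow(truth$formulas)
  sdlog <- sqrt(log(1 + truth$replicate_cv^2))
  withr::with_seed(truth$seed, {
    reps <- lapply(seq_len(n_replicates), function(r) {
      mz_obs <- truth$formulas$mz *
        (1 + rnorm(n, 0, truth$ppm_sigma) * 1e-6)
      int_obs <- truth$intensity * rlnorm(n, -sdlog^2 / 2, sdlog)
      peaklist(c(mz_obs, truth$noise_mz),
               c(int_obs, truth$noise_intensity),
               c(int_obs, truth$noise_intensity) / truth$noise_floor,
               sample_id = sprintf("rep%d", r))
    })
    blank <- peaklist(truth$noise_mz, truth$noise_intensity,
                      truth$noise_intensity / truth$noise_floor,
                      sample_id = "blank")
    list(replicates = reps, blank = blank)
  })
}

#' Generate a sigmoidal dose-response viability table
#'
#' Live-cell counts follow `top / (1 + (dose / ec50)^hill)` with
#' multiplicative mean-preserving lognormal noise; doses are log-spaced
#' around the EC50.
#'
#' @param ec50 True EC50 (same units as doses, > 0).
#' @param hill Hill slope (default 2).
#' @param top Response at vanishing dose (default 1e6 cells/mL).
#' @param n_doses Number of log-spaced doses (>= 4, default 8).
#' @param noise_cv Multiplicative noise CV (default 0.1).
#' @param seed Integer seed.
#' @param n_replicates Replicates per dose; the default 2 mirrors an
#'   exposure series run in biological duplicate.
#' @param dose_span Decades covered on each side of the EC50. The default
#'   1.75 with 8 doses reproduces the canonical half-log (3.16-fold)
#'   serial-dilution design.
#' @return A `data.frame` with columns `dose`, `response`, `replicate`.
#' @export
generate_dose_response <- function(ec50, hill = 2, top = 1e6, n_doses = 8,
                                   noise_cv = 0.1, seed = 1,
                                   n_replicates = 2, dose_span = 1.75) {
  stopifnot(ec50 > 0, n_doses >= 4, noise_cv >= 0, n_replicates >= 1)
  doses <- ec50 * 10^seq(-dose_span, dose_span, length.out = n_doses)
  sdlog <- sqrt(log(1 + noise_cv^2))
  withr::with_seed(as.integer(seed), {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      mu <- top / (1 + (doses / ec50)^hill)
      data.frame(dose = doses,
                 response = mu * rlnorm(n_doses, -sdlog^2 / 2, sdlog),
                 replicate = r)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Write a ground truth's peak lists and truth table to disk
#'
#' Emits one tab-delimited peak-list file per replicate plus
#' `<prefix>_blank.tsv` and `<prefix>_truth.tsv` (columns:
#' `mz_theoretical`, `formula` in Hill order, `intensity_true`,
#' `is_phenolic`).
#'
#' @param truth A [simulate_ground_truth()] object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default "sample").
#' @param n_replicates Number of replicates to write (default 2).
#' @return Character vector of the written paths, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "sample",
                               n_replicates = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_peaklists(truth, n_replicates)
  paths <- character(0)
  for (r in seq_along(gen$replicates)) {
    p <- file.path(dir, sprintf("%s_rep%d.tsv", prefix, r))
    write_peaklist(gen$replicates[[r]], p)
    paths <- c(paths, p)
  }
  pb <- file.path(dir, sprintf("%s_blank.tsv", prefix))
  write_peaklist(gen$blank, pb)
  tt <- data.frame(mz_theoretical = truth$formulas$mz,
                   formula = truth$formulas$formula,
                   intensity_true = truth$intensity,
                   is_phenolic = truth$formulas$is_phenolic)
  pt <- file.path(dir, sprintf("%s_truth.tsv", prefix))
  utils::write.table(tt, pt, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, pb, pt))
}
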