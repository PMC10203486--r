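#' Construct a peak list
#'
#' A peak list is a `data.frame` with numeric columns `mz`, `intensity`
#' and `snr`, sorted by increasing m/z, carrying `sample_id`, `treatment`
#' and `fraction` labels as attributes.
#'
#' @param mz Mass-to-charge values (Th), positive and finite.
#' @param intensity Non-negative intensities (arbitrary units).
#' @param snr Non-negative signal-to-noise ratios.
#' @param sample_id,treatment,fraction Optional labels.
#' @return A `data.frame` of class `peaklist`.
#' @export
peaklist <- function(mz, intensity, snr, sample_id = NA_character_,
                     treatment = NA_character_, fraction = NA_character_) {
  mz <- as.numeric(mz); intensity <- as.numeric(intensity)
  snr <- as.numeric(snr)
  if (length(intensity) != length(mz) || length(snr) != length(mz)) {
    stop("mz, intensity and snr must have the same length")
  }
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be positive and finite")
  if (any(!is.finite(intensity)) || any(intensity < 0)) {
    stop("intensities must be non-negative and finite")
  }
  if (any(!is.finite(snr)) || any(snr < 0)) {
    stop("snr must be non-negative and finite")
  }
  ord <- order(mz)
  df <- data.frame(mz = mz[ord], intensity = intensity[ord], snr = snr[ord])
  .as_peaklist(df, sample_id, treatment, fraction)
}

.as_peaklist <- function(df, sample_id = NA_character_,
                         treatment = NA_character_, fraction = NA_character_) {
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, treatment = treatment,
            fraction = fraction, class = c("peaklist", "data.frame"))
}

# Rebuild a peaklist from a plain data.frame, inheriting labels.
.rebuild <- function(df, template) {
  df <- df[order(df$mz), c("mz", "intensity", "snr"), drop = FALSE]
  .as_peaklist(df, attr(template, "sample_id"), attr(template, "treatment"),
               attr(template, "fraction"))
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Peak list '%s' (%d peaks", attr(x, "sample_id"), nrow(x)))
  if (nrow(x) > 0L) {
    cat(sprintf(", m/z %.4f-%.4f", min(x$mz), max(x$mz)))
  }
  cat(")\n")
  print(head(as.data.frame(x), 6))
  if (nrow(x) > 6L) cat(sprintf("... %d more peaks\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a peak list from a delimited file
#'
#' Accepts tab-, comma-, semicolon- or whitespace-delimited files with a
#' header naming (at least) the columns `mz`, `intensity` and `snr`. Rows
#' with non-numeric or non-finite values are rejected with their row
#' numbers reported as a warning.
#'
#' @param path Path to the file.
#' @param sample_id Label for the sample; defaults to the file name.
#' @param treatment,fraction Optional labels.
#' @return A [peaklist()], sorted by m/z.
#' @export
read_peaklist <- function(path, sample_id = basename(path),
                          treatment = NA_character_, fraction = NA_character_) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty peak list: '%s'", path))
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
         else if (grepl(";", first)) ";" else ""
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           colClasses = "character")
  need <- c("mz", "intensity", "snr")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop(sprintf("missing column(s) %s in '%s'",
                 paste(sQuote(miss), collapse = ", "), path))
  }
  if (nrow(raw) == 0L) stop(sprintf("empty peak list: '%s'", path))
  num <- lapply(raw[need], function(x) suppressWarnings(as.numeric(x)))
  bad <- !is.finite(num$mz) | num$mz <= 0 | !is.finite(num$intensity) |
    num$intensity < 0 | !is.finite(num$snr) | num$snr < 0
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) in '%s': %s", sum(bad),
                    path, paste(which(bad), collapse = ", ")))
  }
  if (all(bad)) stop(sprintf("empty peak list after removing malformed rows: '%s'", path))
  peaklist(num$mz[!bad], num$intensity[!bad], num$snr[!bad],
           sample_id = sample_id, treatment = treatment, fraction = fraction)
}

#' Write a peak list to a tab-delimited file
#'
#' @param pl A [peaklist()] (or data.frame with `mz`, `intensity`, `snr`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  utils::write.table(as.data.frame(pl)[, c("mz", "intensity", "snr")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Quality-filter a peak list
#'
#' Retains peaks with S/N strictly above `snr_min`; among those, retains
#' peaks at or above `rel_intensity_min_pct` percent of the most intense
#' surviving peak (the base peak, which therefore always survives the
#' relative-intensity step). The filter is idempotent.
#'
#' @param pl A [peaklist()].
#' @param snr_min Strict S/N threshold (default 4).
#' @param rel_intensity_min_pct Relative-intensity cutoff in percent of
#'   the base peak (default 0.1).
#' @return The filtered [peaklist()]; may be empty (with a warning).
#' @export
filter_quality <- function(pl, snr_min = 4, rel_intensity_min_pct = 0.1) {
  stopifnot(is.data.frame(pl), nrow(pl) >= 1L)
  keep <- pl[pl$snr > snr_min, , drop = FALSE]
  if (nrow(keep) == 0L) {
    warning("no peaks above the S/N threshold")
    return(.rebuild(keep, pl))
  }
  rel <- 100 * keep$intensity / max(keep$intensity)
  out <- keep[rel >= rel_intensity_min_pct, , drop = FALSE]
  if (nrow(out) == 0L) warning("no peaks above the relative-intensity cutoff")
  .rebuild(out, pl)
}

# Minimum ppm distance from each x to any element of ref (both numeric).
.min_ppm_dist <- function(x, ref) {
  if (length(ref) == 0L) return(rep(Inf, length(x)))
  vapply(x, function(v) min(abs(v - ref) / v) * 1e6, numeric(1))
}

#' Remove blank peaks from a sample peak list
#'
#' Drops every sample peak whose m/z lies within `tol_ppm` (relative to
#' the sample peak's m/z) of any blank m/z. Never adds peaks.
#'
#' @param pl Sample [peaklist()].
#' @param blank Blank [peaklist()] (may be empty).
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return The blank-subtracted [peaklist()].
#' @export
subtract_blank <- function(pl, blank, tol_ppm = 5) {
  stopifnot(is.data.frame(pl))
  d <- .min_ppm_dist(pl$mz, blank$mz)
  .rebuild(pl[d > tol_ppm, , drop = FALSE], pl)
}

# Greedy nearest-first one-to-one matching of two m/z vectors within
# tol_ppm (ppm of the midpoint mass). Ties go to the lower-mz candidate.
# Returns a two-column index matrix (i in a, j in b).
.match_peaks <- function(mz_a, mz_b, tol_ppm) {
  if (length(mz_a) == 0L || length(mz_b) == 0L) {
    return(matrix(integer(), ncol = 2))
  }
  dmat <- abs(outer(mz_a, mz_b, "-")) /
    outer(mz_a, mz_b, function(a, b) (a + b) / 2) * 1e6
  cand <- which(dmat <= tol_ppm, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(), ncol = 2))
  d <- dmat[cand]
  ord <- order(d, mz_a[cand[, 1]], mz_b[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used_a <- logical(length(mz_a)); used_b <- logical(length(mz_b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Consensus of replicate peak lists
#'
#' Keeps only peaks matched across all replicates within `tol_ppm`
#' (greedy nearest-first one-to-one matching). The consensus m/z is the
#' intensity-weighted mean and the consensus intensity the arithmetic mean
#' of the matched peaks, so replicate count does not inflate abundance.
#'
#' @param replicates A list of at least two [peaklist()]s.
#' @param tol_ppm Matching tolerance in ppm (default 5).
#' @return The consensus [peaklist()] (snr = mean of matched snr values).
#' @export
replicate_consensus <- function(replicates, tol_ppm = 5) {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("replicate consensus requires at least two replicate peak lists")
  }
  base <- as.data.frame(replicates[[1]])
  sets_mz <- as.list(base$mz)
  sets_int <- as.list(base$intensity)
  sets_snr <- as.list(base$snr)
  key_mz <- base$mz
  for (r in 2:length(replicates)) {
    rep_df <- as.data.frame(replicates[[r]])
    m <- .match_peaks(key_mz, rep_df$mz, tol_ppm)
    if (nrow(m) == 0L) {
      sets_mz <- list(); break
    }
    ord <- order(m[, 1])
    m <- m[ord, , drop = FALSE]
    sets_mz <- lapply(seq_len(nrow(m)), function(k)
      c(sets_mz[[m[k, 1]]], rep_df$mz[m[k, 2]]))
    sets_int <- lapply(seq_len(nrow(m)), function(k)
      c(sets_int[[m[k, 1]]], rep_df$intensity[m[k, 2]]))
    sets_snr <- lapply(seq_len(nrow(m)), function(k)
      c(sets_snr[[m[k, 1]]], rep_df$snr[m[k, 2]]))
    key_mz <- vapply(sets_mz, function(v) mean(v), numeric(1))
  }
  if (length(sets_mz) == 0L) {
    out <- data.frame(mz = numeric(), intensity = numeric(), snr = numeric())
    return(.rebuild(out, replicates[[1]]))
  }
  mz <- mapply(function(v, w) stats::weighted.mean(v, pmax(w, 1e-300)),
               sets_mz, sets_int)
  out <- data.frame(mz = mz,
                    intensity = vapply(sets_int, mean, numeric(1)),
                    snr = vapply(sets_snr, mean, numeric(1)))
  .rebuild(out, replicates[[1]])
}

#' Merge chromatographic fractions into one peak list
#'
#' Unions the peaks of all fractions; peaks within `tol_ppm` of each other
#' (single-linkage along the sorted m/z axis) are merged with summed
#' intensity and intensity-weighted mean m/z, so total intensity is
#' conserved.
#'
#' @param fractions A list of one or more [peaklist()]s.
#' @param tol_ppm Merge tolerance in ppm (default 5).
#' @return The merged [peaklist()] (snr = max over merged peaks).
#' @export
merge_fractions <- function(fractions, tol_ppm = 5) {
  if (!is.list(fractions) || length(fractions) < 1L) {
    stop("merge_fractions requires at least one peak list")
  }
  all_df <- do.call(rbind, lapply(fractions, function(x)
    as.data.frame(x)[, c("mz", "intensity", "snr")]))
  if (nrow(all_df) == 0L) return(.rebuild(all_df, fractions[[1]]))
  all_df <- all_df[order(all_df$mz), , drop = FALSE]
  gap_ppm <- c(Inf, diff(all_df$mz) / all_df$mz[-1] * 1e6)
  cluster <- cumsum(gap_ppm > tol_ppm)
  merged <- do.call(rbind, lapply(split(all_df, cluster), function(g) {
    w <- if (sum(g$intensity) > 0) g$intensity else rep(1, nrow(g))
    data.frame(mz = stats::weighted.mean(g$mz, w),
               intensity = sum(g$intensity), snr = max(g$snr))
  }))
  .rebuild(merged, fractions[[1]])
}
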