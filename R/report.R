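#' Compare a metric across treatment groups
#'
#' Reproduces the comparative statistics of the workflow: a Shapiro-Wilk
#' normality screen per group, pairwise two-sample Wilcoxon rank-sum tests
#' (exact p-values for small tie-free samples), and a compact letter
#' display at the chosen alpha: groups sharing a letter are not
#' significantly different. Letters are derived deterministically from the
#' maximal cliques of the non-significance graph.
#'
#' With duplicate samples (n = 2 per group) the exact rank-sum test cannot
#' reach p < 0.05; a warning flags this power limit.
#'
#' @param values Named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; `"none"` (default) applies the plain per-pair
#'   alpha policy.
#' @return An object of class `treatment_comparison`: a list with `groups`
#'   (`data.frame`: group, n, mean, median, shapiro_p, letters), `pairs`
#'   (`data.frame`: group1, group2, p), `p_matrix`, `alpha`.
#' @export
compare_groups <- function(values, alpha = 0.05, p_adjust = "none") {
  stopifnot(is.list(values), length(values) >= 2L)
  if (is.null(names(values)) || any(!nzchar(names(values)))) {
    stop("groups must be named")
  }
  ns <- lengths(values)
  if (any(ns < 2L)) {
    stop(sprintf("every group needs at least 2 values (offending: %s)",
                 paste(names(values)[ns < 2L], collapse = ", ")))
  }
  if (all(ns == 2L)) {
    warning("with duplicate samples (n = 2) the exact rank-sum test cannot reach p < 0.05; significance letters will not separate groups")
  }
  gnames <- names(values)
  shapiro_p <- vapply(values, function(v) {
    if (length(v) < 3L || sd(v) == 0) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  prs <- utils::combn(gnames, 2L)
  p <- apply(prs, 2L, function(g) {
    suppressWarnings(stats::wilcox.test(values[[g[1]]], values[[g[2]]],
                                        exact = NULL)$p.value)
  })
  p <- stats::p.adjust(p, method = p_adjust)
  pmat <- matrix(1, length(gnames), length(gnames),
                 dimnames = list(gnames, gnames))
  for (k in seq_len(ncol(prs))) {
    pmat[prs[1, k], prs[2, k]] <- p[k]
    pmat[prs[2, k], prs[1, k]] <- p[k]
  }
  letters_out <- .compact_letters(pmat, alpha,
                                  order_by = -vapply(values, mean, numeric(1)))
  groups <- data.frame(group = gnames, n = as.integer(ns),
                       mean = vapply(values, mean, numeric(1)),
                       median = vapply(values, median, numeric(1)),
                       shapiro_p = shapiro_p,
                       letters = letters_out[gnames],
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(groups = groups,
                 pairs = data.frame(group1 = prs[1, ], group2 = prs[2, ],
                                    p = p, stringsAsFactors = FALSE),
                 p_matrix = pmat, alpha = alpha),
            class = "treatment_comparison")
}

# Compact letter display from a symmetric p-value matrix: letters are the
# maximal cliques of the graph whose edges join pairs with p >= alpha.
.compact_letters <- function(pmat, alpha, order_by = NULL) {
  gnames <- rownames(pmat)
  adj <- pmat >= alpha
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  members <- lapply(cliques, function(cl) gnames[as.integer(cl)])
  rank <- if (is.null(order_by)) seq_along(gnames)
          else rank(order_by, ties.method = "first")
  names(rank) <- gnames
  ord <- order(vapply(members, function(m) min(rank[m]), numeric(1)))
  members <- members[ord]
  out <- setNames(rep("", length(gnames)), gnames)
  for (k in seq_along(members)) {
    out[members[[k]]] <- paste0(out[members[[k]]], letters[k])
  }
  vapply(out, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
         character(1))
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Treatment comparison (alpha = %g)\n", x$alpha))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

# Run one stage with failure context (group / stage name in the error).
.stage <- function(group, stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline failed in group '%s', stage '%s': %s",
                 group, stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full phenolic-profiling pipeline over treatment groups
#'
#' For every group: quality filter each replicate (S/N, relative
#' intensity), subtract the blank, form the replicate consensus, merge
#' chromatographic fractions when present, assign molecular formulas,
#' classify phenolics and summarize them, and build the mass-difference
#' network on the phenolic m/z values. Row counts are logged per stage.
#' The pipeline itself draws no random numbers, so a given input always
#' yields identical output.
#'
#' @param samples Named list of groups. Each group is either a list of
#'   replicate [peaklist()]s (single fraction) or a list of fractions,
#'   each itself a list of replicate peak lists.
#' @param blanks A single blank [peaklist()] shared by all groups, or a
#'   named list with one blank per group.
#' @param transformations Transformation table for the network stage.
#' @param snr_min,rel_intensity_min_pct Quality-filter settings (see
#'   [filter_quality()]).
#' @param match_tol_ppm Tolerance for blank subtraction, replicate
#'   consensus and fraction merging (default 5 ppm).
#' @param assign_tol_ppm Formula-assignment tolerance (default 10 ppm).
#' @param bounds An [element_bounds()] object.
#' @param network_tol_ppm Mass-difference matching tolerance (default 2
#'   ppm).
#' @param network_mode `"ppm"` or `"mda"` (see [build_network()]).
#' @param verbose Emit progress messages.
#' @return An object of class `phenolms_pipeline`: per group a list with
#'   `consensus`, `assigned`, `phenolics` (a `phenolic_summary`),
#'   `network`, `network_summary`, `stage_counts`; plus `params`.
#' @export
run_pipeline <- function(samples, blanks,
                         transformations = default_transformations(),
                         snr_min = 4, rel_intensity_min_pct = 0.1,
                         match_tol_ppm = 5, assign_tol_ppm = 10,
                         bounds = element_bounds(), network_tol_ppm = 2,
                         network_mode = "ppm", verbose = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 1L)
  if (is.null(names(samples))) stop("sample groups must be named")
  get_blank <- function(g) {
    if (is.data.frame(blanks)) blanks
    else {
      if (!g %in% names(blanks)) stop(sprintf("no blank for group '%s'", g))
      blanks[[g]]
    }
  }
  results <- list()
  for (g in names(samples)) {
    grp <- samples[[g]]
    is_fractions <- !is.data.frame(grp[[1]])
    fracs <- if (is_fractions) grp else list(merged = grp)
    counts <- list()
    blank <- get_blank(g)
    consensus_by_frac <- list()
    for (fr in names(fracs) %||% seq_along(fracs)) {
      reps <- fracs[[fr]]
      counts[[length(counts) + 1L]] <-
        data.frame(stage = "raw", fraction = fr,
                   n = sum(vapply(reps, nrow, integer(1))))
      filtered <- .stage(g, "filter_quality", lapply(reps, filter_quality,
        snr_min = snr_min, rel_intensity_min_pct = rel_intensity_min_pct))
      counts[[length(counts) + 1L]] <-
        data.frame(stage = "filtered", fraction = fr,
                   n = sum(vapply(filtered, nrow, integer(1))))
      nosolvent <- .stage(g, "subtract_blank", lapply(filtered,
        subtract_blank, blank = blank, tol_ppm = match_tol_ppm))
      counts[[length(counts) + 1L]] <-
        data.frame(stage = "blank_subtracted", fraction = fr,
                   n = sum(vapply(nosolvent, nrow, integer(1))))
      cons <- .stage(g, "replicate_consensus",
                     replicate_consensus(nosolvent, tol_ppm = match_tol_ppm))
      counts[[length(counts) + 1L]] <-
        data.frame(stage = "consensus", fraction = fr, n = nrow(cons))
      consensus_by_frac[[fr]] <- cons
    }
    consensus <- if (length(consensus_by_frac) > 1L) {
      .stage(g, "merge_fractions",
             merge_fractions(consensus_by_frac, tol_ppm = match_tol_ppm))
    } else consensus_by_frac[[1L]]
    counts[[length(counts) + 1L]] <-
      data.frame(stage = "merged", fraction = "all", n = nrow(consensus))
    assigned <- .stage(g, "assign_formulas",
                       assign_formulas(consensus, tol_ppm = assign_tol_ppm,
                                       bounds = bounds))
    phen <- .stage(g, "summarize_phenolics",
                   suppressWarnings(summarize_phenolics(assigned)))
    phen_mz <- assigned$mz[!is.na(assigned$is_phenolic) & assigned$is_phenolic]
    network <- NULL
    net_summary <- NULL
    if (length(unique(phen_mz)) >= 2L) {
      network <- .stage(g, "build_network",
                        build_network(phen_mz, transformations,
                                      tol_ppm = network_tol_ppm,
                                      mode = network_mode))
      net_summary <- summarize_network(network)
    }
    stage_counts <- do.call(rbind, counts)
    if (verbose) {
      message(sprintf(
        "group %s: %d consensus peaks, %d phenolic formulas, %d network edges",
        g, nrow(consensus), phen$n_phenolics,
        if (is.null(net_summary)) 0L else net_summary$n_edges))
    }
    results[[g]] <- list(consensus = consensus, assigned = assigned,
                         phenolics = phen, network = network,
                         network_summary = net_summary,
                         stage_counts = stage_counts)
  }
  structure(list(groups = results,
                 params = list(snr_min = snr_min,
                               rel_intensity_min_pct = rel_intensity_min_pct,
                               match_tol_ppm = match_tol_ppm,
                               assign_tol_ppm = assign_tol_ppm,
                               network_tol_ppm = network_tol_ppm,
                               network_mode = network_mode)),
            class = "phenolms_pipeline")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phenolms_pipeline <- function(x, ...) {
  cat("Phenolic profiling pipeline results\n")
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    cat(sprintf(
      "  %-10s %4d consensus peaks | phenolics: %.3f%% of signal, %d formulas, DA %.4f | edges: %d\n",
      g, nrow(r$consensus), r$phenolics$rel_intensity_pct,
      r$phenolics$n_phenolics,
      if (is.na(r$phenolics$da)) NA else r$phenolics$da,
      if (is.null(r$network_summary)) 0L else r$network_summary$n_edges))
  }
  invisible(x)
}

#' Simulate a full multi-group metal-stress experiment
#'
#' Generates, per treatment group, a ground truth with a planted phenolic
#' share of total intensity, duplicate replicate peak lists and a blank.
#' Defaults emulate the study design the workflow targets: a control and
#' three metal treatments at sub-lethal exposure, with the metal groups
#' carrying an elevated phenolic share.
#'
#' @param groups Named numeric vector of planted phenolic intensity
#'   fractions per group.
#' @param n_formulas,phenolic_fraction,n_noise,ppm_sigma,replicate_cv
#'   Passed to [simulate_ground_truth()].
#' @param n_replicates Technical replicates per group (default 2).
#' @param seed Integer master seed; per-group seeds are drawn from it.
#' @return A list with `truths`, `samples` (named list of replicate
#'   lists), `blanks` (named list), ready for [run_pipeline()].
#' @export
simulate_experiment <- function(groups = c(control = 0.0204, Cd = 0.0288,
                                           Cu = 0.0295, Co = 0.0302),
                                n_formulas = 60, phenolic_fraction = 0.35,
                                n_noise = 10, n_replicates = 2,
                                ppm_sigma = 2, replicate_cv = 0.1, seed = 1) {
  stopifnot(length(groups) >= 1L, !is.null(names(groups)))
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max - 1L,
                                       length(groups)))
  truths <- list(); samples <- list(); blanks <- list()
  for (k in seq_along(groups)) {
    g <- names(groups)[k]
    truths[[g]] <- simulate_ground_truth(
      n_formulas = n_formulas, phenolic_fraction = phenolic_fraction,
      n_noise = n_noise, seed = seeds[k], ppm_sigma = ppm_sigma,
      replicate_cv = replicate_cv, phenolic_intensity_fraction = groups[[k]])
    gen <- generate_peaklists(truths[[g]], n_replicates = n_replicates)
    samples[[g]] <- gen$replicates
    blanks[[g]] <- gen$blank
  }
  list(truths = truths, samples = samples, blanks = blanks)
}
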