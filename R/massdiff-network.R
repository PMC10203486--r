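#' Heteroatom group of a transformation formula
#'
#' Groups transformations by element content: sulfur-containing (group 1),
#' nitrogen only (2), nitrogen and oxygen (3), oxygen only (4); CH-only
#' transformations are ungrouped (`NA`).
#'
#' @param f A formula table (see [formula_set()]).
#' @return Integer vector (1-4 or `NA`).
#' @export
hetero_group <- function(f) {
  .check_formula(f)
  ifelse(f$s > 0L, 1L,
    ifelse(f$n > 0L & f$o == 0L, 2L,
      ifelse(f$n > 0L & f$o > 0L, 3L,
        ifelse(f$o > 0L, 4L, NA_integer_))))
}

.validate_transformations <- function(tf) {
  stopifnot(is.data.frame(tf))
  if (!all(c("name", "exact_mass") %in% names(tf))) {
    stop("transformation table needs columns 'name' and 'exact_mass'")
  }
  if (nrow(tf) == 0L) stop("empty transformation table")
  if (anyDuplicated(tf$name)) {
    stop(sprintf("duplicate transformation name(s): %s",
                 paste(unique(tf$name[duplicated(tf$name)]), collapse = ", ")))
  }
  if (any(!is.finite(tf$exact_mass)) || any(tf$exact_mass <= 0)) {
    stop("transformation masses must be positive and finite")
  }
  tf
}

#' Load a metabolite transformation table
#'
#' Reads a delimited table of biochemical building blocks (amino-acid
#' residues, nucleobases, sugar/acyl increments, ...) used as candidate
#' mass differences in [build_network()]. Required columns: `name`,
#' `exact_mass` (Da). Optional: `formula` (CHNOS, cross-checked against
#' the computed monoisotopic mass within 1 mDa and used to derive the
#' heteroatom `group` when that column is absent), `group`.
#'
#' @param path Path to a tab-, comma- or semicolon-delimited file.
#' @return A validated `data.frame` with columns `name`, `exact_mass`,
#'   `formula` (may be `NA`), `group`.
#' @export
load_transformations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty transformation table: '%s'", path))
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
         else if (grepl(";", first)) ";" else ""
  tf <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(tf) == 0L) stop(sprintf("empty transformation table: '%s'", path))
  tf$exact_mass <- as.numeric(tf$exact_mass)
  .validate_transformations(tf)
  if (!"formula" %in% names(tf)) tf$formula <- NA_character_
  has_f <- !is.na(tf$formula) & nzchar(tf$formula)
  if (any(has_f)) {
    fm <- parse_formula(tf$formula[has_f])
    calc <- monoisotopic_mass(fm)
    off <- abs(calc - tf$exact_mass[has_f])
    if (any(off > 1e-3)) {
      bad <- tf$name[has_f][off > 1e-3]
      stop(sprintf(
        "exact_mass inconsistent with formula (>1 mDa) for: %s",
        paste(bad, collapse = ", ")))
    }
    if (!"group" %in% names(tf)) tf$group <- NA_integer_
    tf$group[has_f & is.na(tf$group)] <-
      hetero_group(fm)[is.na(tf$group[has_f])]
  }
  if (!"group" %in% names(tf)) tf$group <- NA_integer_
  tf$group <- as.integer(tf$group)
  tf[, c("name", "exact_mass", "formula", "group")]
}

#' Default metabolite transformation table
#'
#' The table shipped with the package: amino-acid residues, nucleobases,
#' common sugar/acetyl/methyl/oxygen increments, glyoxylate, allantoin and
#' related small metabolites, with monoisotopic masses computed from their
#' formulas. It is a package-supplied stand-in for a laboratory's own
#' curated metabolite list and is freely replaceable via
#' [load_transformations()].
#'
#' @return A transformation `data.frame` (see [load_transformations()]).
#' @export
default_transformations <- function() {
  load_transformations(system.file("extdata", "transformations.tsv",
                                   package = "phenolms", mustWork = TRUE))
}

#' Build a mass-difference transformation network
#'
#' Every observed m/z is a node; for every unordered pair of nodes and
#' every transformation, an edge is emitted when the pair's mass
#' difference matches the transformation's exact mass within tolerance.
#' All qualifying (pair, transformation) combinations are kept, so a pair
#' may carry multiple parallel edges.
#'
#' In ppm mode the tolerance is `tol_ppm * 1e-6 * mz_hi`, referenced to
#' the larger member of the pair because instrumental mass error scales
#' with measured m/z; `mode = "mda"` uses an absolute window of `tol_mda`
#' millidalton instead.
#'
#' @param mzs Numeric vector of node m/z values (>= 2 distinct values).
#' @param transformations A transformation table (default:
#'   [default_transformations()]).
#' @param tol_ppm Tolerance in ppm of the larger pair member (default 2).
#' @param mode `"ppm"` (default) or `"mda"`.
#' @param tol_mda Absolute tolerance in mDa when `mode = "mda"`.
#' @return An object of class `massdiff_network`: a list with `nodes`
#'   (`data.frame`: `id`, `mz`) and `edges` (`data.frame`: `node_lo`,
#'   `node_hi`, `mz_lo`, `mz_hi`, `transformation`, `group`,
#'   `delta_observed`, `match_error_ppm`).
#' @export
build_network <- function(mzs, transformations = default_transformations(),
                          tol_ppm = 2, mode = c("ppm", "mda"), tol_mda = 0.5) {
  mode <- match.arg(mode)
  tf <- .validate_transformations(transformations)
  mzs <- sort(unique(as.numeric(mzs)))
  if (length(mzs) < 2L) stop("a network needs at least two distinct nodes")
  nodes <- data.frame(id = sprintf("%.5f", mzs), mz = mzs,
                      stringsAsFactors = FALSE)
  n <- length(mzs)
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  delta <- mzs[j] - mzs[i]
  tol <- if (mode == "ppm") tol_ppm * 1e-6 * mzs[j]
         else rep(tol_mda * 1e-3, length(j))
  edges <- vector("list", nrow(tf))
  for (t in seq_len(nrow(tf))) {
    hit <- which(abs(delta - tf$exact_mass[t]) <= tol)
    if (length(hit) == 0L) next
    edges[[t]] <- data.frame(
      node_lo = nodes$id[i[hit]], node_hi = nodes$id[j[hit]],
      mz_lo = mzs[i[hit]], mz_hi = mzs[j[hit]],
      transformation = tf$name[t],
      group = if ("group" %in% names(tf)) tf$group[t] else NA_integer_,
      delta_observed = delta[hit],
      match_error_ppm = (delta[hit] - tf$exact_mass[t]) / mzs[j[hit]] * 1e6,
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(node_lo = character(), node_hi = character(),
                        mz_lo = numeric(), mz_hi = numeric(),
                        transformation = character(), group = integer(),
                        delta_observed = numeric(),
                        match_error_ppm = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- edges[order(edges$mz_lo, edges$mz_hi, edges$transformation), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 params = list(tol_ppm = tol_ppm, mode = mode,
                               tol_mda = tol_mda)),
            class = "massdiff_network")
}

#' @export
print.massdiff_network <- function(x, ...) {
  cat(sprintf(
    "Mass-difference network: %d nodes, %d edges, %d distinct transformations\n",
    nrow(x$nodes), nrow(x$edges), length(unique(x$edges$transformation))))
  cat(sprintf("  tolerance: %s\n",
              if (x$params$mode == "ppm")
                sprintf("%.3g ppm of the larger pair member", x$params$tol_ppm)
              else sprintf("%.3g mDa absolute", x$params$tol_mda)))
  invisible(x)
}

#' Summarize a mass-difference network
#'
#' Per-transformation edge counts normalized to relative abundances
#' (summing to 1 when edges exist), heteroatom group totals, and distinct
#' transformation count.
#'
#' @param net A [build_network()] result.
#' @return An object of class `network_summary`: a list with `n_nodes`,
#'   `n_edges`, `n_distinct_transformations`, `abundance` (`data.frame`:
#'   `transformation`, `group`, `n_edges`, `abundance`) and `group_totals`
#'   (named numeric for groups 1-4 plus `ungrouped`).
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "massdiff_network"))
  ed <- net$edges
  groups <- c("1", "2", "3", "4", "ungrouped")
  if (nrow(ed) == 0L) {
    return(structure(list(
      n_nodes = nrow(net$nodes), n_edges = 0L,
      n_distinct_transformations = 0L,
      abundance = data.frame(transformation = character(), group = integer(),
                             n_edges = integer(), abundance = numeric()),
      group_totals = setNames(rep(0, length(groups)), groups)),
      class = "network_summary"))
  }
  cnt <- as.data.frame(table(ed$transformation), stringsAsFactors = FALSE)
  names(cnt) <- c("transformation", "n_edges")
  grp <- ed$group[match(cnt$transformation, ed$transformation)]
  ab <- data.frame(transformation = cnt$transformation, group = grp,
                   n_edges = cnt$n_edges,
                   abundance = cnt$n_edges / sum(cnt$n_edges),
                   stringsAsFactors = FALSE)
  ab <- ab[order(-ab$abundance, ab$transformation), , drop = FALSE]
  rownames(ab) <- NULL
  gkey <- ifelse(is.na(ab$group), "ungrouped", as.character(ab$group))
  totals <- setNames(rep(0, length(groups)), groups)
  agg <- tapply(ab$abundance, gkey, sum)
  totals[names(agg)] <- agg
  structure(list(n_nodes = nrow(net$nodes), n_edges = nrow(ed),
                 n_distinct_transformations = nrow(ab),
                 abundance = ab, group_totals = totals),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: %d nodes, %d edges, %d distinct transformations\n",
              x$n_nodes, x$n_edges, x$n_distinct_transformations))
  cat("  heteroatom group totals (fraction of edges):\n")
  print(round(x$group_totals, 3))
  invisible(x)
}

#' Write node and edge tables of a network
#'
#' Emits `<prefix>_nodes.tsv` and `<prefix>_edges.tsv`, plain tab-delimited
#' tables importable by standard graph viewers (node id = m/z string; edge
#' attributes: transformation, group, mass error).
#'
#' @param net A [build_network()] result.
#' @param prefix Output path prefix.
#' @return Character vector of the two paths, invisibly.
#' @export
write_network_tables <- function(net, prefix) {
  stopifnot(inherits(net, "massdiff_network"))
  paths <- paste0(prefix, c("_nodes.tsv", "_edges.tsv"))
  utils::write.table(net$nodes, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
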