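#' Top bottleneck-scored nodes
#'
#' Keeps every node whose bottleneck score falls in the `k_levels` largest
#' *distinct* score values, ties all retained. With `k_levels = 10` this is
#' the "10 best bottleneck scores" rule: a table of 22 proteins can satisfy
#' it when score levels are shared.
#'
#' @param table a candidate table as from [node_metrics()] (columns `name`,
#'   `bottleneck`, `clustering_coefficient`, ...).
#' @param k_levels number of distinct score levels to keep (`Inf` keeps
#'   all).
#' @return Character vector of node names sorted by score descending then
#'   name.
#' @export
top_bottleneck <- function(table, k_levels = 10) {
  stopifnot(is.data.frame(table), nrow(table) >= 1, k_levels >= 1)
  levels_desc <- sort(unique(table$bottleneck), decreasing = TRUE)
  keep_levels <- utils::head(levels_desc, n = min(k_levels, length(levels_desc)))
  sel <- table[table$bottleneck %in% keep_levels, , drop = FALSE]
  sel$name[order(-sel$bottleneck, sel$name)]
}

#' Date-hub filter
#'
#' Retains nodes whose local clustering coefficient is strictly below
#' `cc_threshold`. Hubs with low co-clustering ("date hubs") are taken to
#' bind their partners sequentially and are the interesting regulatory
#' candidates; a node at exactly the threshold is excluded.
#'
#' @param nodes candidate node names (subset of `table$name`).
#' @param table a candidate table with `name` and `clustering_coefficient`.
#' @param cc_threshold clustering-coefficient cutoff, default 0.5.
#' @return Character vector, in the order given.
#' @export
date_hub_filter <- function(nodes, table, cc_threshold = 0.5) {
  stopifnot(all(nodes %in% table$name))
  cc <- table$clustering_coefficient[match(nodes, table$name)]
  nodes[cc < cc_threshold]
}

#' Pathway coverage per node
#'
#' Counts, for each node, the number of term groups whose associated genes
#' contain it. Nodes appearing in no group count 0.
#'
#' @param groups a list of term groups (each with an `associated_genes`
#'   element), as from [group_terms()] or [table2_fixture()].
#' @param nodes character vector of node names.
#' @return A named integer vector over `nodes`.
#' @export
pathway_coverage <- function(groups, nodes) {
  nodes <- as.character(nodes)
  counts <- vapply(nodes, function(nm) {
    sum(vapply(groups, function(g) nm %in% g$associated_genes, logical(1)))
  }, integer(1))
  stats::setNames(as.integer(counts), nodes)
}

#' Median-cutoff selection
#'
#' The sample median of all coverage counts (zeros included; even-length
#' samples take the mean of the two middle values) is the statistical
#' cutoff; nodes with coverage at or above it are selected.
#'
#' @param coverage a named integer vector as from [pathway_coverage()].
#' @return A list with `median` and `selected` (node names sorted by count
#'   descending then name).
#' @export
median_cutoff_select <- function(coverage) {
  stopifnot(length(coverage) >= 1, !is.null(names(coverage)))
  med <- stats::median(as.numeric(coverage))
  sel <- coverage[coverage >= med]
  list(median = med,
       selected = names(sel)[order(-sel, names(sel))])
}

#' Key-protein prioritization cascade
#'
#' Composes the selection pipeline: top bottleneck score levels, date-hub
#' filter on the clustering coefficient, pathway-coverage counting over
#' enrichment groups, and the median-coverage cutoff.
#'
#' @param metrics a candidate table ([node_metrics()] layout).
#' @param groups term groups carrying `associated_genes`.
#' @param k_levels distinct bottleneck levels to keep (default 10).
#' @param cc_threshold date-hub clustering-coefficient cutoff (default 0.5).
#' @return A list of class `prioritization_result` with `candidates`,
#'   `coverage`, `median_cutoff`, `key_proteins`.
#' @export
run_prioritization <- function(metrics, groups, k_levels = 10,
                               cc_threshold = 0.5) {
  cand <- top_bottleneck(metrics, k_levels = k_levels)
  cand <- date_hub_filter(cand, metrics, cc_threshold = cc_threshold)
  cov <- pathway_coverage(groups, cand)
  sel <- median_cutoff_select(cov)
  structure(list(candidates = cand, coverage = cov,
                 median_cutoff = sel$median, key_proteins = sel$selected),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf(paste0("prioritization: %d candidates -> %d key proteins ",
                     "(median pathway coverage cutoff %.3g)\n"),
              length(x$candidates), length(x$key_proteins), x$median_cutoff))
  cat("  key proteins:", paste(x$key_proteins, collapse = ", "), "\n")
  invisible(x)
}
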