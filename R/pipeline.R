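#' Pipeline configuration
#'
#' Bundles every stage parameter of the end-to-end analysis. Defaults
#' reproduce the pinned per-module defaults.
#'
#' @param edges path to a STRING-style edge list, or an
#'   [interaction_network]; ignored when `fixtures = "paper"`.
#' @param seed_nodes optional character vector of seed-protein names.
#' @param gmt path to a GMT annotation file, or an [annotation_set];
#'   ignored when `fixtures = "paper"`.
#' @param score_threshold STRING confidence threshold (default 900).
#' @param mcode an [mcode_params()] list.
#' @param alpha enrichment significance threshold.
#' @param kappa_threshold kappa grouping threshold.
#' @param k_levels distinct bottleneck levels kept by prioritization.
#' @param cc_threshold date-hub clustering-coefficient cutoff.
#' @param fixtures `"paper"` runs the transcribed candidate-table and
#'   pathway-group fixtures with no external inputs; `NULL` (default) runs
#'   from `edges`/`gmt`.
#' @param seed RNG seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(edges = NULL, seed_nodes = NULL, gmt = NULL,
                            score_threshold = 900, mcode = mcode_params(),
                            alpha = 0.05, kappa_threshold = 0.4,
                            k_levels = 10, cc_threshold = 0.5,
                            fixtures = NULL, seed = 1) {
  structure(list(edges = edges, seed_nodes = seed_nodes, gmt = gmt,
                 score_threshold = score_threshold, mcode = mcode,
                 alpha = alpha, kappa_threshold = kappa_threshold,
                 k_levels = k_levels, cc_threshold = cc_threshold,
                 fixtures = fixtures, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end network-pharmacology pipeline
#'
#' Edge list -> topology metrics -> MCODE modules -> hypergeometric
#' enrichment with kappa grouping -> bottleneck/date-hub/median-coverage
#' prioritization. With `fixtures = "paper"` the transcribed candidate
#' table and pathway groups are used directly and only the prioritization
#' cascade runs. Stage outputs are written to `out_dir` (if given) together
#' with a machine-readable run manifest; everything is deterministic under
#' a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; created if missing.
#' @return A list of class `pipeline_result` with `summary`, `metrics`,
#'   `modules`, `enrichment`, `groups`, `prioritization`, `counts`
#'   (node/edge/term counts after each stage).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  counts <- list()
  if (identical(config$fixtures, "paper")) {
    metrics <- table1_fixture()
    groups <- table2_fixture()
    net <- NULL; modules <- list(); enr <- NULL; summary <- NULL
    counts$candidate_rows <- nrow(metrics)
    counts$term_groups <- length(groups)
  } else {
    net <- if (inherits(config$edges, "interaction_network")) config$edges else
      read_string_tsv(config$edges, score_threshold = config$score_threshold,
                      seed_nodes = config$seed_nodes)
    counts$nodes <- unname(network_size(net)["nodes"])
    counts$edges <- unname(network_size(net)["edges"])
    summary <- summarize_network(net)
    metrics <- node_metrics(net)
    modules <- find_modules(net, config$mcode)
    counts$modules <- length(modules)
    annotation <- if (inherits(config$gmt, "annotation_set")) config$gmt else
      if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
    if (!is.null(annotation)) {
      query <- intersect(metrics$name[metrics$role == "seed"],
                         annotation$universe)
      if (!length(query)) query <- intersect(metrics$name, annotation$universe)
      enr <- enrich(query, annotation, alpha = config$alpha)
      groups <- group_terms(enr, annotation$universe,
                            kappa_threshold = config$kappa_threshold)
      counts$enriched_terms <- nrow(enr)
      counts$term_groups <- length(groups)
    } else {
      enr <- NULL; groups <- list()
    }
  }
  prior <- run_prioritization(metrics, groups, k_levels = config$k_levels,
                              cc_threshold = config$cc_threshold)
  counts$candidates <- length(prior$candidates)
  counts$key_proteins <- length(prior$key_proteins)
  result <- structure(list(summary = summary, metrics = metrics,
                           modules = modules, enrichment = enr,
                           groups = groups, prioritization = prior,
                           counts = counts),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_metrics_csv(result$metrics, file.path(out_dir, "metrics.csv"))
  write_modules_tsv(result$modules, file.path(out_dir, "modules.tsv"))
  if (!is.null(result$enrichment)) {
    write_groups_tsv(result$groups, result$enrichment,
                     file.path(out_dir, "groups.tsv"))
  }
  kp <- result$prioritization
  utils::write.table(
    data.frame(name = kp$key_proteins,
               pathway_coverage = unname(kp$coverage[kp$key_proteins])),
    file.path(out_dir, "key_proteins.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    config = config[c("score_threshold", "alpha", "kappa_threshold",
                      "k_levels", "cc_threshold", "seed", "fixtures")],
    mcode = unclass(config$mcode),
    counts = result$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(result$summary)) {
    jsonlite::write_json(unclass(result$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-16s %s\n", nm, x$counts[[nm]]))
  }
  print(x$prioritization)
  invisible(x)
}
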