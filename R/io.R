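#' Read a STRING-style edge list
#'
#' Parses a whitespace/tab separated edge list with columns
#' `protein1 protein2 [combined_score]` as exported from STRING. Scores are
#' integers on the 0--1000 scale; a missing third column is treated as 1000.
#' A header line whose score field is non-numeric is skipped.
#'
#' @param path path to the edge-list file.
#' @param score_threshold integer in \[0, 1000\]; edges with
#'   `score < score_threshold` are dropped. Default 900, the "high
#'   confidence" STRING setting.
#' @param seed_nodes optional character vector; matching nodes are labelled
#'   `"seed"`, all others `"connector"`.
#' @return An [interaction_network]. Filtering everything away yields an
#'   empty network, not an error.
#' @export
read_string_tsv <- function(path, score_threshold = 900, seed_nodes = NULL) {
  stopifnot(length(score_threshold) == 1, score_threshold >= 0,
            score_threshold <= 1000)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  p1 <- character(0); p2 <- character(0); sc <- integer(0)
  for (i in idx) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) < 2) {
      stop(sprintf("malformed edge line %d: expected >= 2 fields", i))
    }
    s <- if (length(fields) >= 3) suppressWarnings(as.numeric(fields[3])) else 1000
    if (is.na(s)) {
      # tolerate a single header row (e.g. "protein1 protein2 combined_score")
      if (i == idx[1]) next
      stop(sprintf("malformed edge line %d: non-numeric score '%s'",
                   i, fields[3]))
    }
    # STRING exports sometimes carry scores on the 0-1 scale
    if (s <= 1 && s != round(s)) s <- s * 1000
    p1 <- c(p1, fields[1]); p2 <- c(p2, fields[2]); sc <- c(sc, as.integer(round(s)))
  }
  keep_e <- sc >= score_threshold
  interaction_network(
    data.frame(protein1 = p1[keep_e], protein2 = p2[keep_e],
               score = sc[keep_e]),
    seed_nodes = seed_nodes)
}

#' Write / read a network in SIF format
#'
#' `write_sif()` emits one `A pp B` line per edge in deterministic
#' lexicographic order; `read_sif()` reads it back (scores are not carried
#' by SIF and default to 1000).
#'
#' @param net an [interaction_network].
#' @param path output (or input) file path.
#' @return `write_sif()` returns `path` invisibly; `read_sif()` an
#'   [interaction_network].
#' @export
write_sif <- function(net, path) {
  e <- network_edges(net)
  writeLines(if (nrow(e)) paste(e$protein1, "pp", e$protein2) else character(0),
             path)
  invisible(path)
}

#' @rdname write_sif
#' @param seed_nodes passed through to [interaction_network()].
#' @export
read_sif <- function(path, seed_nodes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(interaction_network(seed_nodes = seed_nodes))
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop(sprintf("malformed SIF line %d", bad[1]))
  interaction_network(
    data.frame(protein1 = vapply(fields, `[`, "", 1),
               protein2 = vapply(fields, `[`, "", 3)),
    seed_nodes = seed_nodes)
}

#' Read / write gene-set annotations in GMT format
#'
#' Each GMT line is `term_id TAB description TAB gene1 TAB gene2 ...`.
#' Duplicate genes within a line are stored once.
#'
#' @param path file path.
#' @param universe optional explicit gene universe; defaults to the union of
#'   all member genes.
#' @return `read_gmt()` returns an [annotation_set]; `write_gmt()` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  terms <- list(); term_names <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", i))
    }
    terms[[fields[1]]] <- unique(fields[-(1:2)])
    term_names[fields[1]] <- fields[2]
  }
  annotation_set(terms, term_names = term_names, universe = universe)
}

#' @rdname read_gmt
#' @param annotation an [annotation_set].
#' @export
write_gmt <- function(annotation, path) {
  stopifnot(inherits(annotation, "annotation_set"))
  ids <- names(annotation$terms)
  writeLines(vapply(ids, function(id) {
    paste(c(id, annotation$term_names[[id]], annotation$terms[[id]]),
          collapse = "\t")
  }, ""), path)
  invisible(path)
}

metrics_cols <- c("name", "bottleneck", "betweenness", "closeness",
                  "clustering_coefficient", "degree")

#' Write / read a node-metrics table as CSV
#'
#' The column layout mirrors the cytoHubba-style candidate table:
#' `name,bottleneck,betweenness,closeness,clustering_coefficient,degree`.
#' Floats are written at full precision so a round trip is lossless.
#'
#' @param metrics a data frame with (at least) the columns above, as
#'   produced by [node_metrics()].
#' @param path file path.
#' @return `write_metrics_csv()` returns `path` invisibly;
#'   `read_metrics_csv()` the data frame.
#' @export
write_metrics_csv <- function(metrics, path) {
  stopifnot(is.data.frame(metrics), all(metrics_cols %in% names(metrics)))
  out <- metrics[, metrics_cols, drop = FALSE]
  for (col in c("betweenness", "closeness", "clustering_coefficient")) {
    out[[col]] <- format(out[[col]], digits = 17, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(name = "character"))
  if (!all(metrics_cols %in% names(df))) {
    stop("metrics CSV is missing required columns")
  }
  df
}
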