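#' Construct a protein interaction network
#'
#' An `interaction_network` is an undirected simple graph of proteins with an
#' optional seed/connector role per node and an integer STRING-style
#' confidence score (0--1000) per edge. Self-loops are removed and duplicate
#' unordered pairs are collapsed (keeping the maximum score).
#'
#' @param edges a data frame with columns `protein1`, `protein2` and
#'   optionally `score` (integer in \[0, 1000\]; missing scores default to
#'   1000). May have zero rows.
#' @param seed_nodes character vector of node names to label with role
#'   `"seed"`; all remaining nodes are labelled `"connector"`. `NULL` labels
#'   every node `"seed"`.
#' @param nodes optional character vector of additional (possibly isolated)
#'   node names to include.
#' @return An object of class `interaction_network`.
#' @examples
#' net <- interaction_network(data.frame(protein1 = c("A", "B"),
#'                                       protein2 = c("B", "C"),
#'                                       score = c(950L, 800L)))
#' network_size(net)
#' @export
interaction_network <- function(edges = NULL, seed_nodes = NULL, nodes = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(protein1 = character(), protein2 = character(),
                        score = integer())
  }
  stopifnot(is.data.frame(edges))
  if (!all(c("protein1", "protein2") %in% names(edges))) {
    stop("`edges` must have columns 'protein1' and 'protein2'")
  }
  p1 <- as.character(edges$protein1)
  p2 <- as.character(edges$protein2)
  score <- if ("score" %in% names(edges)) as.integer(round(edges$score)) else
    rep(1000L, length(p1))
  score[is.na(score)] <- 1000L
  if (any(score < 0L | score > 1000L)) {
    stop("edge scores must lie in [0, 1000]")
  }
  keep <- p1 != p2
  p1 <- p1[keep]; p2 <- p2[keep]; score <- score[keep]
  # canonical unordered orientation, then dedupe keeping the max score
  swap <- p1 > p2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  if (length(p1)) {
    key <- paste(p1, p2, sep = "\r")
    ord <- order(key, -score)
    first <- !duplicated(key[ord])
    idx <- ord[first]
    p1 <- p1[idx]; p2 <- p2[idx]; score <- score[idx]
  }
  all_nodes <- sort(unique(c(p1, p2, as.character(nodes))))
  g <- igraph::make_empty_graph(n = length(all_nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = all_nodes)
  if (length(p1)) {
    g <- igraph::add_edges(g, rbind(p1, p2))
    g <- igraph::set_edge_attr(g, "score", value = score)
  }
  role <- if (is.null(seed_nodes)) rep("seed", length(all_nodes)) else
    ifelse(all_nodes %in% as.character(seed_nodes), "seed", "connector")
  g <- igraph::set_vertex_attr(g, "role", value = role)
  structure(list(graph = g), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  roles <- table(igraph::V(g)$role)
  cat(sprintf("interaction_network: %d nodes (%s), %d edges\n",
              igraph::vcount(g),
              paste(sprintf("%d %s", roles, names(roles)), collapse = ", "),
              igraph::ecount(g)))
  invisible(x)
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  net$graph
}

#' Nodes, edges and size of an interaction network
#'
#' @param net an `interaction_network`.
#' @return `network_nodes()` returns a character vector of node names
#'   (sorted); `network_edges()` a data frame with columns `protein1`,
#'   `protein2`, `score` in canonical (lexicographic) order;
#'   `network_size()` a named vector with `nodes` and `edges` counts;
#'   `node_roles()` a named character vector of `"seed"`/`"connector"`.
#' @export
network_nodes <- function(net) {
  sort(igraph::V(as_igraph(net))$name)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    return(data.frame(protein1 = character(), protein2 = character(),
                      score = integer()))
  }
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  out <- data.frame(protein1 = el[, 1], protein2 = el[, 2],
                    score = igraph::E(g)$score)
  out <- out[order(out$protein1, out$protein2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname network_nodes
#' @export
network_size <- function(net) {
  g <- as_igraph(net)
  c(nodes = igraph::vcount(g), edges = igraph::ecount(g))
}

#' @rdname network_nodes
#' @export
node_roles <- function(net) {
  g <- as_igraph(net)
  stats::setNames(igraph::V(g)$role, igraph::V(g)$name)[network_nodes(net)]
}

#' Construct an annotation set
#'
#' An `annotation_set` maps term identifiers to gene sets over a gene
#' universe, the container consumed by hypergeometric enrichment.
#'
#' @param terms a named list of character vectors (term id -> member genes);
#'   duplicates within a term are dropped. Empty terms are an error.
#' @param term_names optional named character vector of human-readable term
#'   names (defaults to the term ids).
#' @param universe optional character vector; defaults to the union of all
#'   member genes.
#' @return An object of class `annotation_set` with elements `universe`,
#'   `terms`, `term_names`.
#' @export
annotation_set <- function(terms, term_names = NULL, universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)), all(nzchar(names(terms))))
  terms <- lapply(terms, function(g) sort(unique(as.character(g))))
  if (any(lengths(terms) == 0L)) stop("annotation terms must be non-empty")
  members <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(universe)) {
    universe <- members
  } else {
    universe <- sort(unique(as.character(universe)))
    if (!all(members %in% universe)) {
      stop("every term member must belong to the universe")
    }
  }
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  } else {
    term_names <- stats::setNames(as.character(term_names)[match(names(terms), names(term_names))],
                                  names(terms))
    term_names[is.na(term_names)] <- names(terms)[is.na(term_names)]
  }
  structure(list(universe = universe, terms = terms, term_names = term_names),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d terms over a universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}
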