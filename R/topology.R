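#' Degree histogram of a network
#'
#' @param net an [interaction_network] with at least one node.
#' @return A data frame with columns `k` (degree, >= 1, ascending) and
#'   `count` (number of nodes of that degree). Isolated nodes (k = 0) are
#'   excluded, matching the log-log power-law fit domain.
#' @export
degree_histogram <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) stop("degree_histogram: empty network")
  deg <- igraph::degree(g)
  deg <- deg[deg >= 1]
  tab <- table(deg)
  data.frame(k = as.integer(names(tab)), count = as.integer(tab))
}

#' Fit a power law to a degree distribution
#'
#' Ordinary least squares of `log10(count)` on `log10(k)`:
#' `count = a * k^b` with `a = 10^intercept`, `b` the slope, and `r_squared`
#' computed on the log-log scale. This is the Network Analyzer convention;
#' `k = 0` and zero-count bins must be excluded beforehand (as
#' [degree_histogram()] does).
#'
#' @param points a data frame with columns `k` (>= 1) and `count` (> 0), at
#'   least two distinct `k`.
#' @return A list of class `power_law_fit` with `coefficient_a`,
#'   `exponent_b`, `r_squared`, `points_used`.
#' @examples
#' pts <- data.frame(k = 1:20, count = 258.52 * (1:20)^-1.171)
#' fit_power_law(pts)
#' @export
fit_power_law <- function(points) {
  stopifnot(is.data.frame(points), all(c("k", "count") %in% names(points)))
  k <- points$k; n <- points$count
  if (any(k < 1) || any(n <= 0)) {
    stop("fit_power_law: requires k >= 1 and count > 0")
  }
  if (length(unique(k)) < 2) stop("fit_power_law: need >= 2 distinct k")
  fit <- stats::lm(log10(n) ~ log10(k))
  y <- log10(n)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum(stats::residuals(fit)^2)
  # noiseless data (zero total variance) is a perfect fit by convention
  r2 <- if (ss_tot <= .Machine$double.eps * length(y)) 1 else
    max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(coefficient_a = 10^unname(stats::coef(fit)[1]),
                 exponent_b = unname(stats::coef(fit)[2]),
                 r_squared = r2,
                 points_used = length(k)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power law fit: count = %.4g * k^(%.4g), R^2 = %.4g (%d points)\n",
              x$coefficient_a, x$exponent_b, x$r_squared, x$points_used))
  invisible(x)
}

#' Local and average clustering coefficients
#'
#' `C(v) = 2 * (edges among neighbours of v) / (deg(v) * (deg(v) - 1))`,
#' with `C(v) = 0` for degree < 2. The network average is the mean over all
#' nodes (isolates contribute 0).
#'
#' @param net an [interaction_network].
#' @param v optional node name(s); default all nodes.
#' @return A named numeric vector (or a single number for
#'   `average_clustering`).
#' @export
clustering_coefficient <- function(net, v = NULL) {
  g <- as_igraph(net)
  vids <- if (is.null(v)) igraph::V(g) else {
    missing <- setdiff(v, igraph::V(g)$name)
    if (length(missing)) stop("unknown node(s): ", paste(missing, collapse = ", "))
    igraph::V(g)[v]
  }
  cc <- igraph::transitivity(g, type = "localundirected", vids = vids,
                             isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name[as.integer(vids)])
}

#' @rdname clustering_coefficient
#' @export
average_clustering <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) return(NaN)
  mean(clustering_coefficient(net))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all unordered connected node pairs;
#' unreachable pairs are excluded from both numerator and denominator.
#'
#' @param net an [interaction_network] with at least one connected pair.
#' @return A positive number.
#' @export
characteristic_path_length <- function(net) {
  g <- as_igraph(net)
  d <- igraph::distances(g, weights = NA)
  vals <- d[upper.tri(d)]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("characteristic_path_length: no connected pair")
  mean(vals)
}

#' Betweenness centrality
#'
#' Unnormalized shortest-path betweenness on the unweighted undirected
#' graph: each unordered source--target pair counted once, endpoints
#' excluded, fractional credit shared over tied shortest paths (Brandes).
#'
#' @param net an [interaction_network].
#' @return A named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(net) {
  g <- as_igraph(net)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(g)$name)
}

#' Harmonic closeness centrality
#'
#' `Clo(v) = sum over reachable u != v of 1/d(v, u)`; unreachable nodes
#' contribute 0, so the score is well defined on disconnected graphs.
#'
#' @param net an [interaction_network].
#' @return A named numeric vector over all nodes.
#' @export
harmonic_closeness <- function(net) {
  g <- as_igraph(net)
  h <- igraph::harmonic_centrality(g, weights = NA, normalized = FALSE)
  stats::setNames(as.numeric(h), igraph::V(g)$name)
}

#' BottleNeck scores
#'
#' The cytoHubba BottleNeck centrality. For every root `s`, a BFS
#' shortest-path tree is grown with lexicographic parent tie-breaking; for a
#' non-root node `v` of that tree, `p_s(v)` is the number of tree nodes
#' whose root-path contains `v` (counting `v` itself, i.e. the size of the
#' subtree rooted at `v`). `v` scores one point for `s` iff
#' `p_s(v) > |V(T_s)| / 4` (strict). The BottleNeck score of `v` is its
#' total over all roots. High scorers sit on the trunk of many trees --
#' bridge-like proteins through which much of the network's shortest-path
#' traffic funnels.
#'
#' @param net an [interaction_network].
#' @return A named integer vector over all nodes.
#' @export
bottleneck_scores <- function(net) {
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  nv <- length(nodes)
  score <- stats::setNames(integer(nv), nodes)
  if (nv == 0) return(score)
  ord <- order(nodes)  # lexicographic index order for tie-breaking
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(a) {
    ix <- as.integer(a)
    ix[order(nodes[ix])]  # neighbours in lexicographic name order
  })
  d <- igraph::distances(g, weights = NA)
  for (s in seq_len(nv)) {
    ds <- d[s, ]
    tree <- which(is.finite(ds))
    ntree <- length(tree)
    if (ntree <= 1) next
    # parent = lexicographically smallest neighbour one step closer to root
    parent <- integer(nv)
    for (v in tree) {
      if (v == s) next
      nb <- adj[[v]]
      parent[v] <- nb[ds[nb] == ds[v] - 1][1]
    }
    # subtree sizes: accumulate from the deepest nodes upwards
    size <- integer(nv)
    size[tree] <- 1L
    for (v in tree[order(ds[tree], decreasing = TRUE)]) {
      if (v != s) size[parent[v]] <- size[parent[v]] + size[v]
    }
    hit <- tree[tree != s & size[tree] > ntree / 4]
    score[hit] <- score[hit] + 1L
  }
  score[order(names(score))]
}

#' Full per-node topology table
#'
#' Computes all per-node statistics in one pass and returns the
#' candidate-table layout used downstream by the prioritization cascade.
#'
#' @param net an [interaction_network].
#' @return A data frame with columns `name`, `bottleneck`, `betweenness`,
#'   `closeness` (harmonic), `clustering_coefficient`, `degree`, `role`,
#'   sorted by descending bottleneck then name.
#' @export
node_metrics <- function(net) {
  g <- as_igraph(net)
  nm <- network_nodes(net)
  out <- data.frame(
    name = nm,
    bottleneck = as.integer(bottleneck_scores(net)[nm]),
    betweenness = betweenness_centrality(net)[nm],
    closeness = harmonic_closeness(net)[nm],
    clustering_coefficient = clustering_coefficient(net)[nm],
    degree = as.integer(igraph::degree(g)[nm]),
    role = unname(node_roles(net)[nm]))
  out <- out[order(-out$bottleneck, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Whole-network summary statistics
#'
#' @param net a non-empty [interaction_network].
#' @return A list of class `network_summary` with `n_nodes`, `n_edges`,
#'   `average_degree` (= 2E/N), `average_clustering`, and
#'   `characteristic_path_length` (NA when no pair is connected).
#' @export
summarize_network <- function(net) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0) stop("summarize_network: empty network")
  cpl <- tryCatch(characteristic_path_length(net), error = function(e) NA_real_)
  structure(list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    average_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    average_clustering = average_clustering(net),
    characteristic_path_length = cpl), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("network summary: %d nodes, %d edges\n",
                     "  average degree            %.4g\n",
                     "  average clustering        %.4g\n",
                     "  characteristic path length %.4g\n"),
              x$n_nodes, x$n_edges, x$average_degree, x$average_clustering,
              x$characteristic_path_length))
  invisible(x)
}
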