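#' MCODE parameters
#'
#' Defaults reproduce the documented defaults of the Cytoscape MCODE plugin.
#'
#' @param degree_cutoff minimum degree for a vertex to receive a non-trivial
#'   weight neighbourhood (>= 2).
#' @param node_score_cutoff fraction in \[0, 1\]: a neighbour joins a complex
#'   when its weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core_filter complexes whose induced subgraph has no k-core at
#'   this k are discarded.
#' @param max_depth BFS expansion depth limit from the seed.
#' @param haircut iteratively remove members with fewer than 2 connections
#'   inside the complex.
#' @param fluff add neighbours whose neighbourhood density exceeds
#'   `fluff_density_cutoff` after the core complex is formed.
#' @param fluff_density_cutoff density threshold for fluffing.
#' @return A list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core_filter = 2, max_depth = 100,
                         haircut = TRUE, fluff = FALSE,
                         fluff_density_cutoff = 0.1) {
  stopifnot(degree_cutoff >= 2, node_score_cutoff >= 0, node_score_cutoff <= 1,
            max_depth >= 1)
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff,
                 k_core_filter = k_core_filter, max_depth = max_depth,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff),
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "mcode_params")
}

graph_density_simple <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' The core-clustering coefficient: take the subgraph `G_v` induced by `v`
#' and its neighbours, find its highest k-core, and return
#' `k_max * density(highest k-core)`. Isolated vertices weigh 0.
#'
#' @param net an [interaction_network].
#' @param v a node name, or `NULL` for all nodes.
#' @return A named numeric vector of weights.
#' @export
vertex_weight <- function(net, v = NULL) {
  g <- as_igraph(net)
  names_all <- igraph::V(g)$name
  vs <- if (is.null(v)) names_all else {
    missing <- setdiff(v, names_all)
    if (length(missing)) stop("unknown node(s): ", paste(missing, collapse = ", "))
    v
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  names(adj) <- names_all
  w <- vapply(vs, function(nm) {
    nb <- as.integer(adj[[nm]])
    if (!length(nb)) return(0)
    sub <- igraph::induced_subgraph(g, c(match(nm, names_all), nb))
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= kmax))
    kmax * graph_density_simple(core_sub)
  }, numeric(1))
  stats::setNames(w, vs)
}

#' Score of a candidate module
#'
#' `density * size`, where density is `2E/(n(n-1))` of the induced
#' subgraph. A tighter, larger complex scores higher.
#'
#' @param net an [interaction_network].
#' @param members character vector of member node names, length >= 2.
#' @return A single number.
#' @export
module_score <- function(net, members) {
  g <- as_igraph(net)
  members <- unique(as.character(members))
  if (length(members) < 2) stop("module_score: need >= 2 members")
  missing <- setdiff(members, igraph::V(g)$name)
  if (length(missing)) stop("unknown node(s): ", paste(missing, collapse = ", "))
  sub <- igraph::induced_subgraph(g, members)
  graph_density_simple(sub) * length(members)
}

mcode_haircut <- function(g, members) {
  repeat {
    sub <- igraph::induced_subgraph(g, members)
    deg <- igraph::degree(sub)
    drop <- igraph::V(sub)$name[deg < 2]
    if (!length(drop) || length(members) <= length(drop)) {
      if (length(drop)) members <- setdiff(members, drop)
      break
    }
    members <- setdiff(members, drop)
  }
  members
}

#' Detect dense modules with MCODE
#'
#' From-scratch MCODE: vertices are weighted by [vertex_weight()], complexes
#' are grown breadth-first from the highest-weight unvisited seed, including
#' unvisited neighbours whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)` (inclusive), down to `max_depth`
#' levels. Haircut trims members with fewer than two intra-module links;
#' optional fluff adds dense-neighbourhood boundary nodes. Complexes without
#' a k-core at `k_core_filter` are discarded. All tie-breaks are
#' lexicographic, so results are deterministic.
#'
#' @param net an [interaction_network].
#' @param params an [mcode_params()] list.
#' @return A list of modules sorted by descending score (ties by seed
#'   name); each module is a list with `members` (sorted), `seed_vertex`,
#'   `density`, `score`. May be empty.
#' @export
find_modules <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  g <- as_igraph(net)
  nodes <- igraph::V(g)$name
  if (!length(nodes)) return(list())
  w <- vertex_weight(net)
  adj <- igraph::as_adj_list(g, mode = "all")
  names(adj) <- nodes
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  seed_order <- nodes[order(-w[nodes], nodes)]
  modules <- list()
  for (seed in seed_order) {
    if (visited[seed]) next
    visited[seed] <- TRUE
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < params$max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        nb <- nodes[as.integer(adj[[u]])]
        ok <- nb[!visited[nb] & w[nb] >= threshold]
        if (length(ok)) {
          visited[ok] <- TRUE
          nxt <- c(nxt, ok)
        }
      }
      members <- c(members, nxt)
      frontier <- sort(nxt)
      depth <- depth + 1
    }
    if (params$haircut) members <- mcode_haircut(g, members)
    if (length(members) < 2) next
    if (params$fluff) {
      extra <- character(0)
      for (u in sort(members)) {
        nb <- setdiff(nodes[as.integer(adj[[u]])], c(members, extra))
        for (cand in nb) {
          nbh <- c(cand, nodes[as.integer(adj[[cand]])])
          dens <- graph_density_simple(igraph::induced_subgraph(g, unique(nbh)))
          if (dens > params$fluff_density_cutoff) extra <- c(extra, cand)
        }
      }
      members <- c(members, extra)
    }
    sub <- igraph::induced_subgraph(g, members)
    if (params$k_core_filter >= 1 &&
        max(igraph::coreness(sub)) < params$k_core_filter) next
    modules[[length(modules) + 1]] <- list(
      members = sort(unique(members)),
      seed_vertex = seed,
      density = graph_density_simple(sub),
      score = graph_density_simple(sub) * length(unique(members)))
  }
  if (!length(modules)) return(modules)
  ord <- order(-vapply(modules, `[[`, 0, "score"),
               vapply(modules, `[[`, "", "seed_vertex"))
  modules[ord]
}

#' Write modules to a TSV table
#'
#' One row per module: `rank`, `score`, `density`, `size`, `members`
#' (semicolon-joined, sorted).
#'
#' @param modules as returned by [find_modules()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- data.frame(
    rank = seq_along(modules),
    score = vapply(modules, `[[`, 0, "score"),
    density = vapply(modules, `[[`, 0, "density"),
    size = vapply(modules, function(m) length(m$members), 0L),
    members = vapply(modules, function(m) paste(m$members, collapse = ";"), ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
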