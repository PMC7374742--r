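# Brute-force reference implementations, written independently of the
# package's code paths, for exact agreement checks on small graphs.

make_net <- function(edges, nodes = NULL) {
  interaction_network(
    data.frame(protein1 = edges[c(TRUE, FALSE)],
               protein2 = edges[c(FALSE, TRUE)]),
    nodes = nodes)
}

oracle_adj <- function(net) {
  e <- network_edges(net)
  nodes <- network_nodes(net)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(e))) {
    adj[[e$protein1[i]]] <- c(adj[[e$protein1[i]]], e$protein2[i])
    adj[[e$protein2[i]]] <- c(adj[[e$protein2[i]]], e$protein1[i])
  }
  lapply(adj, function(x) sort(unique(x)))
}

# hand-rolled BFS distances from one source (named vector, Inf unreachable)
oracle_bfs <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  queue <- src
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) if (!is.finite(d[v])) {
      d[v] <- d[u] + 1
      queue <- c(queue, v)
    }
  }
  d
}

oracle_harmonic_closeness <- function(net) {
  adj <- oracle_adj(net)
  vapply(names(adj), function(v) {
    d <- oracle_bfs(adj, v)
    d <- d[names(d) != v & is.finite(d)]
    sum(1 / d)
  }, numeric(1))
}

oracle_path_length <- function(net) {
  # Floyd-Warshall all-pairs
  nodes <- network_nodes(net)
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  e <- network_edges(net)
  for (i in seq_len(nrow(e))) {
    d[e$protein1[i], e$protein2[i]] <- 1
    d[e$protein2[i], e$protein1[i]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

# enumerate all shortest paths between a pair by depth-first walking of the
# BFS distance field; returns a list of node-name vectors
oracle_all_shortest_paths <- function(adj, s, t) {
  d <- oracle_bfs(adj, s)
  if (!is.finite(d[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][d[adj[[v]]] == d[v] - 1]
    out <- list()
    for (p in preds) for (path in walk(p)) {
      out[[length(out) + 1]] <- c(path, v)
    }
    out
  }
  walk(t)
}

oracle_betweenness <- function(net) {
  adj <- oracle_adj(net)
  nodes <- names(adj)
  b <- stats::setNames(rep(0, length(nodes)), nodes)
  n <- length(nodes)
  if (n < 3) return(b)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    paths <- oracle_all_shortest_paths(adj, nodes[i], nodes[j])
    if (!length(paths)) next
    for (path in paths) {
      inner <- setdiff(path, c(nodes[i], nodes[j]))
      b[inner] <- b[inner] + 1 / length(paths)
    }
  }
  b
}

oracle_clustering <- function(net) {
  adj <- oracle_adj(net)
  vapply(names(adj), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
}

# independent bottleneck scorer: same pinned tree rule, but p_s(v) counted
# by walking every tree node's root-path through its parents
oracle_bottleneck <- function(net) {
  adj <- oracle_adj(net)
  nodes <- names(adj)
  score <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (s in nodes) {
    d <- oracle_bfs(adj, s)
    tree <- names(d)[is.finite(d)]
    if (length(tree) <= 1) next
    parent <- character(0)
    for (v in tree) {
      if (v == s) next
      cands <- adj[[v]][d[adj[[v]]] == d[v] - 1]
      parent[v] <- sort(cands)[1]
    }
    onpath <- stats::setNames(rep(0L, length(tree)), tree)
    for (t in tree) {
      v <- t
      repeat {
        onpath[v] <- onpath[v] + 1L
        if (v == s) break
        v <- parent[v]
      }
    }
    hit <- setdiff(tree[onpath > length(tree) / 4], s)
    score[hit] <- score[hit] + 1L
  }
  score
}

# exact hypergeometric tail probabilities by pmf enumeration
oracle_hyper_two_sided <- function(k, K, n, N) {
  i <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  p_over <- sum(pmf[i >= k])
  p_under <- sum(pmf[i <= k])
  min(1, 2 * min(p_over, p_under))
}

oracle_kappa <- function(A, B, U) {
  ina <- U %in% A
  inb <- U %in% B
  N <- length(U)
  po <- mean(ina == inb)
  pe <- mean(ina) * mean(inb) + mean(!ina) * mean(!inb)
  if (pe >= 1) return(if (setequal(A, B)) 1 else 0)
  (po - pe) / (1 - pe)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
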