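# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

node_names <- function(n, prefix = "P") {
  sprintf("%s%0*d", prefix, max(4, nchar(n)), seq_len(n))
}

#' Scale-free graph by preferential attachment
#'
#' Barabasi-Albert-style growth pinned for determinism: start from a star
#' of `m + 1` nodes, then attach each arriving node to `m` distinct
#' existing nodes sampled without replacement with probability proportional
#' to degree. No multi-edges, so the edge count is exactly `(n - m) * m`.
#'
#' @param n number of nodes (> m).
#' @param m edges added per arriving node (>= 1).
#' @param seed RNG seed; identical seeds give identical graphs.
#' @return An [interaction_network].
#' @export
scale_free_graph <- function(n, m, seed) {
  if (!(m >= 1 && m < n)) stop("scale_free_graph: need 1 <= m < n")
  with_seed(seed, {
    nm <- node_names(n)
    deg <- integer(n)
    e1 <- integer(0); e2 <- integer(0)
    # initial star: node 1 is the hub of nodes 2..m+1
    for (j in seq_len(m) + 1L) { e1 <- c(e1, 1L); e2 <- c(e2, j) }
    deg[1] <- m; deg[2:(m + 1)] <- 1L
    if (n > m + 1) for (v in (m + 2L):n) {
      existing <- seq_len(v - 1L)
      targets <- sample(existing, m, replace = FALSE, prob = deg[existing])
      e1 <- c(e1, rep(v, m)); e2 <- c(e2, targets)
      deg[targets] <- deg[targets] + 1L
      deg[v] <- m
    }
    interaction_network(data.frame(protein1 = nm[e1], protein2 = nm[e2],
                                   score = 1000L))
  })
}

#' Erdos-Renyi random graph
#'
#' Each unordered node pair is an edge independently with probability `p`.
#'
#' @param n number of nodes.
#' @param p edge probability in \[0, 1\].
#' @param seed RNG seed.
#' @return An [interaction_network] (isolated nodes are kept).
#' @export
random_graph <- function(n, p, seed) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  with_seed(seed, {
    nm <- node_names(n)
    if (n < 2 || p == 0) return(interaction_network(nodes = nm))
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    interaction_network(data.frame(protein1 = nm[pairs[1, keep]],
                                   protein2 = nm[pairs[2, keep]],
                                   score = 1000L),
                        nodes = nm)
  })
}

#' Random graph with planted cliques
#'
#' Disjoint cliques are wired into an Erdos-Renyi background by one random
#' bridge edge each, giving a test bed with known dense modules. Total edge
#' count is `|ER edges| + sum(choose(s, 2)) + #cliques`.
#'
#' @param background_n,background_p ER background size and density.
#' @param clique_sizes integer vector of planted clique sizes (each >= 3).
#' @param seed RNG seed.
#' @return A list with `network` and `planted` (list of member-name sets).
#' @export
planted_modules_graph <- function(background_n, background_p, clique_sizes,
                                  seed) {
  stopifnot(all(clique_sizes >= 3), background_n >= 1)
  with_seed(seed, {
    bg <- node_names(background_n, "B")
    edges <- if (background_n >= 2) {
      pairs <- utils::combn(background_n, 2)
      keep <- stats::runif(ncol(pairs)) < background_p
      data.frame(protein1 = bg[pairs[1, keep]], protein2 = bg[pairs[2, keep]])
    } else data.frame(protein1 = character(), protein2 = character())
    planted <- list()
    for (i in seq_along(clique_sizes)) {
      s <- clique_sizes[i]
      members <- sprintf("M%d_%0*d", i, max(2, nchar(s)), seq_len(s))
      planted[[i]] <- members
      pairs <- utils::combn(s, 2)
      edges <- rbind(edges,
                     data.frame(protein1 = members[pairs[1, ]],
                                protein2 = members[pairs[2, ]]),
                     data.frame(protein1 = sample(members, 1),
                                protein2 = sample(bg, 1)))
    }
    edges$score <- 1000L
    list(network = interaction_network(edges, nodes = bg), planted = planted)
  })
}

#' Annotation universe with one planted enriched term
#'
#' Builds `n_terms` gene sets over a universe; one designated term receives
#' `planted_overlap` members of the query, the rest of the universe and
#' terms are filled uniformly at random. Defaults give a clearly enriched
#' planted term under a Bonferroni-corrected two-sided hypergeometric test.
#'
#' @param universe_n universe size (default 1000).
#' @param n_terms number of terms (default 50).
#' @param term_size genes per term (default 40).
#' @param planted_overlap query genes placed in the planted term
#'   (default 20).
#' @param query_size total query size (default 25).
#' @param seed RNG seed.
#' @return A list with `annotation` (an [annotation_set]), `query`
#'   (character vector) and `planted_term` (its term id).
#' @export
annotation_with_planted_term <- function(universe_n = 1000, n_terms = 50,
                                         term_size = 40, planted_overlap = 20,
                                         query_size = 25, seed = 1) {
  stopifnot(planted_overlap <= min(term_size, query_size),
            term_size <= universe_n, query_size <= universe_n)
  with_seed(seed, {
    genes <- node_names(universe_n, "g")
    query <- sample(genes, query_size)
    planted_id <- "T001"
    planted <- c(query[seq_len(planted_overlap)],
                 sample(setdiff(genes, query), term_size - planted_overlap))
    terms <- list()
    terms[[planted_id]] <- planted
    if (n_terms > 1) for (i in 2:n_terms) {
      terms[[sprintf("T%03d", i)]] <- sample(genes, term_size)
    }
    list(annotation = annotation_set(terms, universe = genes),
         query = query, planted_term = planted_id)
  })
}

#' Toy three-tier mass-action cascade
#'
#' A small activation cascade with closed-form-checkable pieces and
#' documented conserved moieties, for exercising the ODE machinery:
#' tier 1 is the reversible activation `A <-> A_P` (kf = 0.1/s,
#' kr = 0.05/s); the active form catalyses tier 2
#' (`B + A_P -> B_P + A_P`, k = 1/(uM s); `B_P -> B`, k = 0.2/s) and B_P in
#' turn catalyses tier 3 with the same constants. Conserved moieties:
#' `A + A_P`, `B + B_P`, `C + C_P`, each totalling 1 uM.
#'
#' @return A [kinetic_model].
#' @export
toy_cascade_model <- function() {
  kinetic_model(
    species = c(A = 1, A_P = 0, B = 1, B_P = 0, C = 1, C_P = 0),
    reactions = list(
      list(id = "act_A", reactants = c(A = 1), products = c(A_P = 1),
           rate = 0.1, reverse_rate = 0.05),
      list(id = "act_B", reactants = c(B = 1, A_P = 1),
           products = c(B_P = 1, A_P = 1), rate = 1),
      list(id = "deact_B", reactants = c(B_P = 1), products = c(B = 1),
           rate = 0.2),
      list(id = "act_C", reactants = c(C = 1, B_P = 1),
           products = c(C_P = 1, B_P = 1), rate = 1),
      list(id = "deact_C", reactants = c(C_P = 1), products = c(C = 1),
           rate = 0.2)))
}
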