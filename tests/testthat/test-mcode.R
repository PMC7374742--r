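k_clique <- function(prefix, k) {
  pr <- utils::combn(k, 2)
  data.frame(protein1 = sprintf("%s%d", prefix, pr[1, ]),
             protein2 = sprintf("%s%d", prefix, pr[2, ]))
}

# independent peel-and-score weight: peel minimum-degree vertices to find
# the highest k-core of the closed neighbourhood, then k * density
oracle_vertex_weight <- function(net, v) {
  e <- network_edges(net)
  nb <- unique(c(e$protein2[e$protein1 == v], e$protein1[e$protein2 == v]))
  if (!length(nb)) return(0)
  members <- c(v, nb)
  sub <- e[e$protein1 %in% members & e$protein2 %in% members, ]
  best_k <- 0; best_dens <- 0
  for (k in 1:(length(members) - 1)) {
    mem <- members; se <- sub
    repeat {
      deg <- table(factor(c(se$protein1, se$protein2), levels = mem))
      drop <- names(deg)[deg < k]
      if (!length(drop) || !length(mem)) break
      mem <- setdiff(mem, drop)
      se <- se[se$protein1 %in% mem & se$protein2 %in% mem, ]
    }
    if (length(mem) > 1) {
      best_k <- k
      best_dens <- 2 * nrow(se) / (length(mem) * (length(mem) - 1))
    }
  }
  best_k * best_dens
}

test_that("vertex weight is k-core order times core density", {
  k4 <- interaction_network(k_clique("K", 4))
  expect_equal(unname(vertex_weight(k4, "K1")), 3)

  edge <- make_net(c("A", "B"))
  expect_equal(unname(vertex_weight(edge, "A")), 1)

  iso <- interaction_network(nodes = "X")
  expect_equal(unname(vertex_weight(iso, "X")), 0)

  g <- random_graph(25, 0.25, seed = 17)
  w <- vertex_weight(g)
  for (v in network_nodes(g)) {
    expect_equal(unname(w[v]), oracle_vertex_weight(g, v))
  }
})

test_that("module score is density times size", {
  k5 <- interaction_network(k_clique("K", 5))
  expect_equal(module_score(k5, sprintf("K%d", 1:5)), 5)

  cyc4 <- make_net(c("A", "B", "B", "C", "C", "D", "D", "A"))
  expect_equal(module_score(cyc4, c("A", "B", "C", "D")), 8 / 3)

  expect_error(module_score(k5, "K1"), "2 members")

  g <- random_graph(20, 0.4, seed = 2)
  members <- network_nodes(g)[1:8]
  e <- network_edges(g)
  inside <- sum(e$protein1 %in% members & e$protein2 %in% members)
  expect_equal(module_score(g, members), 2 * inside / (8 * 7) * 8)
})

test_that("disjoint cliques are each recovered as one module", {
  net <- interaction_network(rbind(k_clique("A", 5), k_clique("B", 5)),
                             nodes = sprintf("I%02d", 1:10))
  mods <- find_modules(net)
  expect_length(mods, 2)
  for (m in mods) {
    expect_equal(m$score, 5)
    expect_equal(m$density, 1)
    expect_length(m$members, 5)
  }
  expect_setequal(c(mods[[1]]$members, mods[[2]]$members),
                  c(sprintf("A%d", 1:5), sprintf("B%d", 1:5)))
})

test_that("trees yield no modules (haircut and 2-core filter)", {
  tree <- scale_free_graph(30, 1, seed = 3)
  expect_length(find_modules(tree), 0)
})

test_that("planted cliques are recovered from a sparse background", {
  pg <- planted_modules_graph(60, 0.03, c(6, 4), seed = 3)
  mods <- find_modules(pg$network)
  expect_gte(length(mods), 1)
  expect_gte(jaccard(mods[[1]]$members, pg$planted[[1]]), 0.8)
})

test_that("returned modules are connected, contain a 2-core, and are disjoint", {
  pg <- planted_modules_graph(80, 0.06, c(6, 5, 4), seed = 9)
  mods <- find_modules(pg$network)
  expect_gte(length(mods), 1)
  all_members <- unlist(lapply(mods, `[[`, "members"))
  expect_equal(anyDuplicated(all_members), 0)
  e <- network_edges(pg$network)
  for (m in mods) {
    sub <- e[e$protein1 %in% m$members & e$protein2 %in% m$members, ]
    subnet <- interaction_network(sub)
    expect_setequal(network_nodes(subnet), m$members)  # no isolated member
    expect_equal(characteristic_path_length(subnet) > 0, TRUE)
    deg <- table(c(sub$protein1, sub$protein2))
    expect_true(all(deg >= 2))  # haircut held
    expect_equal(m$score, module_score(pg$network, m$members))
  }
})

test_that("loosening the node-score cutoff only grows the top complex", {
  pg <- planted_modules_graph(50, 0.08, c(5), seed = 12)
  params_tight <- mcode_params(node_score_cutoff = 0.05, haircut = FALSE)
  params_loose <- mcode_params(node_score_cutoff = 0.5, haircut = FALSE)
  m_tight <- find_modules(pg$network, params_tight)
  m_loose <- find_modules(pg$network, params_loose)
  expect_gte(length(m_tight), 1)
  expect_gte(length(m_loose), 1)
  # the globally highest-weight vertex seeds the first complex in both runs
  expect_equal(m_tight[[1]]$seed_vertex, m_loose[[1]]$seed_vertex)
  expect_true(all(m_tight[[1]]$members %in% m_loose[[1]]$members))
})

test_that("planted-clique recovery holds across 20 seeds", {
  hits <- vapply(1:20, function(s) {
    pg <- planted_modules_graph(60, 0.03, c(6), seed = s)
    mods <- find_modules(pg$network)
    length(mods) >= 1 && jaccard(mods[[1]]$members, pg$planted[[1]]) >= 0.8
  }, logical(1))
  expect_true(all(hits))
})

test_that("modules TSV lists rank, score, density, size, members", {
  net <- interaction_network(rbind(k_clique("A", 5), k_clique("B", 4)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_modules_tsv(find_modules(net), f)
  df <- utils::read.delim(f)
  expect_equal(df$rank, 1:2)
  expect_equal(df$size, c(5L, 4L))
  expect_equal(df$members[1], paste(sprintf("A%d", 1:5), collapse = ";"))
})
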