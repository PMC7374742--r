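test_that("degree histogram matches direct adjacency tallies", {
  tri <- make_net(c("A", "B", "B", "C", "A", "C"))
  expect_equal(degree_histogram(tri), data.frame(k = 2L, count = 3L))

  star <- make_net(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  expect_equal(degree_histogram(star),
               data.frame(k = c(1L, 4L), count = c(4L, 1L)))

  ba <- scale_free_graph(200, 2, seed = 7)
  h <- degree_histogram(ba)
  e <- network_edges(ba)
  tally <- table(c(e$protein1, e$protein2))
  expect_equal(sum(h$count), 200)
  expect_equal(h, data.frame(k = as.integer(names(table(as.integer(tally)))),
                             count = as.integer(table(as.integer(tally)))))
  expect_error(degree_histogram(interaction_network()), "empty")
})

test_that("power-law fit recovers noiseless parameters exactly", {
  fit <- fit_power_law(data.frame(k = 1:20, count = 258.52 * (1:20)^-1.171))
  expect_equal(fit$exponent_b, -1.171, tolerance = 1e-6)
  expect_equal(fit$coefficient_a, 258.52, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)

  # flat counts give slope 0
  flat <- fit_power_law(data.frame(k = 1:10, count = rep(5, 10)))
  expect_equal(flat$exponent_b, 0, tolerance = 1e-12)

  # exact recovery holds across the (a, b) plane
  for (a in c(0.5, 12, 400)) for (b in c(-3, -1.5, -0.2, 0)) {
    f <- fit_power_law(data.frame(k = 1:15, count = a * (1:15)^b))
    expect_equal(f$coefficient_a, a, tolerance = 1e-6)
    expect_equal(f$exponent_b, b, tolerance = 1e-6)
    expect_equal(f$r_squared, 1, tolerance = 1e-6)
  }
  expect_error(fit_power_law(data.frame(k = c(2, 2), count = c(3, 4))),
               "distinct")
})

test_that("noisy power-law fit equals an independent normal-equations solve", {
  withr::local_seed(99)
  k <- 1:30
  cnt <- 100 * k^-1.2 * exp(stats::rnorm(30, sd = 0.2))
  fit <- fit_power_law(data.frame(k = k, count = cnt))
  X <- cbind(1, log10(k))
  beta <- solve(t(X) %*% X, t(X) %*% log10(cnt))
  expect_equal(fit$coefficient_a, 10^beta[1], tolerance = 1e-9)
  expect_equal(fit$exponent_b, beta[2], tolerance = 1e-9)
})

test_that("clustering coefficients match neighbour-pair enumeration", {
  tri <- make_net(c("A", "B", "B", "C", "A", "C"))
  expect_equal(unname(clustering_coefficient(tri, "A")), 1)
  star <- make_net(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  expect_equal(unname(clustering_coefficient(star, "C")), 0)

  er <- random_graph(30, 0.3, seed = 1)
  expect_equal(clustering_coefficient(er), oracle_clustering(er))
  expect_equal(average_clustering(er), mean(oracle_clustering(er)))
})

test_that("characteristic path length averages over connected pairs", {
  path3 <- make_net(c("A", "B", "B", "C"))
  expect_equal(characteristic_path_length(path3), 4 / 3)
  for (n in c(2, 5, 9)) {
    kn <- random_graph(n, 1, seed = 1)
    expect_equal(characteristic_path_length(kn), 1)
  }
  er <- random_graph(25, 0.12, seed = 3)  # may be disconnected
  expect_equal(characteristic_path_length(er), oracle_path_length(er))
  expect_error(characteristic_path_length(
    interaction_network(nodes = c("A", "B"))), "connected")
})

test_that("betweenness matches exhaustive shortest-path enumeration", {
  path3 <- make_net(c("A", "B", "B", "C"))
  expect_equal(betweenness_centrality(path3), c(A = 0, B = 1, C = 0))
  star <- make_net(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  expect_equal(betweenness_centrality(star)[["C"]], 6)
  er <- random_graph(10, 0.35, seed = 8)
  expect_equal(betweenness_centrality(er), oracle_betweenness(er))
})

test_that("harmonic closeness sums reciprocal BFS distances", {
  star <- make_net(c("C", "L1", "C", "L2", "C", "L3"))
  expect_equal(harmonic_closeness(star)[["C"]], 3)
  path3 <- make_net(c("A", "B", "B", "C"))
  expect_equal(harmonic_closeness(path3)[["A"]], 1.5)
  er <- random_graph(15, 0.2, seed = 21)
  expect_equal(harmonic_closeness(er), oracle_harmonic_closeness(er))
})

test_that("bottleneck scores follow the quarter-of-tree rule", {
  iso <- interaction_network(nodes = c("A", "B"))
  expect_equal(bottleneck_scores(iso), c(A = 0L, B = 0L))

  # star: the centre carries all 4 root-paths from every leaf root
  # (p = 4 > 5/4); leaves are terminal (p = 1) and never score
  star <- make_net(c("C", "L1", "C", "L2", "C", "L3", "C", "L4"))
  expect_equal(bottleneck_scores(star),
               c(C = 4L, L1 = 0L, L2 = 0L, L3 = 0L, L4 = 0L))

  er <- random_graph(9, 0.3, seed = 4)
  expect_equal(bottleneck_scores(er), oracle_bottleneck(er))
})

test_that("exact centrality agreement with brute force on many small graphs", {
  for (seed in 1:6) {
    for (p in c(0.2, 0.45)) {
      g <- random_graph(8 + (seed %% 5), p, seed = seed)
      expect_equal(betweenness_centrality(g), oracle_betweenness(g))
      expect_equal(harmonic_closeness(g), oracle_harmonic_closeness(g))
      expect_equal(bottleneck_scores(g), oracle_bottleneck(g))
      expect_equal(clustering_coefficient(g), oracle_clustering(g))
    }
  }
})

test_that("network summary aggregates consistently", {
  k4 <- random_graph(4, 1, seed = 1)
  s <- summarize_network(k4)
  expect_equal(s$n_nodes, 4)
  expect_equal(s$n_edges, 6)
  expect_equal(s$average_degree, 3)
  expect_equal(s$average_clustering, 1)
  expect_equal(s$characteristic_path_length, 1)

  path3 <- make_net(c("A", "B", "B", "C"))
  s2 <- summarize_network(path3)
  expect_equal(s2$average_clustering, 0)
  expect_equal(s2$characteristic_path_length, 4 / 3)

  g <- scale_free_graph(60, 2, seed = 2)
  s3 <- summarize_network(g)
  expect_equal(s3$average_degree,
               2 * s3$n_edges / s3$n_nodes)
  expect_equal(s3$average_clustering, mean(oracle_clustering(g)))
  expect_equal(s3$characteristic_path_length, oracle_path_length(g))
})

test_that("degree sum equals twice the edge count (handshake lemma)", {
  for (seed in 1:5) {
    g <- random_graph(40, 0.1, seed = seed)
    h <- degree_histogram(g)
    expect_equal(sum(h$k * h$count), 2 * unname(network_size(g)["edges"]))
  }
})

test_that("scale-free fits show negative exponent and better log-log fit than ER", {
  ba <- scale_free_graph(600, 3, seed = 13)
  fit_ba <- fit_power_law(degree_histogram(ba))
  expect_lt(fit_ba$exponent_b, 0)
  n_edges <- unname(network_size(ba)["edges"])
  er <- random_graph(600, n_edges / choose(600, 2), seed = 13)
  fit_er <- fit_power_law(degree_histogram(er))
  expect_lt(fit_er$r_squared, fit_ba$r_squared)
})

test_that("node_metrics assembles the candidate-table layout", {
  g <- random_graph(12, 0.3, seed = 6)
  m <- node_metrics(g)
  expect_named(m, c("name", "bottleneck", "betweenness", "closeness",
                    "clustering_coefficient", "degree", "role"))
  expect_setequal(m$name, network_nodes(g))
  expect_equal(sort(m$bottleneck, decreasing = TRUE), m$bottleneck)
  expect_equal(stats::setNames(m$betweenness, m$name)[sort(m$name)],
               oracle_betweenness(g))
})
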