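test_that("connectivity_matrix is the absolute Pearson correlation with zero diagonal", {
  t_axis <- 1:140
  s1 <- sin(t_axis / 5)
  mat <- rbind(a = s1, b = s1, c = -s1 + 0.0, d = cos(t_axis / 3))
  g <- connectivity_matrix(mat)
  expect_equal(g$weights["a", "b"], 1)
  expect_equal(g$weights["a", "c"], 1) # anti-correlation folds to 1
  expect_equal(diag(g$weights), rep(0, 4), ignore_attr = TRUE)
  expect_true(all(g$weights >= 0 & g$weights <= 1))

  bad <- rbind(x = s1, y = rep(2, 140))
  expect_error(connectivity_matrix(bad), "ROI y")
})

test_that("independent series have low connectivity in nearly all trials", {
  hits <- 0
  for (s in 1:100) {
    set.seed(s)
    mat <- rbind(rnorm(140), rnorm(140))
    g <- connectivity_matrix(mat)
    if (g$weights[1, 2] < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("proportional thresholding keeps the strongest edges deterministically", {
  w <- matrix(0, 4, 4)
  vals <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  g <- threshold_graph(w, density = 0.5)
  expect_equal(sum(g$mask[upper.tri(g$mask)]), 3)
  kept <- w[upper.tri(w)][g$mask[upper.tri(g$mask)] == 1]
  expect_setequal(kept, c(0.9, 0.8, 0.7))

  # density 1 retains every off-diagonal pair
  g1 <- threshold_graph(w, density = 1)
  expect_equal(g1$mask, 1 - diag(4), ignore_attr = TRUE)

  # ties at the cut resolve toward the lexicographically smallest (i, j)
  wt <- matrix(0, 3, 3)
  wt[upper.tri(wt)] <- c(0.5, 0.5, 0.5)
  wt <- wt + t(wt)
  gt <- threshold_graph(wt, density = 1 / 3)
  expect_equal(gt$mask[1, 2], 1)
  expect_equal(sum(gt$mask) / 2, 1)
  expect_identical(gt$mask, threshold_graph(wt, density = 1 / 3)$mask)

  expect_error(threshold_graph(w, density = 0), "density")
})

test_that("local measures match closed forms on canonical graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  m <- local_graph_measures(graph_from_adjacency(tri))
  expect_equal(m$degree, rep(2, 3))
  expect_equal(m$k_coreness_centrality, rep(2, 3))
  expect_equal(m$betweenness_centrality, rep(0, 3))
  expect_equal(m$eigenvector_centrality, rep(1 / sqrt(3), 3))

  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  mp <- local_graph_measures(graph_from_adjacency(path))
  expect_equal(mp$betweenness_centrality, c(0, 1, 0))
  expect_equal(sum(mp$pagerank_centrality), 1, tolerance = 1e-9)

  # single edge: eigenvalues +/-1 give subgraph centrality cosh(1)
  edge <- matrix(0, 2, 2)
  edge[1, 2] <- edge[2, 1] <- 1
  me <- local_graph_measures(graph_from_adjacency(edge))
  expect_equal(me$subgraph_centrality, rep(cosh(1), 2), tolerance = 1e-9)

  # star with 3 leaves: center lies on all 3 leaf pairs' shortest paths
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  ms <- local_graph_measures(graph_from_adjacency(star))
  expect_equal(ms$betweenness_centrality[1], 3)
  expect_equal(bf_betweenness(star)[1], 3)

  empty <- matrix(0, 3, 3)
  expect_error(local_graph_measures(graph_from_adjacency(empty)), "no edges")
})

test_that("diversity coefficient hits its entropy bounds", {
  # node 1 with all strength into one module -> 0; spread over all -> 1
  adj <- matrix(0, 5, 5)
  adj[1, 2:5] <- adj[2:5, 1] <- 1
  g <- graph_from_adjacency(adj, weights = adj * 0.5)
  # all of node 1's strength flows into a single module -> entropy 0
  d <- diversity_coefficient(g, modules = c(1, 2, 2, 2, 2))
  expect_equal(d[1], 0)
  # strength spread equally over 4 modules -> 1 after normalization
  d_even <- diversity_coefficient(g, modules = c(5, 1, 2, 3, 4))
  expect_equal(d_even[1], -sum(rep(.25, 4) * log(.25)) / log(5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("global measures: star assortativity, complete-graph sigma, small-world regime", {
  star <- matrix(0, 6, 6)
  star[1, 2:6] <- star[2:6, 1] <- 1
  gs <- global_graph_measures(graph_from_adjacency(star), n_rewires = 5,
                              seed = 1)
  expect_equal(gs$assortativity, -1, tolerance = 1e-12)
  expect_equal(gs$assortativity, bf_assortativity(star), tolerance = 1e-12)

  comp <- matrix(1, 5, 5) - diag(5)
  gc <- global_graph_measures(graph_from_adjacency(comp), n_rewires = 5,
                              seed = 1)
  expect_equal(gc$small_worldness, 1)
  expect_false(gc$small_worldness_infinite)

  # regular ring lattice: all degrees equal -> assortativity flagged to 0
  ring <- matrix(0, 8, 8)
  for (i in 1:8) {
    ring[i, (i %% 8) + 1] <- 1
    ring[(i %% 8) + 1, i] <- 1
  }
  gr <- global_graph_measures(graph_from_adjacency(ring), n_rewires = 5,
                              seed = 1)
  expect_equal(gr$assortativity, 0)
  expect_true(gr$assortativity_degenerate)
})

test_that("ring lattice with shortcuts sits in the small-world regime", {
  n <- 50
  lat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in 1:2) {
      j <- ((i + s - 1) %% n) + 1
      lat[i, j] <- lat[j, i] <- 1
    }
  }
  sigmas <- vapply(1:10, function(s) {
    set.seed(s)
    adj <- lat
    for (k in 1:5) {
      ij <- sample(n, 2)
      adj[ij[1], ij[2]] <- adj[ij[2], ij[1]] <- 1
    }
    global_graph_measures(graph_from_adjacency(adj), n_rewires = 10,
                          seed = s)$small_worldness
  }, numeric(1))
  expect_true(all(sigmas > 1))
})

test_that("node-level measures agree with brute-force oracles on random graphs", {
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(4:7, 1)
    repeat {
      adj <- matrix(0, n, n)
      adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.5)
      adj <- adj + t(adj)
      if (is_connected_adj(adj) && sum(adj) > 0) break
    }
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- runif(n * (n - 1) / 2)
    w <- w + t(w)
    g <- graph_from_adjacency(adj, weights = w)
    m <- local_graph_measures(g)
    expect_equal(m$degree, bf_degree(adj))
    expect_equal(m$node_strength, bf_strength(w, adj))
    expect_equal(m$betweenness_centrality, bf_betweenness(adj),
                 tolerance = 1e-9)
    expect_equal(m$k_coreness_centrality, bf_kcore(adj))
    expect_equal(m$subgraph_centrality, bf_subgraph(adj), tolerance = 1e-8)
    expect_equal(m$eigenvector_centrality, bf_eigenvector(adj),
                 tolerance = 1e-6)
    expect_equal(m$pagerank_centrality, bf_pagerank(adj), tolerance = 1e-9)
    expect_equal(sum(m$pagerank_centrality), 1, tolerance = 1e-9)
    expect_equal(sum(m$eigenvector_centrality^2), 1, tolerance = 1e-9)
  }
})
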