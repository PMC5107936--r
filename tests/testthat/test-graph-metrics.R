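test_that("closed forms hold on canonical graphs", {
  k4 <- complete_net(4)
  expect_equal(clustering_coefficient(k4), 1)
  expect_equal(characteristic_path_length(k4), 1)
  expect_equal(global_efficiency(k4), 1)
  expect_equal(local_efficiency(k4), 1)
  # single-module partition of a complete graph scores Q = 0
  expect_equal(covnet:::as_igraph(k4) |>
                 igraph::modularity(rep(1, 4)), 0)

  s5 <- star_net(5)
  expect_equal(clustering_coefficient(s5), 0) # no triangles
  expect_equal(local_efficiency(s5), 0)       # edgeless neighbourhoods

  expect_equal(characteristic_path_length(path_net(4)), 10 / 6)
  expect_equal(global_efficiency(path_net(3)), 5 / 6)

  # two disjoint edges: only within-component pairs counted
  expect_equal(characteristic_path_length(net_from_edges(4, c(1, 2, 3, 4))), 1)
  # empty network conventions
  empty <- net_from_edges(5, integer())
  expect_equal(clustering_coefficient(empty), 0)
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(empty), "no edges")
})

test_that("clustering matches exhaustive triangle counting on a chorded cycle", {
  net <- net_from_edges(5, c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1, 1, 3))
  expect_equal(clustering_coefficient(net), oracle_cp(net$adjacency))
  expect_equal(local_efficiency(net), oracle_leff(net$adjacency))
})

test_that("all metrics agree with brute-force oracles on random small graphs", {
  withr::with_seed(2024, {
    for (i in 1:25) {
      n <- sample(4:7, 1)
      adj <- random_connected_adj(n, p = runif(1, 0.3, 0.8))
      net <- net_from_adj(adj)
      expect_equal(clustering_coefficient(net), oracle_cp(adj),
                   tolerance = 1e-12)
      expect_equal(characteristic_path_length(net), oracle_lp(adj),
                   tolerance = 1e-12)
      expect_equal(global_efficiency(net), oracle_geff(adj),
                   tolerance = 1e-12)
      expect_equal(local_efficiency(net), oracle_leff(adj),
                   tolerance = 1e-12)
      expect_equal(node_betweenness(net)$betweenness,
                   oracle_betweenness(adj), tolerance = 1e-10)
    }
  })
})

test_that("betweenness follows the shortest-path definition on known graphs", {
  s5 <- star_net(5)
  b <- node_betweenness(s5)
  expect_equal(b$betweenness, c(6, 0, 0, 0, 0)) # choose(4, 2) leaf pairs
  ring <- ring_net(6)
  expect_length(unique(round(node_betweenness(ring)$betweenness, 10)), 1)
})

test_that("hub detection flags nodes above twice the mean betweenness", {
  hubs <- identify_hubs(star_net(5))
  expect_equal(hubs$normalized_betweenness[1], 5) # 6 / (6/5)
  expect_true(hubs$is_hub[1])
  expect_false(any(hubs$is_hub[-1]))
  expect_equal(mean(hubs$normalized_betweenness), 1)
  # sorted descending, as a hub table should be
  expect_true(!is.unsorted(rev(hubs$normalized_betweenness)))

  expect_false(any(identify_hubs(ring_net(6))$is_hub))
  expect_false(any(identify_hubs(complete_net(5))$is_hub))
  # all-zero betweenness: empty hub set with a warning
  expect_warning(h0 <- identify_hubs(net_from_edges(4, c(1, 2, 3, 4))),
                 "zero")
  expect_false(any(h0$is_hub))
})

test_that("modularity scores and recovers planted structure", {
  two_tri <- net_from_edges(6, c(1, 2, 2, 3, 1, 3, 4, 5, 5, 6, 4, 6))
  # component partition scores exactly 0.5 by the Newman-Girvan formula
  expect_equal(oracle_modularity(two_tri$adjacency, c(1, 1, 1, 2, 2, 2)), 0.5)
  fit <- network_modularity(two_tri, seed = 1)
  expect_equal(fit$q, 0.5)
  expect_equal(fit$q, oracle_modularity(two_tri$adjacency, fit$partition))

  # planted 4-module network: recovered partition matches ground truth
  skip_if_not_installed("mclust")
  planted <- rep(1:4, each = 8)
  adj <- withr::with_seed(77, {
    p <- ifelse(outer(planted, planted, "=="), 0.8, 0.05)
    a <- matrix(0L, 32, 32)
    up <- upper.tri(a)
    a[up] <- as.integer(runif(sum(up)) < p[up])
    a + t(a)
  })
  fit <- network_modularity(net_from_adj(adj), seed = 2)
  ari <- mclust::adjustedRandIndex(fit$partition, planted)
  expect_gte(ari, 0.9)
  # planted modularity beats degree-matched rewired versions
  net <- net_from_adj(adj)
  null_q <- vapply(1:10, function(i) {
    network_modularity(rewire_degree_preserving(net, 10, seed = i),
                       seed = i, n_restarts = 5)$q
  }, numeric(1))
  expect_gt(fit$q, mean(null_q))
})

test_that("largest component relative size counts isolated nodes", {
  expect_equal(largest_component_relative_size(ring_net(6)), 1)
  expect_equal(largest_component_relative_size(net_from_edges(68, integer())),
               1 / 68)
  # components of size 4 and 2 on 6 nodes
  net <- net_from_edges(6, c(1, 2, 2, 3, 3, 4, 5, 6))
  expect_equal(largest_component_relative_size(net), 4 / 6)
})

test_that("adding an edge never decreases efficiency nor increases Lp", {
  withr::with_seed(31, {
    for (i in 1:10) {
      adj <- random_connected_adj(6, p = 0.4)
      missing <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
      if (!nrow(missing)) next
      pick <- missing[sample(nrow(missing), 1), ]
      adj2 <- adj
      adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
      expect_gte(global_efficiency(net_from_adj(adj2)),
                 global_efficiency(net_from_adj(adj)))
      expect_lte(characteristic_path_length(net_from_adj(adj2)),
                 characteristic_path_length(net_from_adj(adj)))
    }
  })
})

test_that("global efficiency is 1 exactly on complete graphs only", {
  expect_equal(global_efficiency(complete_net(6)), 1)
  near <- complete_net(6)
  adj <- near$adjacency
  adj[1, 2] <- adj[2, 1] <- 0L
  expect_lt(global_efficiency(net_from_adj(adj)), 1)
})
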