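path3 <- interaction_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))

test_that("shortest-path distances and counts match hand cases", {
  sp <- all_pairs_shortest_paths(path3)
  expect_identical(sp$dist["a", "c"], 2)
  expect_identical(sp$sigma["a", "c"], 1)
  cyc <- interaction_network(letters[1:4],
    rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_identical(all_pairs_shortest_paths(cyc)$sigma["a", "c"], 2)
  # disconnected pair
  iso <- interaction_network(c("a", "b", "z"), rbind(c("a", "b")))
  sp2 <- all_pairs_shortest_paths(iso)
  expect_identical(sp2$dist["a", "z"], Inf)
  expect_identical(sp2$sigma["a", "z"], 0)
})

test_that("clustering coefficient follows its definition", {
  tri <- interaction_network(letters[1:3],
    rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_identical(clustering_coefficient(tri, "a"), 1)
  star <- interaction_network(c("h", "l1", "l2", "l3"),
    rbind(c("h", "l1"), c("h", "l2"), c("h", "l3")))
  expect_identical(clustering_coefficient(star, "h"), 0)
  onepair <- interaction_network(c("n", "a", "b", "c"),
    rbind(c("n", "a"), c("n", "b"), c("n", "c"), c("a", "b")))
  expect_equal(clustering_coefficient(onepair, "n"), 1 / 3)
  expect_error(clustering_coefficient(tri, "zz"), "unknown node")
})

test_that("betweenness and stress match hand cases", {
  expect_identical(betweenness(path3, "b"), 1)
  expect_identical(betweenness(path3, "a"), 0)
  expect_identical(stress(path3, "b"), 1)
  p4 <- interaction_network(letters[1:4],
    rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_identical(betweenness(p4, "b"), 2)
  expect_equal(betweenness(p4, "b", normalized = TRUE), 2 / 3)
})

test_that("node_topology handles degenerate and symmetric graphs", {
  iso <- interaction_network(c("a", "b", "z"), rbind(c("a", "b")))
  z <- node_topology(iso, "z")
  expect_identical(z$eccentricity, 0)
  expect_true(is.na(z$closeness))
  expect_identical(z$stress, 0)
  k4 <- interaction_network(letters[1:4], t(utils::combn(letters[1:4], 2)))
  t4 <- node_topology(k4, "a")
  expect_identical(t4$closeness, 1)
  expect_identical(t4$clustering, 1)
  expect_identical(t4$betweenness, 0)
  # 3-node path hand values
  tb <- node_topology(path3)
  expect_identical(tb$stress[tb$node == "b"], 1)
  expect_identical(tb$neighborhood_connectivity[tb$node == "a"], 2)
})

test_that("network_summary matches hand enumeration", {
  e1 <- interaction_network(c("a", "b"), rbind(c("a", "b")))
  s <- network_summary(e1)
  expect_identical(s$diameter, 1)
  expect_identical(s$characteristic_path_length, 1)
  expect_identical(s$mean_neighbors, 1)
  p4 <- interaction_network(letters[1:4],
    rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(network_summary(p4)$characteristic_path_length, 5 / 3)
  expect_error(network_summary(interaction_network(character(0))), "empty")
})

test_that("handshake identity holds on random graphs", {
  for (s in 1:20) {
    net <- simulate_network(sample(2:12, 1), "erdos_renyi", 0.3, seed = s)
    expect_identical(sum(node_degree(net)), 2L * nrow(net$edges))
  }
})

test_that("tree leaves have zero betweenness and stress; path-count identity holds", {
  for (s in 1:10) {
    net <- simulate_network(8, "tree_plus_chords", 0, seed = s)
    deg <- node_degree(net)
    leaves <- names(deg)[deg == 1]
    expect_true(all(betweenness(net)[leaves] == 0))
    expect_true(all(stress(net)[leaves] == 0))
    # on a tree all shortest paths are unique: sum btw = sum over pairs (d-1)
    sp <- all_pairs_shortest_paths(net)
    d <- sp$dist[upper.tri(sp$dist)]
    expect_equal(sum(betweenness(net)), sum(d - 1))
  }
})

test_that("metrics are invariant under node relabeling", {
  for (s in 1:5) {
    net <- simulate_network(7, "erdos_renyi", 0.4, seed = s)
    perm <- local_seed_sample(s, net$nodes)
    relab <- stats::setNames(paste0("x", seq_along(perm)), perm)
    net2 <- interaction_network(unname(relab[net$nodes]),
      if (nrow(net$edges)) cbind(relab[net$edges[, 1]],
                                 relab[net$edges[, 2]]))
    for (fn in list(node_degree, betweenness, stress,
                    clustering_coefficient))
      expect_equal(unname(fn(net2)[relab[net$nodes]]),
                   unname(fn(net)[net$nodes]))
  }
})

test_that("betweenness agrees with igraph on random graphs", {
  for (s in 1:10) {
    net <- simulate_network(9, "erdos_renyi", 0.35, seed = s)
    ig <- as_igraph(net)
    expect_equal(unname(betweenness(net)[net$nodes]),
                 unname(igraph::betweenness(ig)[net$nodes]))
    tr <- igraph::transitivity(ig, type = "localundirected",
                               isolates = "zero")
    expect_equal(unname(clustering_coefficient(net)[net$nodes]),
                 unname(ifelse(is.nan(tr), 0, tr)))
  }
})
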