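# Graph measures against hand-enumerated cases and exhaustive oracles.

test_that("separation on the path graph matches hand enumeration", {
  res <- separation(path5(), c("1", "2"), c("4", "5"))
  expect_equal(res$d_ab, 2.5)
  expect_equal(res$d_aa, 1)
  expect_equal(res$d_bb, 1)
  expect_equal(res$s_ab, 1.5)
})

test_that("identical sets overlap maximally (negative separation)", {
  g <- path5()
  res <- separation(g, c("2", "3", "4"), c("2", "3", "4"))
  expect_equal(res$d_ab, 0)
  expect_equal(res$s_ab, -res$d_aa)
  expect_lt(res$s_ab, 0)
})

test_that("separation is symmetric in its sets", {
  set.seed(31)
  for (i in 1:20) {
    adj <- random_connected_adj(7)
    g <- adj_to_igraph(adj)
    a <- sample(rownames(adj), 3)
    b <- sample(rownames(adj), 3)
    expect_identical(separation(g, a, b)$s_ab, separation(g, b, a)$s_ab)
  }
})

test_that("module shortest distance matches hand enumeration", {
  expect_equal(module_shortest_distance(path5(), c("1", "2"),
                                        c("4", "5"))$d_shortest, 3)
  # two triangles joined completely: every cross distance is 1
  g <- igraph::make_full_bipartite_graph(3, 3)
  igraph::V(g)$name <- paste0("n", 1:6)
  g <- igraph::add_edges(g, c("n1", "n2", "n2", "n3", "n4", "n5", "n5", "n6"))
  expect_equal(module_shortest_distance(g, paste0("n", 1:3),
                                        paste0("n", 4:6))$d_shortest, 1)
})

test_that("flow centrality solves the star and the 4-cycle", {
  fc <- flow_centrality(star5(), c("l1", "l2"), c("l3", "l4"))
  hub <- fc[fc$gene == "c", ]
  expect_equal(hub$fc_norm, 1)
  expect_equal(hub$fc_raw, 4)

  fc2 <- flow_centrality(cycle4(), "a", "b")
  expect_equal(fc2$fc_norm[fc2$gene == "x"], 0.5)
  expect_equal(fc2$fc_norm[fc2$gene == "y"], 0.5)
})

test_that("gene total distance matches hand enumeration", {
  expect_equal(gene_total_distance(star5(), "c",
                                   c("l1", "l2"), c("l3", "l4"))$total_distance, 4)
  expect_equal(gene_total_distance(path5(), "3",
                                   c("1", "2"), c("4", "5"))$total_distance, 6)
})

test_that("all four measures agree with exhaustive oracles on random graphs", {
  set.seed(77)
  for (i in 1:40) {
    n <- sample(5:8, 1)
    adj <- random_connected_adj(n)
    g <- adj_to_igraph(adj)
    nodes <- rownames(adj)
    a <- sample(nodes, 2)
    b <- sample(setdiff(nodes, a), 2)
    a_idx <- match(a, nodes); b_idx <- match(b, nodes)

    osep <- oracle_separation(adj, a_idx, b_idx)
    sep <- separation(g, a, b)
    expect_equal(sep$s_ab, osep$s_ab)
    expect_equal(sep$d_ab, osep$d_ab)

    expect_equal(module_shortest_distance(g, a, b)$d_shortest,
                 oracle_module_distance(adj, a_idx, b_idx))

    ofc <- oracle_flow(adj, a_idx, b_idx, seq_len(n))
    fc <- flow_centrality(g, a, b)
    fc <- fc[match(nodes, fc$gene), ]
    expect_equal(fc$fc_raw, unname(ofc$fc_raw))
    expect_equal(fc$fc_norm, unname(ofc$fc_norm))

    v <- sample(nodes, 1)
    expect_equal(gene_total_distance(g, v, a, b)$total_distance,
                 oracle_total_distance(adj, match(v, nodes), a_idx, b_idx))
  }
})

test_that("flow centrality fractions are bounded", {
  net <- simulate_network(sim_config(seed = 41, network_n = 120L, n_bridges = 1L,
                                     target_set_spec = list(size_a = 10L, size_b = 10L,
                                                            mode = "separated")))
  fc <- flow_centrality(net$graph, net$truth$target_a, net$truth$target_b)
  expect_true(all(fc$fc_norm >= 0 & fc$fc_norm <= 1, na.rm = TRUE))
  expect_true(all(fc$fc_raw <= fc$pairs_used + 1e-9))
  expect_equal(fc$fc_norm, fc$fc_raw / fc$pairs_used)
})

test_that("adding an edge never increases a distance", {
  set.seed(51)
  adj <- random_connected_adj(8, p = 0.3)
  g <- adj_to_igraph(adj)
  d0 <- igraph::distances(g)
  absent <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  pick <- absent[sample(nrow(absent), 1), ]
  g2 <- igraph::add_edges(g, rownames(adj)[pick])
  d1 <- igraph::distances(g2)[rownames(d0), colnames(d0)]
  expect_true(all(d1 <= d0))
  # and the closest-measure separation cannot grow either
  a <- rownames(adj)[1:3]; b <- rownames(adj)[4:6]
  expect_lte(separation(g2, a, b)$d_ab, separation(g, a, b)$d_ab)
})

test_that("unmapped genes are dropped with a warning naming them", {
  expect_warning(res <- separation(path5(), c("1", "2", "zz"), c("4", "5")),
                 "zz")
  expect_equal(res$n_dropped, 1)
  expect_equal(res$n_mapped_a, 2)
})

test_that("singleton and disconnected sets raise informative errors", {
  expect_error(suppressWarnings(separation(path5(), c("1", "zz"), c("4", "5"))),
               "at least 2")
  two_comp <- igraph::make_graph(~ a - b, b - c, x - y, y - z)
  expect_error(
    suppressWarnings(separation(two_comp, c("a", "b"), c("x", "y"),
                                lcc = FALSE)),
    "components")
  expect_error(
    suppressWarnings(module_shortest_distance(two_comp, c("a", "b"),
                                              c("x", "y"), lcc = FALSE)),
    "disconnected")
})

test_that("largest-component restriction is flagged and applied", {
  two_comp <- igraph::make_graph(~ a - b, b - c, c - a, x - y)
  expect_warning(g <- interaction_network(two_comp), "largest connected")
  expect_equal(sort(igraph::V(g)$name), c("a", "b", "c"))
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "b", "a"))
  simple <- interaction_network(edges)
  expect_equal(igraph::ecount(simple), 1)
})
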