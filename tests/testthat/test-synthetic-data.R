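# Synthetic-data generator: determinism, the latent-factor correlation
# structure, planted effects, and the planted network sets.

test_that("same config gives byte-identical expression and networks", {
  cfg <- synergy_config(seed = 42)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$expr, s2$expr)
  expect_identical(s1$truth, s2$truth)
  n1 <- simulate_network(cfg)
  n2 <- simulate_network(cfg)
  expect_identical(igraph::as_edgelist(n1$graph), igraph::as_edgelist(n2$graph))
  expect_identical(n1$truth, n2$truth)
})

test_that("zero loadings give independent genes", {
  sim <- simulate_expression(sim_config(
    n_genes = 40, n_samples_per_group = 200, module_sizes = c(20L, 20L),
    module_corr = 0, seed = 3))
  cc <- cor(t(sim$expr$sham))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.15)
})

test_that("one-factor loading r implies within-module correlation r^2", {
  sim <- simulate_expression(sim_config(
    n_genes = 30, n_samples_per_group = 100, module_sizes = 30L,
    module_corr = 0.9, seed = 7))
  cc <- cor(t(sim$expr$sham))
  expect_equal(mean(cc[upper.tri(cc)]), 0.81, tolerance = 0.05 / 0.81)
})

test_that("planted log2 effects reproduce the intended fold change", {
  delta <- log2(1.5)
  cfg <- sim_config(n_genes = 20, n_samples_per_group = 10,
                    module_sizes = integer(0), module_corr = numeric(0),
                    noise_sd = 0.05,
                    deg_map = list(drugA = data.frame(gene = "g0005",
                                                      delta = delta)),
                    seed = 11)
  sim <- simulate_expression(cfg)
  fc <- 2^(mean(sim$expr$drugA["g0005", ]) - mean(sim$expr$sham["g0005", ]))
  expect_equal(fc, 1.5, tolerance = 0.05)
})

test_that("disruption destroys co-expression only in the named group", {
  cfg <- sim_config(module_sizes = 30L, module_corr = 0.9,
                    n_genes = 30, n_samples_per_group = 50,
                    disruption_map = list(drugA = 1L), seed = 5)
  sim <- simulate_expression(cfg)
  mean_cor <- function(x) { cc <- cor(t(x)); mean(cc[upper.tri(cc)]) }
  expect_gt(mean_cor(sim$expr$sham), 0.6)
  expect_lt(abs(mean_cor(sim$expr$drugA)), 0.2)
})

test_that("preferential-attachment networks are heavy-tailed and connected", {
  net <- simulate_network(sim_config(seed = 13, n_bridges = 0L))
  deg <- igraph::degree(net$graph)
  expect_true(igraph::is_connected(net$graph))
  expect_gt(max(deg), 5 * median(deg))
  expect_equal(igraph::vcount(net$graph), 500)
})

test_that("planted overlapping sets separate negatively, separated sets positively", {
  cfg_o <- sim_config(seed = 21, n_bridges = 0L,
                      target_set_spec = list(size_a = 20L, size_b = 20L,
                                             mode = "overlapping",
                                             overlap_frac = 0.3))
  net_o <- simulate_network(cfg_o)
  expect_lt(separation(net_o$graph, net_o$truth$target_a,
                       net_o$truth$target_b)$s_ab, 0)

  cfg_s <- sim_config(seed = 21, n_bridges = 0L,
                      target_set_spec = list(size_a = 20L, size_b = 20L,
                                             mode = "separated"))
  net_s <- simulate_network(cfg_s)
  expect_gt(separation(net_s$graph, net_s$truth$target_a,
                       net_s$truth$target_b)$s_ab, 0)
})

test_that("ground truth round-trips through JSON unchanged", {
  cfg <- synergy_config(seed = 2)
  sim <- simulate_expression(cfg)
  net <- simulate_network(cfg)
  truth <- sim$truth
  truth$target_a <- net$truth$target_a
  truth$target_b <- net$truth$target_b
  truth$bridges <- net$truth$bridges
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, f)
  expect_equal(read_ground_truth(f), truth)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 10, module_sizes = c(6L, 6L)),
               "module_sizes")
  expect_error(sim_config(module_corr = 1.2), "loadings")
  expect_error(sim_config(disruption_map = list(nope = 1L)), "unknown group")
  expect_error(sim_config(disruption_map = list(drugA = 99L)), "module ids")
  expect_error(sim_config(network_n = 5), "network_n")
})

test_that("configuration-model networks are generated connected", {
  cfg <- sim_config(seed = 31, network_model = "configuration",
                    network_param = 2.5, n_bridges = 0L,
                    target_set_spec = list(size_a = 10L, size_b = 10L,
                                           mode = "overlapping",
                                           overlap_frac = 0.3))
  net <- simulate_network(cfg)
  expect_true(igraph::is_connected(net$graph))
})
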