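# Co-expression network construction and module detection.

test_that("perfectly correlated pair has adjacency 1 and TOM 1", {
  x <- matrix(rnorm(20), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  x[2, ] <- 2 * x[1, ] + 3
  for (beta in c(1, 6, 20)) {
    net <- build_network(x, beta = beta)
    expect_equal(net$adjacency["g1", "g2"], 1)
    expect_equal(net$tom["g1", "g2"], 1)
  }
})

test_that("TOM matches a brute-force evaluation of its formula", {
  set.seed(42)
  x <- matrix(rnorm(4 * 12), nrow = 4,
              dimnames = list(paste0("g", 1:4), NULL))
  beta <- 3
  net <- build_network(x, beta = beta)
  a <- abs(cor(t(x)))^beta
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      }
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(a)
  expect_equal(net$tom, tom, tolerance = 1e-12)
})

test_that("adjacency and TOM are symmetric, bounded, monotone in beta", {
  sim <- one_module_expr(seed = 4)
  nets <- lapply(c(4, 8), function(b) build_network(sim$expr$sham, beta = b))
  for (net in nets) {
    expect_lt(max(abs(net$tom - t(net$tom))), 1e-12)
    expect_lt(max(abs(net$adjacency - t(net$adjacency))), 1e-12)
    expect_true(all(net$tom >= 0 & net$tom <= 1 + 1e-12))
    expect_true(all(net$adjacency >= 0 & net$adjacency <= 1))
    expect_equal(unname(diag(net$tom)), rep(1, nrow(net$tom)))
  }
  off <- upper.tri(nets[[1]]$adjacency)
  expect_true(all(nets[[2]]$adjacency[off] <= nets[[1]]$adjacency[off]))
})

test_that("soft-threshold fit is poor for independent noise", {
  sim <- simulate_expression(sim_config(
    n_genes = 1000, n_samples_per_group = 20,
    module_sizes = integer(0), module_corr = numeric(0), seed = 8))
  expect_warning(sft <- pick_soft_threshold(sim$expr$sham,
                                            powers = c(2, 4, 6, 8, 10)),
                 "best fit")
  expect_true(all(sft$sft_r2 < 0.5))
  expect_false(attr(sft, "reached_target"))
})

test_that("chosen power is the smallest meeting the fit target", {
  sim <- simulate_expression(synergy_config(seed = 2))
  sft <- suppressWarnings(pick_soft_threshold(sim$expr$combo))
  chosen <- attr(sft, "chosen_beta")
  if (attr(sft, "reached_target")) {
    hits <- sft$power[sft$sft_r2 >= attr(sft, "target_r2")]
    expect_equal(chosen, min(hits))
  } else {
    expect_equal(chosen, sft$power[which.max(sft$sft_r2)])
  }
  expect_true(chosen %in% sft$power)
})

test_that("published powers work as explicit overrides", {
  sim <- one_module_expr(size = 10, n_noise = 5, n_samples = 10, seed = 6)
  for (beta in c(10, 16, 20)) {
    net <- build_network(sim$expr$sham, beta = beta)
    expect_s3_class(net, "dims_coexpr")
    expect_equal(net$beta, beta)
  }
})

test_that("zero-variance genes are rejected or excluded as specified", {
  x <- matrix(rnorm(30), nrow = 3,
              dimnames = list(paste0("g", 1:3), NULL))
  x[2, ] <- 5
  expect_error(build_network(x, beta = 6), "Zero-variance")
  w <- capture_warnings(pick_soft_threshold(rbind(x, x[c(1, 3), ] + rnorm(20)),
                                            powers = c(2, 4)))
  expect_true(any(grepl("zero-variance", w)))
})

test_that("planted modules are recovered and small clusters go grey", {
  sim <- simulate_expression(sim_config(
    n_genes = 200, n_samples_per_group = 50,
    module_sizes = rep(30L, 5L), module_corr = 0.9, seed = 9))
  mods <- detect_modules(build_network(sim$expr$sham, beta = 6))
  expect_equal(length(unique(mods$module[mods$module > 0])), 5)
  expect_gte(adjusted_rand_index(mods$module, sim$truth$modules$module), 0.8)
  sizes <- table(mods$module[mods$module > 0])
  expect_true(all(sizes >= 3))
})

test_that("all-noise input leaves the majority of genes unassigned", {
  sim <- simulate_expression(sim_config(
    n_genes = 200, n_samples_per_group = 20,
    module_sizes = integer(0), module_corr = numeric(0), seed = 10))
  mods <- detect_modules(build_network(sim$expr$sham, beta = 6))
  expect_gte(mean(mods$module == 0), 0.5)
})

test_that("gene order does not change the partition", {
  sim <- simulate_expression(sim_config(
    n_genes = 90, n_samples_per_group = 30,
    module_sizes = c(30L, 30L), module_corr = 0.9, seed = 12))
  x <- sim$expr$sham
  mods1 <- detect_modules(build_network(x, beta = 6))
  set.seed(1)
  perm <- sample(nrow(x))
  mods2 <- detect_modules(build_network(x[perm, ], beta = 6))
  merged <- dplyr::inner_join(mods1, mods2, by = "gene")
  expect_equal(adjusted_rand_index(merged$module.x, merged$module.y), 1)
})

test_that("module labels are numbered by decreasing size", {
  sim <- simulate_expression(sim_config(
    n_genes = 100, n_samples_per_group = 40,
    module_sizes = c(40L, 25L, 10L), module_corr = 0.9, seed = 14))
  mods <- detect_modules(build_network(sim$expr$sham, beta = 6))
  sizes <- as.vector(table(factor(mods$module[mods$module > 0])))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(mods$color[mods$module == 0] == "grey"))
})
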