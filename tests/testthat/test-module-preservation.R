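# Permutation Zsummary preservation and the synergy-module rule.

test_that("the composite equals its components when they agree", {
  for (z in c(-1.7, 0, 0.4, 2, 5.5)) {
    expect_identical(zsummary_composite(rep(z, 4), rep(z, 3)), z)
  }
  # and is the halved sum of the two medians in general
  expect_equal(zsummary_composite(c(1, 2, 3, 10), c(-1, 0, 4)),
               (2.5 + 0) / 2)
})

test_that("intact modules are conserved, disrupted modules are on", {
  cfg <- sim_config(n_genes = 150, n_samples_per_group = 20,
                    module_sizes = rep(30L, 4L), module_corr = 0.9,
                    disruption_map = list(drugA = c(3L, 4L)), seed = 18)
  sim <- simulate_expression(cfg)
  mods <- truth_modules(sim)
  pres <- module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                              beta = 6, n_perm = 100, seed = 1)
  expect_equal(pres$class[pres$module %in% 1:2], rep("conserved", 2))
  expect_equal(pres$class[pres$module %in% 3:4], rep("on", 2))
  # identical data preserves everything
  self <- module_preservation(sim$expr$sham, sim$expr$sham, mods,
                              beta = 6, n_perm = 100, seed = 1)
  expect_true(all(self$class == "conserved"))
})

test_that("stored zsummary equals the composite of the stored components", {
  sim <- simulate_expression(sim_config(
    n_genes = 100, n_samples_per_group = 15, module_sizes = c(30L, 30L),
    module_corr = 0.9, seed = 19))
  pres <- module_preservation(sim$expr$drugA, sim$expr$sham,
                              truth_modules(sim), n_perm = 50, seed = 3)
  for (i in seq_len(nrow(pres))) {
    expect_identical(pres$zsummary[i],
                     zsummary_composite(
                       c(pres$z_mean_cor[i], pres$z_mean_adj[i],
                         pres$z_prop_var_expl[i], pres$z_mean_kme[i]),
                       c(pres$z_cor_kim[i], pres$z_cor_kme[i],
                         pres$z_cor_cor[i])))
  }
})

test_that("the comparison direction matters and the seed pins the null", {
  cfg <- sim_config(n_genes = 100, n_samples_per_group = 15,
                    module_sizes = c(30L, 30L), module_corr = c(0.9, 0.9),
                    disruption_map = list(drugA = 2L), seed = 20)
  sim <- simulate_expression(cfg)
  mods <- truth_modules(sim)
  fwd <- module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                             n_perm = 50, seed = 5)
  rev <- module_preservation(sim$expr$drugA, sim$expr$sham, mods,
                             n_perm = 50, seed = 5)
  expect_false(isTRUE(all.equal(fwd$zsummary, rev$zsummary)))
  again <- module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                               n_perm = 50, seed = 5)
  expect_identical(fwd$zsummary, again$zsummary)
  expect_error(module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                                   n_perm = 50),
               "seed")
})

test_that("more permutations stabilize zsummary across seeds", {
  sim <- simulate_expression(sim_config(
    n_genes = 80, n_samples_per_group = 15, module_sizes = 25L,
    module_corr = 0.85, seed = 21))
  mods <- truth_modules(sim)
  spread <- function(n_perm) {
    zs <- vapply(1:8, function(s) {
      module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                          n_perm = n_perm, seed = s)$zsummary
    }, numeric(1))
    sd(zs)
  }
  expect_lt(spread(400), spread(50))
})

test_that("classification thresholds follow the stated rule", {
  fake <- tibble::tibble(module = 1:5,
                         zsummary = c(-0.1, 0, 1.0, 2.0, 7.3))
  cls <- classify_modules(fake)
  expect_equal(cls$class,
               c("on", "indeterminate", "indeterminate", "conserved",
                 "conserved"))
})

test_that("tiny modules are skipped with a warning", {
  sim <- simulate_expression(sim_config(
    n_genes = 50, n_samples_per_group = 10, module_sizes = c(20L, 2L),
    module_corr = 0.9, seed = 22))
  mods <- truth_modules(sim)
  expect_warning(
    pres <- module_preservation(sim$expr$sham, sim$expr$drugA, mods,
                                n_perm = 50, seed = 1),
    "fewer than 3")
  expect_false(2L %in% pres$module)
})

test_that("the synergy rule reproduces the worked example", {
  rep <- identify_sy_modules(combo_vs_sham = c(6, 7, 8, 10),
                             combo_vs_drugA = 8,
                             combo_vs_drugB = c(1, 7, 10))
  expect_identical(rep$sy_modules, c(7L, 8L, 10L))
  expect_true(all(rep$sy_modules %in% rep$on_vs_sham))
})

test_that("empty comparisons give no synergy modules", {
  rep <- identify_sy_modules(integer(0), integer(0), integer(0))
  expect_length(rep$sy_modules, 0)
})

test_that("preservation results feed the synergy rule end to end", {
  cfg <- sim_config(n_genes = 120, n_samples_per_group = 20,
                    module_sizes = rep(30L, 3L), module_corr = 0.9,
                    disruption_map = list(sham = 3L, drugA = 3L, drugB = 3L),
                    seed = 23)
  sim <- simulate_expression(cfg)
  mods <- truth_modules(sim)
  pres <- lapply(c("sham", "drugA", "drugB"), function(g) {
    module_preservation(sim$expr$combo, sim$expr[[g]], mods,
                        n_perm = 100, seed = 7)
  })
  rep <- identify_sy_modules(pres[[1]], pres[[2]], pres[[3]])
  expect_identical(rep$sy_modules, 3L)
})

test_that("mismatched module universes are rejected", {
  p1 <- tibble::tibble(module = 1:3, zsummary = c(-1, 1, 3))
  p2 <- tibble::tibble(module = 1:4, zsummary = c(-1, 1, 3, 0))
  expect_error(identify_sy_modules(p1, p2, p1), "different module sets")
})
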