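# Shared fixtures, built in code at test time.

# Path graph 1-2-3-4-5 with character names.
path5 <- function() {
  igraph::make_graph(~ 1 - 2 - 3 - 4 - 5)
}

# Star with named center and four leaves.
star5 <- function() {
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("c", "l1", "l2", "l3", "l4")
  g
}

# 4-cycle a-x-b-y-a.
cycle4 <- function() {
  igraph::make_graph(~ a - x, x - b, b - y, y - a)
}

# Small expression matrix with one planted module of `size` genes
# (loading r) plus `n_noise` independent genes.
one_module_expr <- function(size = 20L, n_noise = 20L, r = 0.9,
                            n_samples = 50L, seed = 1L) {
  sim <- simulate_expression(sim_config(
    n_genes = size + n_noise, n_samples_per_group = n_samples,
    module_sizes = size, module_corr = r, seed = seed))
  sim
}

# Ground-truth module assignment as a dims_modules-compatible tibble.
truth_modules <- function(sim) {
  out <- sim$truth$modules
  class(out) <- c("dims_modules", class(out))
  out
}
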