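#' Simulation configuration for the synthetic modular-screening world
#'
#' Bundles every knob of the synthetic data generator: a four-group
#' expression design (sham, two single drugs, their combination) with
#' latent-factor co-expression modules, module disruptions, planted
#' differential expression, and a scale-free interaction network with
#' planted target sets and bridge nodes.
#'
#' The expression model is a one-factor Gaussian per module: for a gene in
#' module m with loading r, sample s,
#' \deqn{x = \mu + \sigma (r\, e_m(s) + \sqrt{1-r^2}\,\epsilon) + \delta,}
#' where \eqn{e_m(s)} and \eqn{\epsilon} are independent standard normals,
#' \eqn{\sigma} = `noise_sd`, and \eqn{\delta} is the planted log2 effect.
#' Within-module Pearson correlation is therefore \eqn{r^2} by construction.
#' Disrupting a module in a group replaces its loading by `r_disrupted`
#' (default 0), which destroys the co-expression while keeping the module
#' labels meaningful.
#'
#' @param n_genes Number of genes in the expression universe.
#' @param n_samples_per_group Samples per group.
#' @param groups Ordered group labels; the first is the untreated reference.
#' @param module_sizes Integer sizes of planted modules; their sum must not
#'   exceed `n_genes`. Remaining genes are unassigned pure noise.
#' @param module_corr Per-module latent-factor loading r in \[0, 1\]
#'   (recycled to `length(module_sizes)`).
#' @param disruption_map Named list, group -> integer vector of module ids
#'   whose loading is replaced by `r_disrupted` in that group only.
#' @param r_disrupted Replacement loading for disrupted modules.
#' @param deg_map Named list, group -> data frame with columns `gene` and
#'   `delta` (additive log2 effect vs the reference group).
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param baseline_mean Baseline log2 expression added to every value.
#' @param network_model `"barabasi_albert"` or `"configuration"`.
#' @param network_n Number of network nodes (named to overlap the gene
#'   universe, so expression genes map onto the network).
#' @param network_param Model parameter: edges per new node for
#'   Barabasi-Albert; power-law exponent for the configuration model.
#' @param target_set_spec List with `size_a`, `size_b`, `mode`
#'   (`"overlapping"`, `"separated"`, or `"explicit"`); for overlapping
#'   mode also `overlap_frac` (fraction of set B shared with set A); for
#'   explicit mode `nodes_a` and `nodes_b` name the planted node sets
#'   directly (used when the target sets must coincide with expression
#'   module genes).
#' @param n_bridges Number of planted bridge nodes wired to both target
#'   sets so that many A-B shortest paths traverse them.
#' @param seed Integer master seed; every draw derives from it.
#'
#' @return A `dims_sim_config` list, validated.
#' @seealso [simulate_expression()], [simulate_network()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$module_sizes
sim_config <- function(n_genes = 200L,
                       n_samples_per_group = 20L,
                       groups = c("sham", "drugA", "drugB", "combo"),
                       module_sizes = rep(30L, 5L),
                       module_corr = 0.9,
                       disruption_map = list(),
                       r_disrupted = 0,
                       deg_map = list(),
                       noise_sd = 0.3,
                       baseline_mean = 8,
                       network_model = c("barabasi_albert", "configuration"),
                       network_n = 500L,
                       network_param = 3,
                       target_set_spec = list(size_a = 20L, size_b = 20L,
                                              mode = "separated",
                                              overlap_frac = 0.3),
                       n_bridges = 2L,
                       seed = 1L) {
  network_model <- match.arg(network_model)
  module_corr <- rep_len(module_corr, length(module_sizes))
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = as.character(groups),
    module_sizes = as.integer(module_sizes),
    module_corr = as.numeric(module_corr),
    disruption_map = disruption_map,
    r_disrupted = as.numeric(r_disrupted),
    deg_map = deg_map,
    noise_sd = as.numeric(noise_sd),
    baseline_mean = as.numeric(baseline_mean),
    network_model = network_model,
    network_n = as.integer(network_n),
    network_param = network_param,
    target_set_spec = target_set_spec,
    n_bridges = as.integer(n_bridges),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "dims_sim_config")
}

validate_sim_config <- function(cfg) {
  if (sum(cfg$module_sizes) > cfg$n_genes) {
    abort("sum(module_sizes) must not exceed n_genes.")
  }
  if (any(cfg$module_corr < 0 | cfg$module_corr > 1)) {
    abort("All module loadings must lie in [0, 1].")
  }
  if (cfg$r_disrupted < 0 || cfg$r_disrupted > 1) {
    abort("r_disrupted must lie in [0, 1].")
  }
  if (cfg$noise_sd <= 0) abort("noise_sd must be positive.")
  if (cfg$network_n < 10L) abort("network_n must be at least 10.")
  bad_groups <- setdiff(names(cfg$disruption_map), cfg$groups)
  if (length(bad_groups)) {
    abort(sprintf("disruption_map names unknown group(s): %s",
                  paste(bad_groups, collapse = ", ")))
  }
  bad_groups <- setdiff(names(cfg$deg_map), cfg$groups)
  if (length(bad_groups)) {
    abort(sprintf("deg_map names unknown group(s): %s",
                  paste(bad_groups, collapse = ", ")))
  }
  n_mod <- length(cfg$module_sizes)
  for (g in names(cfg$disruption_map)) {
    ids <- cfg$disruption_map[[g]]
    if (any(ids < 1L | ids > n_mod)) {
      abort(sprintf("disruption_map[['%s']] references unknown module ids.", g))
    }
  }
  spec <- cfg$target_set_spec
  if (!spec$mode %in% c("overlapping", "separated", "explicit")) {
    abort("target_set_spec$mode must be 'overlapping', 'separated' or 'explicit'.")
  }
  if (spec$mode == "explicit" &&
      (is.null(spec$nodes_a) || is.null(spec$nodes_b))) {
    abort("Explicit target sets require nodes_a and nodes_b.")
  }
  invisible(cfg)
}

#' @export
print.dims_sim_config <- function(x, ...) {
  cat("<dims_sim_config>\n")
  cat(sprintf("  %d genes x %d samples/group; groups: %s\n",
              x$n_genes, x$n_samples_per_group, paste(x$groups, collapse = ", ")))
  cat(sprintf("  modules: %s (loadings %s)\n",
              paste(x$module_sizes, collapse = "/"),
              paste(format(x$module_corr), collapse = "/")))
  if (length(x$disruption_map)) {
    for (g in names(x$disruption_map)) {
      cat(sprintf("  disrupted in %s: module(s) %s\n", g,
                  paste(x$disruption_map[[g]], collapse = ", ")))
    }
  }
  cat(sprintf("  network: %s, n = %d, param = %s; targets %s; %d bridge(s)\n",
              x$network_model, x$network_n, format(x$network_param),
              x$target_set_spec$mode, x$n_bridges))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Configuration of the planted-synergy stated world
#'
#' The default end-to-end fixture, mirroring the logic of the screened
#' four-group design:
#' * modules 1 and 2 are co-expressed in every group (conserved);
#' * module 3 is co-expressed only under drug A (the drug-A response
#'   module: disrupted in sham, drug B and the combination);
#' * module 4 is co-expressed only under drug B;
#' * module 5 is co-expressed only under the combination treatment, making
#'   it the unique planted synergy module: non-preserved versus sham and
#'   versus both single drugs.
#'
#' Each treated group also carries planted 1.5-fold differentially
#' expressed genes. The interaction network plants the drug-A and drug-B
#' response module genes as the two target sets and wires bridge nodes to
#' both, so the bridges carry the cross-set shortest-path traffic.
#'
#' @param seed Integer master seed.
#' @param n_degs Planted DEGs per treated group.
#' @return A [sim_config()] object.
#' @export
synergy_config <- function(seed = 1L, n_degs = 15L) {
  genes <- function(i) sprintf("g%04d", i)
  deg_delta <- log2(1.5)
  # module gene blocks under the default sizes rep(30, 5)
  mod3 <- genes(61:90)
  mod4 <- genes(91:120)
  sim_config(
    disruption_map = list(
      sham  = c(3L, 4L, 5L),
      drugA = c(4L, 5L),
      drugB = c(3L, 5L),
      combo = c(3L, 4L)
    ),
    deg_map = list(
      drugA = data.frame(gene = genes(1:n_degs), delta = deg_delta),
      drugB = data.frame(gene = genes(31:(30 + n_degs)), delta = deg_delta),
      combo = data.frame(gene = genes(c(1:n_degs, 31:(30 + n_degs))),
                         delta = deg_delta)
    ),
    target_set_spec = list(size_a = 30L, size_b = 30L, mode = "explicit",
                           nodes_a = mod3, nodes_b = mod4),
    seed = seed
  )
}
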