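#' Simulate grouped expression data with planted modules
#'
#' Draws one genes x samples log2 expression matrix per group from the
#' one-factor module model described in [sim_config()]. Module factors are
#' redrawn independently per group, so co-expression (not expression level)
#' is what modules share across groups; disruptions replace the factor
#' loading in the named group only; planted differential expression adds a
#' constant log2 offset relative to the reference group.
#'
#' @param config A [sim_config()] object.
#' @return A `dims_sim` list with elements
#'   * `expr`: named list of genes x samples matrices, one per group;
#'   * `group_map`: tibble with columns `sample`, `group`;
#'   * `truth`: `dims_ground_truth` list (module membership, per-group
#'     disrupted modules, per-group DEG tables).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 7))
#' dim(sim$expr$sham)
simulate_expression <- function(config) {
  stopifnot(inherits(config, "dims_sim_config"))
  validate_sim_config(config)

  gene_ids <- sprintf("g%04d", seq_len(config$n_genes))
  module <- integer(config$n_genes)
  pos <- 1L
  for (m in seq_along(config$module_sizes)) {
    sz <- config$module_sizes[m]
    module[pos:(pos + sz - 1L)] <- m
    pos <- pos + sz
  }
  names(module) <- gene_ids

  n <- config$n_samples_per_group
  expr <- list()
  for (gi in seq_along(config$groups)) {
    g <- config$groups[gi]
    set.seed(derive_seed(config$seed, paste0("expr-", g)))
    loadings <- config$module_corr
    if (g %in% names(config$disruption_map)) {
      loadings[config$disruption_map[[g]]] <- config$r_disrupted
    }
    factors <- matrix(rnorm(length(config$module_sizes) * n),
                      nrow = length(config$module_sizes))
    eps <- matrix(rnorm(config$n_genes * n), nrow = config$n_genes)
    x <- matrix(config$baseline_mean, nrow = config$n_genes, ncol = n)
    for (j in seq_len(config$n_genes)) {
      m <- module[j]
      if (m > 0L) {
        r <- loadings[m]
        x[j, ] <- x[j, ] + config$noise_sd *
          (r * factors[m, ] + sqrt(1 - r^2) * eps[j, ])
      } else {
        x[j, ] <- x[j, ] + config$noise_sd * eps[j, ]
      }
    }
    if (g %in% names(config$deg_map)) {
      dm <- config$deg_map[[g]]
      idx <- match(dm$gene, gene_ids)
      if (anyNA(idx)) abort(sprintf("deg_map[['%s']] names unknown genes.", g))
      x[idx, ] <- x[idx, ] + dm$delta
    }
    dimnames(x) <- list(gene_ids, sprintf("%s_s%02d", g, seq_len(n)))
    expr[[g]] <- x
  }

  group_map <- purrr::map_dfr(config$groups, function(g) {
    tibble::tibble(sample = colnames(expr[[g]]), group = g)
  })

  truth <- structure(list(
    modules = tibble::tibble(gene = gene_ids, module = unname(module)),
    disrupted = config$disruption_map,
    degs = lapply(config$deg_map, function(d) tibble::as_tibble(d)),
    target_a = character(),
    target_b = character(),
    bridges = character()
  ), class = "dims_ground_truth")

  structure(list(expr = expr, group_map = group_map, truth = truth),
            class = "dims_sim")
}

#' Simulate a scale-free interaction network with planted target sets
#'
#' Generates an undirected simple connected graph (Barabasi-Albert
#' preferential attachment, or a power-law configuration model with bounded
#' retries on disconnection), then plants two target node sets per
#' `config$target_set_spec`:
#' * `"overlapping"`: set B shares `overlap_frac` of its nodes with set A
#'   and draws the rest from A's immediate neighborhood, so the separation
#'   score of the pair is negative by construction;
#' * `"separated"`: the sets are grown around two mutually far nodes, are
#'   disjoint, and no A-B edge exists, so every cross distance is at least 2
#'   and the separation score is positive.
#'
#' `n_bridges` extra nodes are then appended, each wired to every node of A
#' and of B, so that length-2 A-bridge-B paths dominate the A-B shortest
#' paths and the bridges carry maximal flow centrality.
#'
#' @param config A [sim_config()] object.
#' @return A `dims_simnet` list with `graph` (an igraph object whose node
#'   names overlap the expression gene universe) and `truth` (target sets
#'   `target_a`, `target_b` and `bridges`).
#' @export
#' @examples
#' net <- simulate_network(sim_config(seed = 3))
#' igraph::vcount(net$graph)
simulate_network <- function(config) {
  stopifnot(inherits(config, "dims_sim_config"))
  validate_sim_config(config)

  node_ids <- sprintf("g%04d", seq_len(config$network_n))
  g <- NULL
  for (attempt in 1:10) {
    set.seed(derive_seed(config$seed, paste0("network-", attempt)))
    if (config$network_model == "barabasi_albert") {
      g <- igraph::sample_pa(config$network_n, m = config$network_param,
                             directed = FALSE)
    } else {
      alpha <- config$network_param
      degs <- pmin(round(2 * (1 - stats::runif(config$network_n))^(-1 / (alpha - 1))),
                   config$network_n %/% 4L)
      if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1
      g <- igraph::simplify(
        igraph::sample_degseq(degs, method = "configuration")
      )
    }
    g <- igraph::simplify(g)
    if (igraph::is_connected(g)) break
    g <- NULL
  }
  if (is.null(g)) {
    abort("Could not generate a connected network within 10 attempts.")
  }
  igraph::V(g)$name <- node_ids

  set.seed(derive_seed(config$seed, "targets"))
  spec <- config$target_set_spec
  d <- igraph::distances(g)
  sets <- switch(spec$mode,
    separated = plant_separated_sets(g, d, spec),
    overlapping = plant_overlapping_sets(g, d, spec),
    explicit = {
      missing <- setdiff(c(spec$nodes_a, spec$nodes_b), node_ids)
      if (length(missing)) {
        abort(sprintf("Explicit target nodes absent from the network: %s",
                      paste(head(missing, 5L), collapse = ", ")))
      }
      list(a = unique(spec$nodes_a), b = unique(spec$nodes_b))
    })

  bridges <- character()
  if (config$n_bridges > 0L) {
    bridges <- sprintf("bridge%d", seq_len(config$n_bridges))
    g <- igraph::add_vertices(g, config$n_bridges, name = bridges)
    anchor <- unique(c(sets$a, sets$b))
    edges <- as.vector(t(as.matrix(expand.grid(bridges, anchor,
                                               stringsAsFactors = FALSE))))
    g <- igraph::add_edges(g, edges)
  }
  if (!igraph::is_connected(g)) {
    abort("Planting disconnected the network; this should not happen.")
  }

  truth <- structure(list(
    modules = tibble::tibble(gene = character(), module = integer()),
    disrupted = list(),
    degs = list(),
    target_a = sets$a,
    target_b = sets$b,
    bridges = bridges
  ), class = "dims_ground_truth")

  structure(list(graph = g, truth = truth), class = "dims_simnet")
}

# Grow A and B around two mutually far nodes; keep them disjoint and
# non-adjacent so every cross distance is >= 2 and separation is positive.
plant_separated_sets <- function(g, d, spec) {
  n <- nrow(d)
  u0 <- sample.int(n, 1L)
  v1 <- which.max(d[u0, ])
  v2 <- which.max(d[v1, ])
  ord_a <- order(d[v1, ], seq_len(n))
  a_idx <- ord_a[seq_len(spec$size_a)]
  dist_to_a <- apply(d[, a_idx, drop = FALSE], 1L, min)
  cand <- setdiff(order(d[v2, ], seq_len(n)), a_idx)
  cand <- cand[dist_to_a[cand] >= 2]
  if (length(cand) < spec$size_b) {
    abort("Network too small to plant separated target sets.")
  }
  b_idx <- cand[seq_len(spec$size_b)]
  list(a = rownames(d)[a_idx], b = rownames(d)[b_idx])
}

# Set B shares overlap_frac of its nodes with A; the rest sit in A's
# immediate neighborhood, forcing the cross distances below the
# within-set distances and hence a negative separation.
plant_overlapping_sets <- function(g, d, spec) {
  n <- nrow(d)
  deg <- igraph::degree(g)
  hubs <- which(deg >= median(deg))
  u <- sample(hubs, 1L)
  ord <- order(d[u, ], seq_len(n))
  a_idx <- ord[seq_len(spec$size_a)]
  n_shared <- max(1L, round((spec$overlap_frac %||% 0.3) * spec$size_b))
  shared <- a_idx[seq_len(min(n_shared, length(a_idx)))]
  dist_to_a <- apply(d[, a_idx, drop = FALSE], 1L, min)
  cand <- setdiff(seq_len(n)[order(dist_to_a, d[u, ], seq_len(n))], a_idx)
  b_idx <- c(shared, cand[seq_len(spec$size_b - length(shared))])
  list(a = rownames(d)[a_idx], b = rownames(d)[b_idx])
}

#' @export
print.dims_sim <- function(x, ...) {
  cat("<dims_sim>\n")
  cat(sprintf("  groups: %s\n", paste(names(x$expr), collapse = ", ")))
  cat(sprintf("  %d genes x %d samples per group\n",
              nrow(x$expr[[1]]), ncol(x$expr[[1]])))
  cat(sprintf("  planted modules: %d\n", max(x$truth$modules$module)))
  invisible(x)
}

#' @export
print.dims_simnet <- function(x, ...) {
  cat("<dims_simnet>\n")
  cat(sprintf("  %d nodes, %d edges; |A| = %d, |B| = %d, %d bridge(s)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              length(x$truth$target_a), length(x$truth$target_b),
              length(x$truth$bridges)))
  invisible(x)
}
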