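# Interaction-network computations: 'closest'-measure separation between
# two target sets, size-normalized mean pairwise distance, flow centrality
# by shortest-path counting, and a per-gene total distance score. All
# distances are unweighted hop counts (BFS).

#' Build an interaction network from edges, a file, or an igraph object
#'
#' Coerces to an undirected simple graph (self-loops and multi-edges
#' removed). By default the graph is restricted to its largest connected
#' component so that distance-based queries are well defined; set
#' `lcc = FALSE` to keep everything (disconnected pairs are then skipped
#' and counted by the individual measures).
#'
#' @param x An igraph object, a two-column edge data frame, or a path to a
#'   two-column TSV / SIF edge list.
#' @param lcc Restrict to the largest connected component?
#' @return An igraph object with named vertices.
#' @export
#' @examples
#' g <- interaction_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' igraph::vcount(g)
interaction_network <- function(x, lcc = TRUE) {
  g <- if (inherits(x, "igraph")) {
    x
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    edges <- read_edge_list(x)
    igraph::graph_from_data_frame(edges, directed = FALSE)
  } else if (is.data.frame(x)) {
    igraph::graph_from_data_frame(x[, 1:2], directed = FALSE)
  } else {
    abort("Cannot interpret `x` as an interaction network.")
  }
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  if (lcc && !igraph::is_connected(g)) {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    warn(sprintf("Restricting to the largest connected component (%d of %d nodes).",
                 length(keep), igraph::vcount(g)))
    g <- igraph::induced_subgraph(g, keep)
  }
  g
}

# Map a gene set onto network nodes, warning with the dropped names.
map_gene_set <- function(g, genes, label) {
  genes <- unique(as.character(genes))
  present <- genes %in% igraph::V(g)$name
  if (any(!present)) {
    warn(sprintf("Dropping %d gene(s) from set %s absent from the network: %s",
                 sum(!present), label,
                 paste(head(genes[!present], 5L), collapse = ", ")))
  }
  genes[present]
}

#' Separation of two target sets on the interaction network
#'
#' The 'closest'-measure separation
#' \deqn{S_{AB} = d_{AB} - \frac{d_{AA} + d_{BB}}{2},}
#' where \eqn{d_{AB}} is the mean over all members of the distance to the
#' nearest member of the other set, and \eqn{d_{AA}}, \eqn{d_{BB}} are the
#' mean nearest-other-member distances within each set (self excluded).
#' Shared nodes contribute 0 to \eqn{d_{AB}}. Negative \eqn{S_{AB}} means
#' the two target neighborhoods overlap (the network signature of a
#' complementary, potentially synergistic pair); positive means they are
#' topologically isolated from each other.
#'
#' @param net An igraph network (or anything [interaction_network()]
#'   accepts).
#' @param a,b Character vectors of gene ids (>= 2 mapped nodes each).
#' @param lcc Restrict to the largest connected component first (default);
#'   with `lcc = FALSE` disconnected pairs are skipped and counted where
#'   the measure allows it, or raise an error where it does not.
#' @return A one-row `dims_separation` tibble: `d_ab`, `d_aa`, `d_bb`,
#'   `s_ab`, `n_mapped_a`, `n_mapped_b`, `n_dropped`.
#' @export
#' @examples
#' path <- igraph::make_graph(~ 1 - 2 - 3 - 4 - 5)
#' separation(path, c("1", "2"), c("4", "5"))$s_ab
separation <- function(net, a, b, lcc = TRUE) {
  g <- interaction_network(net, lcc = lcc)
  a0 <- unique(as.character(a)); b0 <- unique(as.character(b))
  a <- map_gene_set(g, a0, "A")
  b <- map_gene_set(g, b0, "B")
  n_dropped <- (length(a0) - length(a)) + (length(b0) - length(b))
  if (length(a) < 2L || length(b) < 2L) {
    abort("Each set must map to at least 2 network nodes (within-set distance undefined for singletons).")
  }
  d_cross <- igraph::distances(g, v = a, to = b)
  if (all(is.infinite(d_cross))) {
    abort("No connectivity between sets A and B (different components).")
  }
  min_a <- apply(d_cross, 1L, min)
  min_b <- apply(d_cross, 2L, min)
  if (any(is.infinite(c(min_a, min_b)))) {
    abort("Some members have no path to the other set (different components).")
  }
  d_ab <- (sum(min_a) + sum(min_b)) / (length(a) + length(b))
  d_aa <- mean_nearest_within(g, a)
  d_bb <- mean_nearest_within(g, b)
  out <- tibble::tibble(
    d_ab = d_ab, d_aa = d_aa, d_bb = d_bb,
    s_ab = d_ab - (d_aa + d_bb) / 2,
    n_mapped_a = length(a), n_mapped_b = length(b),
    n_dropped = n_dropped)
  new_dims_result(out, "dims_separation")
}

mean_nearest_within <- function(g, s) {
  d <- igraph::distances(g, v = s, to = s)
  diag(d) <- Inf
  m <- apply(d, 1L, min)
  if (any(is.infinite(m))) {
    abort("A set member has no path to any other member of its set.")
  }
  mean(m)
}

#' Size-normalized mean shortest distance between two modules
#'
#' \deqn{d^{shortest}_{I(A)I(B)} = \frac{1}{|I(A)||I(B)|}
#'   \sum_{a \in I(A), b \in I(B)} d(a, b)} over connected pairs;
#' disconnected pairs are skipped and counted rather than given a
#' pseudo-distance.
#'
#' @inheritParams separation
#' @return A one-row `dims_module_distance` tibble: `d_shortest`,
#'   `pairs_used`, `pairs_skipped`.
#' @export
module_shortest_distance <- function(net, a, b, lcc = TRUE) {
  g <- interaction_network(net, lcc = lcc)
  a <- map_gene_set(g, a, "A")
  b <- map_gene_set(g, b, "B")
  if (length(a) < 1L || length(b) < 1L) abort("Empty mapped set.")
  d <- igraph::distances(g, v = a, to = b)
  used <- is.finite(d)
  if (!any(used)) abort("All A-B pairs are disconnected.")
  out <- tibble::tibble(
    d_shortest = mean(d[used]),
    pairs_used = sum(used),
    pairs_skipped = sum(!used))
  new_dims_result(out, "dims_module_distance")
}

#' Flow centrality of candidate nodes between two target sets
#'
#' For node v and sets A, B,
#' \deqn{FC_{A,B}(v) = \frac{1}{|A||B|} \sum_{a \in A, b \in B}
#'   \frac{\sigma_{ab}(v)}{\sigma_{ab}},}
#' where \eqn{\sigma_{ab}} counts the a-b shortest paths and
#' \eqn{\sigma_{ab}(v)} those passing through v. Pairs with a = b, pairs in
#' different components, and (per candidate) pairs with v as an endpoint
#' are skipped. Both the raw pair-sum `fc_raw` and the per-usable-pair
#' normalization `fc_norm` are reported; driver ranking defaults to the raw
#' sum, whose magnitude grows with the number of pairs served.
#'
#' @inheritParams separation
#' @param candidates Character vector of candidate nodes; default all
#'   network nodes.
#' @return A `dims_flow` tibble: `gene`, `fc_raw`, `fc_norm`,
#'   `pairs_used`; attribute `pairs_total` (|A| x |B|) and `pairs_skipped`
#'   (identical or disconnected pairs, before the per-candidate endpoint
#'   rule).
#' @export
#' @examples
#' star <- igraph::make_star(5, mode = "undirected", center = 1)
#' igraph::V(star)$name <- c("c", "l1", "l2", "l3", "l4")
#' fc <- flow_centrality(star, c("l1", "l2"), c("l3", "l4"))
#' fc[fc$gene == "c", ]
flow_centrality <- function(net, a, b, candidates = NULL, lcc = TRUE) {
  g <- interaction_network(net, lcc = lcc)
  a <- map_gene_set(g, a, "A")
  b <- map_gene_set(g, b, "B")
  if (!length(a) || !length(b)) abort("Empty mapped target set.")
  nodes <- igraph::V(g)$name
  candidates <- if (is.null(candidates)) nodes else map_gene_set(g, candidates, "candidates")
  if (!length(candidates)) abort("Empty candidate set.")

  sources <- unique(c(a, b))
  bfs <- lapply(sources, function(s) bfs_path_counts(g, s))
  names(bfs) <- sources

  n_cand <- length(candidates)
  fc_raw <- numeric(n_cand)
  usable <- integer(n_cand)
  names(fc_raw) <- names(usable) <- candidates
  skipped <- 0L
  for (aa in a) {
    da <- bfs[[aa]]$dist; sa <- bfs[[aa]]$sigma
    for (bb in b) {
      if (aa == bb || is.infinite(da[bb])) {
        skipped <- skipped + 1L
        next
      }
      db <- bfs[[bb]]$dist; sb <- bfs[[bb]]$sigma
      d_ab <- da[bb]
      sigma_ab <- sa[bb]
      v <- candidates
      on_path <- (da[v] + db[v]) == d_ab
      frac <- ifelse(on_path, sa[v] * sb[v] / sigma_ab, 0)
      endpoint <- v == aa | v == bb
      frac[endpoint] <- 0
      fc_raw <- fc_raw + frac
      usable <- usable + as.integer(!endpoint)
    }
  }
  out <- tibble::tibble(
    gene = candidates,
    fc_raw = unname(fc_raw),
    fc_norm = unname(ifelse(usable > 0, fc_raw / usable, NA_real_)),
    pairs_used = unname(usable))
  new_dims_result(out, "dims_flow",
                  pairs_total = length(a) * length(b),
                  pairs_skipped = skipped,
                  set_sizes = c(n_a = length(a), n_b = length(b)))
}

# BFS distances and shortest-path counts from one source. sigma[v] is the
# number of distinct shortest s-v paths, accumulated level by level:
# sigma[v] = sum of sigma[u] over neighbors u one level closer to s.
bfs_path_counts <- function(g, s) {
  nodes <- igraph::V(g)$name
  dist <- igraph::distances(g, v = s)[1L, nodes]
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  sigma <- setNames(numeric(length(nodes)), nodes)
  sigma[s] <- 1
  maxd <- max(dist[is.finite(dist)])
  if (maxd >= 1) {
    for (lev in seq_len(maxd)) {
      prev <- sigma * (dist == lev - 1)
      contrib <- as.vector(adj %*% prev)
      at_lev <- which(dist == lev)
      sigma[at_lev] <- contrib[at_lev]
    }
  }
  list(dist = dist, sigma = sigma)
}

#' Total distance from one gene to the members of two target sets
#'
#' \eqn{\sum_{u \in (A \cup B) \setminus \{v\}} d(v, u)} over reachable u.
#' This reconstructs a per-gene "shortest distance" score used to rank
#' driver candidates: small totals mean the gene sits close to both target
#' neighborhoods.
#'
#' @inheritParams separation
#' @param v A single gene id present in the network.
#' @return A one-row tibble: `gene`, `total_distance`, `n_reachable`,
#'   `n_unreachable`.
#' @export
gene_total_distance <- function(net, v, a, b, lcc = TRUE) {
  g <- interaction_network(net, lcc = lcc)
  v <- as.character(v)
  if (!v %in% igraph::V(g)$name) abort(sprintf("Gene '%s' is not in the network.", v))
  targets <- setdiff(unique(c(map_gene_set(g, a, "A"), map_gene_set(g, b, "B"))), v)
  d <- igraph::distances(g, v = v, to = targets)[1L, ]
  reach <- is.finite(d)
  if (!any(reach)) abort(sprintf("Gene '%s' is unreachable from all of A and B.", v))
  tibble::tibble(gene = v,
                 total_distance = sum(d[reach]),
                 n_reachable = sum(reach),
                 n_unreachable = sum(!reach))
}

# Vectorized total-distance scores for many candidates (used by
# rank_drivers); unreachable targets are skipped per candidate.
total_distance_scores <- function(g, candidates, a, b) {
  targets <- unique(c(a, b))
  d <- igraph::distances(g, v = candidates, to = targets)
  finite <- is.finite(d)  # d(v, v) = 0, so a candidate inside the targets
                          # contributes nothing for its own entry
  tibble::tibble(
    gene = candidates,
    total_distance = rowSums(ifelse(finite, d, 0)),
    n_reachable = rowSums(finite) - as.integer(candidates %in% targets))
}
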