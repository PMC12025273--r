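# Driver prioritization: union of the top-k genes by ascending total
# shortest distance and by descending flow centrality between the two
# single-drug target neighborhoods.

#' Rank driver-gene candidates by network proximity indices
#'
#' Scores every candidate by (i) its total shortest distance to the members
#' of the two target sets ([gene_total_distance()]; smaller = closer) and
#' (ii) its flow centrality between the sets ([flow_centrality()];
#' larger = more of the A-B shortest-path traffic). The driver set is the
#' union of the two top-k lists; genes in both lists are the "common"
#' drivers, so `|drivers| = 2k - |common|` always. Ties are broken by score
#' and then lexicographically by gene id, making the ranking deterministic.
#'
#' @inheritParams separation
#' @param candidates Candidate pool; default all network nodes (drivers,
#'   like bridge nodes, need not belong to A or B).
#' @param k Size of each top list (default 10, clamped to the pool size
#'   with a warning).
#' @param fc_column Which flow-centrality column ranks the genes:
#'   `"raw"` (pair-sum, default) or `"norm"` (per-pair average).
#' @return A `dims_drivers` tibble: `gene`, `total_distance`, `fc_raw`,
#'   `fc_norm`, `rank_distance`, `rank_fc`, `in_top_distance`, `in_top_fc`,
#'   `driver`, `common`; attributes `top_k_distance`, `top_k_fc`,
#'   `drivers`, `common`, `k`.
#' @export
#' @examples
#' net <- simulate_network(sim_config(seed = 11))
#' rk <- rank_drivers(net$graph, net$truth$target_a, net$truth$target_b, k = 5)
#' attr(rk, "common")
rank_drivers <- function(net, a, b, candidates = NULL, k = 10L,
                         fc_column = c("raw", "norm"), lcc = TRUE) {
  fc_column <- match.arg(fc_column)
  g <- interaction_network(net, lcc = lcc)
  a <- map_gene_set(g, a, "A")
  b <- map_gene_set(g, b, "B")
  candidates <- if (is.null(candidates)) {
    igraph::V(g)$name
  } else {
    map_gene_set(g, candidates, "candidates")
  }
  candidates <- sort(unique(candidates))
  if (!length(candidates)) abort("Empty candidate set.")
  if (k > length(candidates)) {
    warn(sprintf("k = %d exceeds the candidate pool (%d); clamping.",
                 k, length(candidates)))
    k <- length(candidates)
  }

  dist_scores <- total_distance_scores(g, candidates, a, b)
  flow <- flow_centrality(g, a, b, candidates = candidates, lcc = FALSE)
  scores <- dist_scores |>
    left_join(tibble::as_tibble(flow), by = "gene")

  fc_score <- if (fc_column == "raw") scores$fc_raw else scores$fc_norm
  ord_dist <- order(scores$total_distance, scores$gene)
  ord_fc <- order(-fc_score, scores$gene)
  rank_distance <- integer(nrow(scores)); rank_distance[ord_dist] <- seq_len(nrow(scores))
  rank_fc <- integer(nrow(scores)); rank_fc[ord_fc] <- seq_len(nrow(scores))

  top_dist <- scores$gene[ord_dist][seq_len(k)]
  top_fc <- scores$gene[ord_fc][seq_len(k)]
  drivers <- union(top_dist, top_fc)
  common <- intersect(top_dist, top_fc)

  out <- scores |>
    mutate(rank_distance = rank_distance,
           rank_fc = rank_fc,
           in_top_distance = .data$gene %in% top_dist,
           in_top_fc = .data$gene %in% top_fc,
           driver = .data$gene %in% drivers,
           common = .data$gene %in% common) |>
    arrange(.data$rank_fc)
  new_dims_result(out, "dims_drivers",
                  top_k_distance = top_dist, top_k_fc = top_fc,
                  drivers = drivers, common = common, k = as.integer(k),
                  fc_column = fc_column)
}

#' @export
print.dims_drivers <- function(x, ...) {
  cat(sprintf("<dims_drivers> k = %d; %d drivers (%d common, %d specific)\n",
              attr(x, "k"), length(attr(x, "drivers")),
              length(attr(x, "common")),
              length(attr(x, "drivers")) - length(attr(x, "common"))))
  NextMethod()
}
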