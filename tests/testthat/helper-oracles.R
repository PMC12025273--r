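# Independent brute-force oracles for the graph measures. Deliberately
# naive: Floyd-Warshall distances on a plain adjacency matrix and full
# enumeration of simple shortest paths by depth-first search. Nothing here
# shares code with the package implementation (which uses BFS via igraph).

# Floyd-Warshall all-pairs distances from a 0/1 adjacency matrix.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  dimnames(d) <- dimnames(adj)
  d
}

# All shortest simple paths between two nodes, as a list of index vectors.
enumerate_shortest_paths <- function(adj, from, to) {
  d <- fw_distances(adj)
  target_len <- d[from, to]
  if (!is.finite(target_len)) return(list())
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      if (length(path) - 1L == target_len) paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    if (length(path) - 1L >= target_len) return(invisible())
    for (nb in which(adj[last, ] == 1)) {
      if (!nb %in% path) walk(c(path, nb))
    }
  }
  walk(from)
  paths
}

# Oracle separation: directly from the written definition.
oracle_separation <- function(adj, a_idx, b_idx) {
  d <- fw_distances(adj)
  min_to <- function(i, set) min(d[i, set])
  d_ab <- (sum(vapply(a_idx, min_to, numeric(1), set = b_idx)) +
           sum(vapply(b_idx, min_to, numeric(1), set = a_idx))) /
    (length(a_idx) + length(b_idx))
  d_aa <- mean(vapply(a_idx, function(i) min(d[i, setdiff(a_idx, i)]), numeric(1)))
  d_bb <- mean(vapply(b_idx, function(i) min(d[i, setdiff(b_idx, i)]), numeric(1)))
  list(d_ab = d_ab, d_aa = d_aa, d_bb = d_bb, s_ab = d_ab - (d_aa + d_bb) / 2)
}

oracle_module_distance <- function(adj, a_idx, b_idx) {
  d <- fw_distances(adj)
  vals <- as.vector(d[a_idx, b_idx, drop = FALSE])
  mean(vals[is.finite(vals)])
}

# Oracle flow centrality by explicit path enumeration.
oracle_flow <- function(adj, a_idx, b_idx, cand_idx) {
  fc_raw <- setNames(numeric(length(cand_idx)), cand_idx)
  usable <- setNames(integer(length(cand_idx)), cand_idx)
  for (a in a_idx) {
    for (b in b_idx) {
      if (a == b) next
      paths <- enumerate_shortest_paths(adj, a, b)
      if (!length(paths)) next
      for (j in seq_along(cand_idx)) {
        v <- cand_idx[j]
        if (v == a || v == b) next
        usable[j] <- usable[j] + 1L
        hits <- sum(vapply(paths, function(p) v %in% p, logical(1)))
        fc_raw[j] <- fc_raw[j] + hits / length(paths)
      }
    }
  }
  list(fc_raw = fc_raw,
       fc_norm = ifelse(usable > 0, fc_raw / usable, NA_real_),
       usable = usable)
}

oracle_total_distance <- function(adj, v, a_idx, b_idx) {
  d <- fw_distances(adj)
  targets <- setdiff(union(a_idx, b_idx), v)
  vals <- d[v, targets]
  sum(vals[is.finite(vals)])
}

# A random connected simple graph on n nodes (edge probability p),
# returned as a plain adjacency matrix with node names v1..vn.
random_connected_adj <- function(n, p = 0.4) {
  repeat {
    adj <- matrix(0L, n, n)
    upper <- which(upper.tri(adj))
    adj[upper] <- as.integer(runif(length(upper)) < p)
    adj <- adj + t(adj)
    if (all(is.finite(fw_distances(adj)))) break
  }
  dimnames(adj) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
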