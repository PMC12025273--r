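# Weighted co-expression network construction and module detection:
# soft-thresholded |correlation| adjacency, topological overlap, average
# linkage clustering with a fixed-height cut and a minimum module size.

#' Choose a soft-thresholding power by the scale-free fit criterion
#'
#' For each candidate power \eqn{\beta} the weighted connectivity
#' \eqn{k_i = \sum_{j \ne i} |cor(x_i, x_j)|^\beta} is computed, k is binned
#' (equal-occupancy bins), and \eqn{\log_{10} p(k)} is regressed on
#' \eqn{\log_{10} k}. The scale-free topology fit index is the R-squared of
#' that regression (reported as 0 when the slope is non-negative). The
#' chosen power is the smallest one whose fit index reaches `target_r2`
#' (0.8 by default); when no candidate reaches it, the best-fitting power is
#' returned with a warning.
#'
#' @param expr Numeric genes x samples matrix (log2 scale), gene rownames.
#' @param powers Integer candidate powers (at least two).
#' @param target_r2 Fit-index threshold for acceptance.
#' @param n_bins Number of equal-occupancy connectivity bins.
#' @return A `dims_sft` tibble with columns `power`, `sft_r2`, `slope`,
#'   `mean_k`, and attributes `chosen_beta` and `reached_target`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 2))
#' sft <- pick_soft_threshold(sim$expr$combo, powers = c(2, 4, 6, 8))
#' attr(sft, "chosen_beta")
pick_soft_threshold <- function(expr, powers = c(1:10, seq(12L, 20L, 2L)),
                                target_r2 = 0.8, n_bins = 10L) {
  check_expr_matrix(expr)
  if (ncol(expr) < 4L) abort("At least 4 samples are required.")
  if (length(powers) < 2L) abort("Provide at least 2 candidate powers.")
  expr <- drop_zero_variance(expr)
  if (nrow(expr) < 2L) abort("Fewer than 2 usable (non-constant) genes.")

  abs_cor <- abs(cor(t(expr)))
  rows <- purrr::map_dfr(sort(unique(as.integer(powers))), function(beta) {
    k <- rowSums(abs_cor^beta) - 1  # remove the self term
    fit <- scale_free_fit(k, n_bins = n_bins)
    tibble::tibble(power = beta, sft_r2 = fit$r2, slope = fit$slope,
                   mean_k = mean(k))
  })

  hit <- rows$power[rows$sft_r2 >= target_r2]
  reached <- length(hit) > 0L
  if (reached) {
    chosen <- min(hit)
  } else {
    chosen <- rows$power[which.max(rows$sft_r2)]
    warn(sprintf(
      "No candidate power reached the scale-free fit target %.2f; using the best fit (beta = %d, R2 = %.3f).",
      target_r2, chosen, max(rows$sft_r2)))
  }
  new_dims_result(rows, "dims_sft",
                  chosen_beta = chosen, target_r2 = target_r2,
                  reached_target = reached)
}

# Scale-free topology fit: equal-occupancy binning of k, density per bin,
# log-log regression. Returns r2 = 0 when the fitted slope is >= 0.
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  breaks <- unique(quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
  if (length(breaks) < 4L) return(list(r2 = 0, slope = NA_real_))
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  width <- diff(breaks)
  dens <- as.vector(table(bin)) / (length(k) * width)
  keep <- dens > 0 & mean_k > 0
  if (sum(keep) < 3L) return(list(r2 = 0, slope = NA_real_))
  fit <- lm(log10(dens[keep]) ~ log10(mean_k[keep]))
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(r2 = if (is.na(slope) || slope >= 0) 0 else r2, slope = slope)
}

#' Build the weighted co-expression network (adjacency and TOM)
#'
#' Unsigned adjacency \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with unit
#' diagonal, and the topological overlap matrix
#' \deqn{TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},}
#' where \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; \eqn{TOM_{ii} = 1}.
#'
#' @param expr Numeric genes x samples matrix, gene rownames.
#' @param beta Soft-thresholding power (>= 1).
#' @return A `dims_coexpr` list with `genes`, `adjacency`, `tom`, `beta`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 2))
#' net <- build_network(sim$expr$combo, beta = 6)
#' range(net$tom)
build_network <- function(expr, beta) {
  check_expr_matrix(expr)
  if (beta < 1) abort("beta must be >= 1.")
  v <- apply(expr, 1L, var)
  if (any(v <= .Machine$double.eps)) {
    abort("Zero-variance gene(s) present; filter them before build_network().")
  }
  adj <- abs(cor(t(expr)))^beta
  diag(adj) <- 1
  tom <- tom_similarity(adj)
  structure(list(genes = rownames(expr), adjacency = adj, tom = tom,
                 beta = as.integer(beta)),
            class = "dims_coexpr")
}

# TOM from an adjacency with unit diagonal; shared-neighbor term L computed
# with the diagonal zeroed so u != i, j automatically.
tom_similarity <- function(adj) {
  a0 <- adj
  diag(a0) <- 0
  l <- a0 %*% a0
  k <- rowSums(a0)
  kmin <- outer(k, k, pmin)
  tom <- (l + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' @export
print.dims_coexpr <- function(x, ...) {
  cat(sprintf("<dims_coexpr> %d genes, beta = %d, mean TOM = %.4f\n",
              length(x$genes), x$beta, mean(x$tom[upper.tri(x$tom)])))
  invisible(x)
}

#' Detect co-expression modules on the TOM dendrogram
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM.
#' By default the cut height is chosen adaptively: a grid of candidate
#' heights (quantiles of the merge heights) is scanned, each candidate
#' partition keeps only clusters of at least `min_size` genes, and the
#' partition maximizing the size-weighted mean cluster silhouette (on the
#' 1 - TOM scale) wins. Clusters whose mean silhouette falls below
#' `min_silhouette` are then dissolved into the unassigned label 0 — this
#' is the branch-quality criterion that removes chance-correlated small
#' clusters a plain height cut would keep. Passing an explicit
#' `cut_height` bypasses the scan. Modules are renumbered by decreasing
#' size; label 0 (the conventional grey module) collects unassigned genes.
#'
#' @param net A `dims_coexpr` from [build_network()].
#' @param min_size Minimum module size (>= 2); default 3.
#' @param cut_height Optional fixed dendrogram cut height on the 1 - TOM
#'   scale; `NULL` (default) selects the height adaptively.
#' @param min_silhouette Quality floor for a cluster to survive; clusters
#'   with no silhouette contrast score 0 and are dissolved.
#' @return A `dims_modules` tibble with columns `gene`, `module` (0 =
#'   unassigned), `color` (cosmetic alias; grey = unassigned).
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 2))
#' mods <- detect_modules(build_network(sim$expr$combo, beta = 6))
#' table(mods$module)
detect_modules <- function(net, min_size = 3L, cut_height = NULL,
                           min_silhouette = 0.1) {
  stopifnot(inherits(net, "dims_coexpr"))
  if (min_size < 2L) abort("min_size must be >= 2.")
  genes <- net$genes
  if (length(genes) < min_size) {
    warn("Fewer genes than min_size; labeling everything unassigned.")
    labels <- rep(0L, length(genes))
  } else {
    diss <- 1 - net$tom
    tree <- hclust(as.dist(diss), method = "average")
    prune <- function(lab) {
      sizes <- table(lab)
      lab[lab %in% as.integer(names(sizes)[sizes < min_size])] <- 0L
      lab
    }
    if (!is.null(cut_height)) {
      labels <- if (cut_height >= max(tree$height)) {
        rep(1L, length(genes))
      } else {
        unname(cutree(tree, h = cut_height))
      }
      labels <- prune(labels)
    } else {
      heights <- candidate_cut_heights(tree$height)
      best <- NULL
      for (h in heights) {
        lab <- prune(unname(cutree(tree, h = h)))
        if (all(lab == 0L)) next
        sil <- cluster_silhouettes(diss, lab)
        # size-weighted mean cluster silhouette, discounted by the
        # assigned fraction: a partition must not buy tight clusters by
        # shedding most genes into the grey pool
        score <- sum(sil$sil * sil$size) / sum(sil$size) *
          sum(sil$size) / length(lab)
        if (is.null(best) || score > best$score) {
          best <- list(labels = lab, score = score, h = h)
        }
      }
      labels <- if (is.null(best)) rep(0L, length(genes)) else best$labels
      cut_height <- if (is.null(best)) NA_real_ else unname(best$h)
    }
    if (any(labels > 0L)) {
      # Size-aware quality floor: small clusters arise by chance easily and
      # must clear the full bar; clusters of 10+ genes cannot be chance
      # aggregates at these correlations, so a third of the bar suffices.
      sil <- cluster_silhouettes(diss, labels)
      floor_by_size <- ifelse(sil$size >= 10L, min_silhouette / 3,
                              min_silhouette)
      weak <- sil$id[sil$sil < floor_by_size]
      labels[labels %in% weak] <- 0L
    }
    labels <- renumber_by_size(labels)
  }
  out <- tibble::tibble(gene = genes, module = labels,
                        color = module_colors(labels))
  new_dims_result(out, "dims_modules",
                  min_size = as.integer(min_size), cut_height = cut_height,
                  min_silhouette = min_silhouette)
}

# Candidate cut heights: midpoints between consecutive distinct merge
# heights among the top merges (so the gap between within-module and
# between-module merges is always sampled), plus coarser quantile-based
# midpoints lower down for fragmented regimes.
candidate_cut_heights <- function(heights) {
  hs <- sort(unique(heights))
  if (length(hs) < 2L) return(hs)
  upper <- utils::tail(hs, 31L)
  mids_upper <- (utils::head(upper, -1L) + utils::tail(upper, -1L)) / 2
  lower <- unique(quantile(hs, probs = seq(0.25, 0.95, length.out = 15L)))
  sort(unique(c(mids_upper, lower)))
}

# Mean silhouette per cluster on a dissimilarity matrix: for each assigned
# gene, own = mean dissimilarity to its cluster mates, other = smallest
# mean dissimilarity to any OTHER cluster. Contrasting against clusters
# only (not the unassigned pool) keeps a fragmented module from scoring
# well simply because its stray siblings sit in the grey pool; the grey
# pool is used as the contrast only when the partition has a single
# cluster. A partition with one cluster and no unassigned genes has no
# contrast and scores 0.
cluster_silhouettes <- function(diss, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  pools <- as.list(ids)
  if (length(ids) == 1L && any(labels == 0L)) pools <- c(pools, list(0L))
  ind <- vapply(pools, function(p) as.numeric(labels == p),
                numeric(length(labels)))
  counts <- colSums(ind)
  mean_d <- sweep(diss %*% ind, 2L, counts, "/")
  sil_gene <- numeric(length(labels))
  for (j in seq_along(ids)) {
    members <- labels == ids[j]
    n_c <- counts[j]
    own <- if (n_c > 1) (mean_d[members, j] * n_c) / (n_c - 1) else rep(Inf, sum(members))
    other_cols <- setdiff(seq_along(pools), j)
    if (length(other_cols)) {
      oth <- apply(mean_d[members, other_cols, drop = FALSE], 1L, min)
      sil_gene[members] <- (oth - own) / pmax(oth, own)
    } else {
      sil_gene[members] <- 0
    }
  }
  tibble::tibble(
    id = ids,
    size = vapply(ids, function(m) sum(labels == m), numeric(1)),
    sil = vapply(ids, function(m) mean(sil_gene[labels == m]), numeric(1)))
}

# Relabel nonzero clusters 1, 2, ... by decreasing size (ties: first seen).
renumber_by_size <- function(labels) {
  nz <- labels[labels != 0L]
  if (!length(nz)) return(labels)
  sizes <- sort(table(nz), decreasing = TRUE)
  map <- setNames(seq_along(sizes), names(sizes))
  ifelse(labels == 0L, 0L, as.integer(map[as.character(labels)]))
}

module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue")
  ifelse(labels == 0L, "grey",
         ifelse(labels <= length(palette), palette[pmax(labels, 1L)],
                paste0("module", labels)))
}

#' Extract the gene set of one module
#'
#' @param modules A `dims_modules` tibble.
#' @param id Module label (positive integer).
#' @return Character vector of gene ids.
#' @export
module_genes <- function(modules, id) {
  modules$gene[modules$module == id]
}
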