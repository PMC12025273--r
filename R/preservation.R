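# Permutation Zsummary module preservation. Modules are taken as defined in
# the `ref` dataset (the treatment whose modules are named), and the
# question asked is whether their density and connectivity survive in the
# `test` dataset (the comparator). The direction is part of the interface:
# swapping ref and test is a different analysis, not a symmetry.

#' Permutation Zsummary preservation of modules between two datasets
#'
#' For each module the seven component statistics are computed — density
#' side, all in the test dataset: mean within-module correlation, mean
#' within-module adjacency at power `beta`, proportion of variance
#' explained by the module eigengene, and mean module membership (kME);
#' connectivity side, each a ref-vs-test correlation of per-gene patterns:
#' intramodular connectivity (kIM), kME, and the within-module correlation
#' matrix itself. Each observed statistic is standardized against `n_perm`
#' random gene sets of the same size drawn (without replacement) from the
#' full universe in the same datasets, giving a Z per component, and
#' \deqn{Z_{summary} = \frac{median(Z_{meanCor}, Z_{meanAdj},
#'   Z_{propVarExpl}, Z_{meanKME}) + median(Z_{cor.kIM}, Z_{cor.kME},
#'   Z_{cor.cor})}{2}.}
#'
#' A module with \eqn{Z_{summary} < 0} is drug-responsive ("on"); one with
#' \eqn{Z_{summary} \ge 2} is preserved ("conserved"); the band in between
#' is "indeterminate".
#'
#' @param ref_expr Genes x samples matrix in which the modules were defined
#'   (the treatment dataset).
#' @param test_expr Genes x samples matrix of the comparator in which
#'   preservation is evaluated. Must share the gene universe of `ref_expr`.
#' @param modules A `dims_modules` tibble (label 0 is ignored).
#' @param beta Soft power for the adjacency-based components.
#' @param n_perm Number of permutation gene sets (>= 50).
#' @param seed Integer seed (mandatory; permutations are deterministic).
#' @return A `dims_preservation` tibble: one row per module with the seven
#'   component Zs, `zsummary`, `class`, and `size`.
#' @export
#' @examples
#' sim <- simulate_expression(sim_config(seed = 5, n_samples_per_group = 10))
#' mods <- detect_modules(build_network(sim$expr$combo, beta = 6))
#' pres <- module_preservation(sim$expr$combo, sim$expr$sham, mods,
#'                             n_perm = 50, seed = 1)
module_preservation <- function(ref_expr, test_expr, modules, beta = 6L,
                                n_perm = 200L, seed) {
  check_expr_matrix(ref_expr, "ref_expr")
  check_expr_matrix(test_expr, "test_expr")
  if (missing(seed)) abort("A seed is mandatory for the permutation null.")
  if (n_perm < 50L) abort("n_perm must be at least 50.")
  if (!setequal(rownames(ref_expr), rownames(test_expr))) {
    abort("ref_expr and test_expr must share the same gene universe.")
  }
  test_expr <- test_expr[rownames(ref_expr), , drop = FALSE]

  usable <- apply(ref_expr, 1L, var) > .Machine$double.eps &
    apply(test_expr, 1L, var) > .Machine$double.eps
  if (!all(usable)) {
    warn(sprintf("Dropping %d zero-variance gene(s) from preservation statistics.",
                 sum(!usable)))
  }
  universe <- rownames(ref_expr)[usable]
  c_ref <- cor(t(ref_expr[universe, , drop = FALSE]))
  c_test <- cor(t(test_expr[universe, , drop = FALSE]))

  mod_ids <- sort(unique(modules$module[modules$module > 0L]))
  rows <- purrr::map_dfr(mod_ids, function(m) {
    members <- intersect(modules$gene[modules$module == m], universe)
    if (length(members) < 3L) {
      warn(sprintf("Module %d has fewer than 3 usable genes; skipped.", m))
      return(tibble::tibble())
    }
    obs <- preservation_stats(c_ref, c_test, members, beta)
    set.seed(derive_seed(seed, paste0("perm-m", m)))
    null <- matrix(NA_real_, nrow = n_perm, ncol = 7L)
    for (p in seq_len(n_perm)) {
      rand <- sample(universe, length(members))
      null[p, ] <- preservation_stats(c_ref, c_test, rand, beta)
    }
    mu <- colMeans(null)
    sig <- apply(null, 2L, sd)
    z <- (obs - mu) / sig
    if (any(sig == 0)) {
      warn(sprintf("Zero permutation spread for module %d; affected Z set to 0.", m))
      z[sig == 0] <- 0
    }
    names(z) <- c("z_mean_cor", "z_mean_adj", "z_prop_var_expl", "z_mean_kme",
                  "z_cor_kim", "z_cor_kme", "z_cor_cor")
    zsummary <- zsummary_composite(z[1:4], z[5:7])
    tibble::tibble(module = m, size = length(members), !!!as.list(z),
                   zsummary = zsummary,
                   class = zsummary_class(zsummary))
  })
  new_dims_result(rows, "dims_preservation",
                  n_perm = as.integer(n_perm), seed = as.integer(seed),
                  beta = as.integer(beta))
}

# The seven component statistics for a gene set, from precomputed full
# correlation matrices. Order: meanCor, meanAdj, propVarExpl, meanKME,
# cor.kIM, cor.kME, cor.cor.
preservation_stats <- function(c_ref, c_test, members, beta) {
  ct <- c_test[members, members]
  cr <- c_ref[members, members]
  off <- upper.tri(ct)
  at <- abs(ct)^beta
  ar <- abs(cr)^beta

  eig_t <- module_eigen(ct)
  eig_r <- module_eigen(cr)

  c(mean(ct[off]),
    mean(at[off]),
    eig_t$lambda1 / length(members),
    mean(eig_t$kme),
    safe_cor(rowSums(ar) - 1, rowSums(at) - 1),
    safe_cor(eig_r$kme, eig_t$kme),
    safe_cor(cr[off], ct[off]))
}

# First eigenvector of a correlation matrix; kME_i = sqrt(lambda1) * v_i
# (the correlation of gene i with the standardized PC1 score), with the
# eigenvector oriented so that the average membership is non-negative.
module_eigen <- function(cmat) {
  e <- eigen(cmat, symmetric = TRUE)
  v <- e$vectors[, 1L]
  if (sum(v) < 0) v <- -v
  list(lambda1 = e$values[1L], kme = sqrt(max(e$values[1L], 0)) * v)
}

#' Composite Zsummary from its component Z statistics
#'
#' \eqn{(median(Z_{density}) + median(Z_{connectivity})) / 2}: the median of
#' the four density-side Zs plus the median of the three connectivity-side
#' Zs, halved. When all seven components equal z, the composite equals z.
#'
#' @param z_density Numeric vector of the four density Zs.
#' @param z_connectivity Numeric vector of the three connectivity Zs.
#' @return A single number.
#' @export
#' @examples
#' zsummary_composite(rep(1.3, 4), rep(1.3, 3))  # 1.3
zsummary_composite <- function(z_density, z_connectivity) {
  (median(z_density) + median(z_connectivity)) / 2
}

safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

zsummary_class <- function(z) {
  dplyr::case_when(z < 0 ~ "on", z >= 2 ~ "conserved",
                   .default = "indeterminate")
}

#' Classify modules from their Zsummary
#'
#' Applies the thresholds: "on" (drug-responsive) below 0, "conserved" at
#' or above 2, "indeterminate" in between. Already stored on the
#' preservation result; this recomputes from `zsummary` alone.
#'
#' @param pres A `dims_preservation` tibble (or any data frame with
#'   `module` and `zsummary` columns).
#' @return Tibble with `module`, `zsummary`, `class`.
#' @export
classify_modules <- function(pres) {
  tibble::tibble(module = pres$module, zsummary = pres$zsummary,
                 class = zsummary_class(pres$zsummary))
}

#' Modules classified as drug-responsive ("on") in a preservation result
#'
#' @param pres A `dims_preservation` tibble or an integer vector of module
#'   ids (passed through unchanged).
#' @return Sorted integer vector of module ids.
#' @export
on_modules <- function(pres) {
  if (is.numeric(pres)) return(sort(as.integer(pres)))
  sort(pres$module[zsummary_class(pres$zsummary) == "on"])
}

#' Identify synergy (Sy) modules of the combination treatment
#'
#' A combination-treatment module is a synergy module when it is
#' drug-responsive versus the untreated group AND non-preserved versus at
#' least one of the single drugs:
#' \deqn{Sy = (On_{vs A} \cup On_{vs B}) \cap On_{vs sham}.}
#'
#' @param combo_vs_sham,combo_vs_drugA,combo_vs_drugB Preservation results
#'   of the combination-treatment modules against each comparator
#'   (`dims_preservation` tibbles), or bare integer vectors of On-module
#'   ids for each comparison.
#' @return A `dims_sy_report` list with `sy_modules` (sorted ids), the
#'   three On sets, and a per-module `provenance` tibble recording which
#'   comparisons flagged each module.
#' @export
#' @examples
#' rep <- identify_sy_modules(combo_vs_sham = c(6, 7, 8, 10),
#'                            combo_vs_drugA = 8,
#'                            combo_vs_drugB = c(1, 7, 10))
#' rep$sy_modules
identify_sy_modules <- function(combo_vs_sham, combo_vs_drugA, combo_vs_drugB) {
  universe_of <- function(x) {
    if (is.numeric(x)) as.integer(x) else as.integer(x$module)
  }
  if (!is.numeric(combo_vs_sham)) {
    u <- lapply(list(combo_vs_sham, combo_vs_drugA, combo_vs_drugB), universe_of)
    if (!all(vapply(u, setequal, logical(1), y = u[[1]]))) {
      abort("The three preservation results cover different module sets.")
    }
  }
  on_sham <- on_modules(combo_vs_sham)
  on_a <- on_modules(combo_vs_drugA)
  on_b <- on_modules(combo_vs_drugB)
  sy <- sort(intersect(union(on_a, on_b), on_sham))
  all_mods <- sort(unique(c(on_sham, on_a, on_b,
                            universe_of(combo_vs_sham))))
  provenance <- tibble::tibble(
    module = all_mods,
    on_vs_sham = all_mods %in% on_sham,
    on_vs_drugA = all_mods %in% on_a,
    on_vs_drugB = all_mods %in% on_b
  ) |>
    mutate(sy = .data$on_vs_sham & (.data$on_vs_drugA | .data$on_vs_drugB))
  structure(list(sy_modules = sy, on_vs_sham = on_sham, on_vs_drugA = on_a,
                 on_vs_drugB = on_b, provenance = provenance),
            class = "dims_sy_report")
}

#' @export
print.dims_sy_report <- function(x, ...) {
  cat("<dims_sy_report>\n")
  cat(sprintf("  On vs sham:  {%s}\n", paste(x$on_vs_sham, collapse = ", ")))
  cat(sprintf("  On vs drugA: {%s}\n", paste(x$on_vs_drugA, collapse = ", ")))
  cat(sprintf("  On vs drugB: {%s}\n", paste(x$on_vs_drugB, collapse = ", ")))
  cat(sprintf("  Sy modules:  {%s}\n", paste(x$sy_modules, collapse = ", ")))
  invisible(x)
}
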