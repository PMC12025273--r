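# Per-gene two-group differential expression on log2 data, with the
# screen thresholds fold change > 1.2 and p < 0.05 (Bonferroni column
# always reported, optionally used as the gate).

#' Differentially expressed genes between two groups
#'
#' Per gene, a Welch two-sample t-test on log2 expression;
#' `log2fc = mean(test) - mean(ref)` and `fold_change = 2^|log2fc|` with the
#' direction kept in `direction`. With `shrink_var = TRUE` the gene-wise
#' variances are moderated toward the common value with
#' `limma::squeezeVar()` (empirical-Bayes pooling) before the t statistic
#' is formed; the default is the plain Welch test.
#'
#' @param ref Genes x samples matrix of the reference group (e.g. sham).
#' @param test Genes x samples matrix of the treated group.
#' @param shrink_var Moderate variances with limma's empirical Bayes?
#' @return A `dims_deg` tibble: `gene`, `mean_ref`, `mean_test`, `log2fc`,
#'   `direction`, `fold_change`, `p_raw`, `p_bonferroni`, `passes`
#'   (default gate FC > 1.2 and raw p < 0.05).
#' @export
#' @examples
#' sim <- simulate_expression(synergy_config(seed = 4))
#' deg <- differential_expression(sim$expr$sham, sim$expr$drugA)
#' head(deg[order(deg$p_raw), ])
differential_expression <- function(ref, test, shrink_var = FALSE) {
  check_expr_matrix(ref, "ref")
  check_expr_matrix(test, "test")
  if (ncol(ref) < 2L || ncol(test) < 2L) {
    abort("At least 2 samples per group are required.")
  }
  if (!setequal(rownames(ref), rownames(test))) {
    abort("ref and test must share the same gene universe.")
  }
  test <- test[rownames(ref), , drop = FALSE]

  n1 <- ncol(ref); n2 <- ncol(test)
  m1 <- rowMeans(ref); m2 <- rowMeans(test)
  v1 <- apply(ref, 1L, var); v2 <- apply(test, 1L, var)

  if (shrink_var) {
    sq1 <- limma::squeezeVar(v1, df = n1 - 1L)
    sq2 <- limma::squeezeVar(v2, df = n2 - 1L)
    se2 <- sq1$var.post / n1 + sq2$var.post / n2
    df <- (n1 - 1L) + (n2 - 1L) + 2 * sq1$df.prior[1]
    df <- rep_len(df, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df = df)
  # Degenerate genes: no variance in either group. Equal means -> p = 1;
  # different means -> an exact separation, p -> 0.
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, .Machine$double.xmin)

  n_tested <- length(m1)
  log2fc <- m2 - m1
  out <- tibble::tibble(
    gene = rownames(ref),
    mean_ref = unname(m1),
    mean_test = unname(m2),
    log2fc = unname(log2fc),
    direction = ifelse(log2fc >= 0, "up", "down"),
    fold_change = 2^abs(unname(log2fc)),
    p_raw = pmin(1, unname(p)),
    p_bonferroni = pmin(1, unname(p) * n_tested)
  )
  out$passes <- out$fold_change > 1.2 & out$p_raw < 0.05
  new_dims_result(out, "dims_deg",
                  n_tested = n_tested, shrink_var = shrink_var)
}

#' Filter DEG records to the screened gene set
#'
#' A gene is kept iff `fold_change > fc_min` and the chosen p-value
#' (raw by default, Bonferroni-adjusted when `use_bonferroni = TRUE`) is
#' below `p_max`.
#'
#' @param records A `dims_deg` tibble from [differential_expression()].
#' @param fc_min Fold-change gate (default 1.2).
#' @param p_max Significance gate (default 0.05).
#' @param use_bonferroni Gate on the Bonferroni-adjusted p instead of raw p?
#' @return Character vector of gene ids passing both gates.
#' @export
filter_degs <- function(records, fc_min = 1.2, p_max = 0.05,
                        use_bonferroni = FALSE) {
  p <- if (use_bonferroni) records$p_bonferroni else records$p_raw
  records$gene[records$fold_change > fc_min & p < p_max]
}

#' Pairwise and all-way overlap of named gene sets
#'
#' For every unordered pair: intersection and union counts plus two
#' percentage conventions (the denominator used in published overlap
#' percentages is rarely stated): `pct_of_union` = overlap / pair union,
#' `pct_of_total` = overlap / number of distinct genes across all sets.
#' One final row (`set1 = set2 = "all"`) reports the all-way intersection.
#'
#' @param sets Named list (>= 2) of character vectors.
#' @return A tibble with columns `set1`, `set2`, `n1`, `n2`, `n_overlap`,
#'   `n_union`, `pct_of_union`, `pct_of_total`.
#' @export
#' @examples
#' overlap_analysis(list(x = c("a", "b", "c"), y = c("b", "c", "d")))
overlap_analysis <- function(sets) {
  if (length(sets) < 2L || is.null(names(sets))) {
    abort("Provide at least two named gene sets.")
  }
  sets <- lapply(sets, unique)
  total <- length(unique(unlist(sets)))
  pairs <- combn(names(sets), 2L, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    ov <- length(intersect(a, b)); un <- length(union(a, b))
    tibble::tibble(set1 = p[1], set2 = p[2],
                   n1 = length(a), n2 = length(b),
                   n_overlap = ov, n_union = un,
                   pct_of_union = if (un > 0) 100 * ov / un else NA_real_,
                   pct_of_total = if (total > 0) 100 * ov / total else NA_real_)
  })
  all_int <- length(Reduce(intersect, sets))
  all_un <- total
  rows |>
    bind_rows(tibble::tibble(
      set1 = "all", set2 = "all",
      n1 = NA_integer_, n2 = NA_integer_,
      n_overlap = all_int, n_union = all_un,
      pct_of_union = if (all_un > 0) 100 * all_int / all_un else NA_real_,
      pct_of_total = if (total > 0) 100 * all_int / total else NA_real_))
}
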