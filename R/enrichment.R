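# Local over-representation analysis: one-sided Fisher exact test per term
# against a user-supplied annotation (e.g. read from GMT), standing in for
# web-service enrichment tools.

#' Over-representation of a gene set against an annotation
#'
#' For each term, the 2x2 table (k, n - k; K - k, N - K - n + k) is tested
#' with a one-sided Fisher exact test (enrichment direction), where k is
#' the query/term overlap, n the query size, K the term size and N the
#' background size. Annotation genes are intersected with the background
#' first. P-values are adjusted by Benjamini-Hochberg (default) or
#' Bonferroni.
#'
#' @param query Character vector of genes (must lie in `background`).
#' @param annotation Named list of term gene sets, e.g. from [read_gmt()].
#' @param background Character vector defining the gene universe (defaults
#'   to the union of the annotation when omitted).
#' @param alpha Significance level for the `significant` flag.
#' @param method Adjustment method: `"bh"` or `"bonferroni"`.
#' @return A `dims_enrichment` tibble sorted by p: `term`, `k`, `term_size`,
#'   `query_size`, `background_size`, `p_fisher`, `p_adjusted`,
#'   `significant`.
#' @export
#' @examples
#' anno <- list(t1 = c("a", "b", "c"), t2 = c("d", "e"))
#' overrepresentation(c("a", "b"), anno, background = letters[1:10])
overrepresentation <- function(query, annotation, background = NULL,
                               alpha = 0.05, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (is.null(background)) background <- unique(unlist(annotation))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  extra <- setdiff(query, background)
  if (length(extra)) {
    warn(sprintf("Dropping %d query gene(s) outside the background.", length(extra)))
  }
  query <- intersect(query, background)
  if (!length(query)) abort("Query is empty after intersecting with the background.")

  n <- length(query)
  n_bg <- length(background)
  rows <- purrr::map_dfr(names(annotation), function(term) {
    term_genes <- intersect(annotation[[term]], background)
    k <- length(intersect(query, term_genes))
    bigk <- length(term_genes)
    tab <- matrix(c(k, n - k, bigk - k, n_bg - bigk - n + k), nrow = 2L)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble::tibble(term = term, k = k, term_size = bigk, query_size = n,
                   background_size = n_bg, p_fisher = p)
  })
  rows <- rows |>
    mutate(p_adjusted = p.adjust(.data$p_fisher,
                                 method = if (method == "bh") "BH" else "bonferroni"),
           significant = .data$p_adjusted < alpha) |>
    arrange(.data$p_fisher, .data$term)
  new_dims_result(rows, "dims_enrichment", alpha = alpha, method = method)
}
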