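# broom-style tidiers. The result objects are already tibbles; tidy()
# strips the result class (and, where useful, folds attributes into
# columns), glance() gives the one-row summary.

strip_result <- function(x) {
  tibble::as_tibble(unclass(x)[!vapply(unclass(x), is.null, logical(1))])
}

#' @rdname tidy_dims
#' @export
tidy.dims_sft <- function(x, ...) {
  tibble::as_tibble(x) |>
    mutate(chosen = .data$power == attr(x, "chosen_beta"))
}

#' Tidy and summarize screening results
#'
#' `tidy()` returns the per-unit table (per power, per module, per gene);
#' `glance()` returns a one-row summary.
#'
#' @param x A result object from this package.
#' @param ... Unused.
#' @name tidy_dims
#' @export
glance.dims_sft <- function(x, ...) {
  tibble::tibble(chosen_beta = attr(x, "chosen_beta"),
                 reached_target = attr(x, "reached_target"),
                 target_r2 = attr(x, "target_r2"),
                 best_r2 = max(x$sft_r2))
}

#' @rdname tidy_dims
#' @export
tidy.dims_preservation <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy_dims
#' @export
glance.dims_preservation <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x),
                 n_on = sum(x$class == "on"),
                 n_conserved = sum(x$class == "conserved"),
                 n_indeterminate = sum(x$class == "indeterminate"),
                 n_perm = attr(x, "n_perm"))
}

#' @rdname tidy_dims
#' @export
tidy.dims_sy_report <- function(x, ...) x$provenance

#' @rdname tidy_dims
#' @export
glance.dims_sy_report <- function(x, ...) {
  tibble::tibble(n_sy = length(x$sy_modules),
                 n_on_vs_sham = length(x$on_vs_sham),
                 n_on_vs_drugA = length(x$on_vs_drugA),
                 n_on_vs_drugB = length(x$on_vs_drugB))
}

#' @rdname tidy_dims
#' @export
tidy.dims_deg <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy_dims
#' @export
glance.dims_deg <- function(x, ...) {
  tibble::tibble(n_tested = attr(x, "n_tested"),
                 n_pass = sum(x$passes),
                 n_pass_bonferroni = sum(x$fold_change > 1.2 & x$p_bonferroni < 0.05))
}

#' @rdname tidy_dims
#' @export
tidy.dims_drivers <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy_dims
#' @export
glance.dims_drivers <- function(x, ...) {
  tibble::tibble(k = attr(x, "k"),
                 n_drivers = length(attr(x, "drivers")),
                 n_common = length(attr(x, "common")),
                 n_specific = length(attr(x, "drivers")) - length(attr(x, "common")))
}

#' @rdname tidy_dims
#' @export
tidy.dims_modules <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy_dims
#' @export
glance.dims_modules <- function(x, ...) {
  nz <- x$module[x$module > 0]
  tibble::tibble(n_modules = length(unique(nz)),
                 n_assigned = length(nz),
                 n_unassigned = sum(x$module == 0),
                 largest = if (length(nz)) max(table(nz)) else 0L)
}
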