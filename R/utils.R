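# Internal helpers shared across modules.

# Derive a reproducible child seed from a parent seed and a component label.
# Keeps results below 2^31 - 1 so set.seed() always accepts them.
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(component)) * seq_along(utf8ToInt(as.character(component))))
  as.integer((abs(seed) * 48271 + h) %% 2147483587L)
}

# Expression matrices are genes x samples with rownames = gene ids.
check_expr_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric genes x samples matrix.", arg))
  }
  if (is.null(rownames(x))) {
    abort(sprintf("`%s` must have gene ids as rownames.", arg))
  }
  if (anyNA(x)) {
    abort(sprintf("`%s` contains missing values; a complete matrix is required.", arg))
  }
  invisible(x)
}

# Drop genes with zero variance across samples, warning with their names.
drop_zero_variance <- function(x, warn_label = "genes") {
  v <- apply(x, 1L, var)
  bad <- v <= .Machine$double.eps
  if (any(bad)) {
    warn(sprintf(
      "Excluding %d zero-variance %s: %s",
      sum(bad), warn_label,
      paste(head(rownames(x)[bad], 5L), collapse = ", ")
    ))
    x <- x[!bad, , drop = FALSE]
  }
  x
}

# Adjusted Rand index between two labelings (used by tests and examples).
#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects,
#' used to score recovery of planted modules. 1 means identical partitions
#' (up to relabeling), 0 is the expected value under random labeling.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

new_dims_result <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}
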