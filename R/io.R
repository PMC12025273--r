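# Plain-text readers/writers for all pipeline artifacts. Everything is TSV
# or JSON so each stage can be re-run independently.

#' Read / write a genes x samples expression matrix as TSV
#'
#' The first column holds gene ids, the header holds sample ids.
#'
#' @param path File path.
#' @return `read_expression()` returns a numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  check_expr_matrix(m)
}

#' @rdname read_expression
#' @param expr Numeric genes x samples matrix with gene rownames.
#' @export
write_expression <- function(expr, path) {
  check_expr_matrix(expr)
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read / write a sample-to-group map as TSV
#'
#' Two columns: `sample`, `group`.
#' @param path File path.
#' @export
read_group_map <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' @rdname read_group_map
#' @param group_map Data frame with columns `sample` and `group`.
#' @export
write_group_map <- function(group_map, path) {
  readr::write_tsv(group_map[, c("sample", "group")], path)
  invisible(path)
}

#' Read / write an undirected edge list as TSV
#'
#' Two tab-separated columns, no header by default; SIF files
#' (node1 interaction node2) are accepted on read.
#'
#' @param path File path.
#' @param header Does the file carry a header line?
#' @return `read_edge_list()` returns a two-column character tibble.
#' @export
read_edge_list <- function(path, header = FALSE) {
  df <- readr::read_tsv(path, col_names = header == TRUE,
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  if (!header) names(df) <- paste0("X", seq_along(df))
  if (ncol(df) == 3L) df <- df[, c(1L, 3L)]  # SIF: node1 type node2
  df <- df[, 1:2]
  names(df) <- c("from", "to")
  df
}

#' @rdname read_edge_list
#' @param edges Two-column data frame of node ids.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(tibble::as_tibble(edges[, 1:2]), path, col_names = FALSE)
  invisible(path)
}

#' Serialize ground truth to JSON and back
#'
#' Round-trips the `dims_ground_truth` produced by [simulate_expression()]
#' and [simulate_network()] unchanged.
#'
#' @param truth A `dims_ground_truth` list.
#' @param path File path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "dims_ground_truth"))
  payload <- list(
    modules = as.data.frame(truth$modules),
    disrupted = truth$disrupted,
    degs = lapply(truth$degs, as.data.frame),
    target_a = truth$target_a,
    target_b = truth$target_b,
    bridges = truth$bridges
  )
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    modules = tibble::tibble(gene = as.character(p$modules$gene),
                             module = as.integer(p$modules$module)),
    disrupted = lapply(p$disrupted, as.integer),
    degs = lapply(p$degs, function(d) {
      tibble::tibble(gene = as.character(d$gene), delta = as.numeric(d$delta))
    }),
    target_a = as.character(p$target_a),
    target_b = as.character(p$target_b),
    bridges = as.character(p$bridges)
  ), class = "dims_ground_truth")
}

#' Read a GMT gene-set annotation file
#'
#' Standard GMT: one term per line — term id, description, then member
#' genes, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors (term -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
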