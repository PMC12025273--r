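# ggplot2 diagnostics for each result type.

#' @rdname autoplot_dims
#' @export
autoplot.dims_sft <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$sft_r2)) +
    ggplot2::geom_hline(yintercept = attr(object, "target_r2"),
                        linetype = "dashed", colour = "red") +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "black"),
                                 guide = "none") +
    ggplot2::labs(x = "soft-thresholding power",
                  y = "scale-free topology fit index",
                  title = "Soft-threshold selection")
}

#' Diagnostic plots for screening results
#'
#' `autoplot()` methods: soft-threshold fit curve, per-module preservation
#' Zsummary against the 0 (drug-responsive) and 2 (conserved) thresholds,
#' a DEG volcano with the fold-change and p gates, and the driver-ranking
#' plane (total distance vs flow centrality).
#'
#' @param object A result object from this package.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_dims
#' @export
autoplot.dims_preservation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$zsummary)) +
    ggplot2::geom_hline(yintercept = 0, colour = "black") +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed", colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$module), vjust = -0.8,
                       size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "module size", y = "preservation Zsummary",
                  colour = NULL,
                  title = "Module preservation (below 0 = drug-responsive)")
}

#' @rdname autoplot_dims
#' @param fc_min,p_max Gates drawn on the volcano.
#' @export
autoplot.dims_deg <- function(object, fc_min = 1.2, p_max = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data$p_raw))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$passes), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = "Differential expression screen")
}

#' @rdname autoplot_dims
#' @export
autoplot.dims_drivers <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_distance,
                                   y = .data$fc_raw + 1)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$driver,
                                     shape = .data$common), alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "red", `FALSE` = "grey60")) +
    ggplot2::labs(x = "total shortest distance to targets",
                  y = "flow centrality (pair-sum + 1)",
                  colour = "driver", shape = "common",
                  title = "Driver ranking plane")
}
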