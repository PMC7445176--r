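# ggplot2 views of a nat_analysis: per-category feature distributions and a
# heatmap of log2 fold changes across the phosphate states.

#' Length, GC and expression distributions by transcript category
#'
#' Violin-plus-box panels of spliced length (log10), GC content and maximum
#' FPKM (log10, pseudocount 0.01) for NATs, lincRNAs and mRNAs.
#'
#' @param analysis A `nat_analysis` object ([nat_analysis()]).
#' @return A ggplot object.
#' @export
plot_category_distributions <- function(analysis) {
  df <- analysis$features |>
    filter(.data$category %in% c("NAT", "LINCRNA", "MRNA")) |>
    transmute(
      .data$category,
      `length (log10 nt)` = log10(.data$length_nt),
      `GC content (%)` = .data$gc_pct,
      `max FPKM (log10)` = log10(.data$fpkm_max + 0.01)
    ) |>
    pivot_longer(-"category", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$value,
                                   fill = .data$category)) +
    ggplot2::geom_violin(alpha = 0.6, colour = NA) +
    ggplot2::geom_boxplot(width = 0.2, outlier.size = 0.4, fill = "white") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of log2 fold changes relative to control across Pi states
#'
#' One row per Pi-responsive transcript, one column per condition, filled
#' with log2(FPKM / FPKM at C4) (pseudocount from the analysis thresholds).
#'
#' @param analysis A `nat_analysis` object.
#' @param patterns Response patterns to include (default: everything except
#'   `NONE`).
#' @return A ggplot object.
#' @export
plot_response_heatmap <- function(analysis,
                                  patterns = setdiff(RESPONSE_PATTERNS, "NONE")) {
  keep <- analysis$responses |>
    filter(.data$pattern %in% patterns) |>
    pull("transcript_id")
  pc <- analysis$params$fc_pseudocount
  lfc <- analysis$profiles |>
    filter(.data$transcript_id %in% keep) |>
    group_by(.data$transcript_id) |>
    mutate(log2fc = log2((.data$fpkm + pc) /
                           (.data$fpkm[.data$condition == "C4"] + pc))) |>
    ungroup() |>
    mutate(condition = factor(.data$condition, levels = PI_CONDITIONS))
  ggplot2::ggplot(lfc, ggplot2::aes(x = .data$condition,
                                    y = .data$transcript_id,
                                    fill = .data$log2fc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 FC vs C4") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' @rdname plot_category_distributions
#' @param object A `nat_analysis` object.
#' @param type `"distributions"` or `"heatmap"`.
#' @param ... Unused.
#' @export
autoplot.nat_analysis <- function(object, type = c("distributions", "heatmap"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
         distributions = plot_category_distributions(object),
         heatmap = plot_response_heatmap(object))
}
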