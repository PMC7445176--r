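# Descriptive comparisons across transcript categories (length, GC content,
# expression level) and the bookkeeping tables that mirror the pipeline's
# gate accounting.

#' Per-category descriptive summaries
#'
#' Medians of spliced length, GC content and expression level (maximum FPKM
#' across conditions) for each transcript category.
#'
#' @param features Tibble with one row per transcript: `transcript_id`,
#'   `category` (NAT / LINCRNA / MRNA), `length_nt`, `gc_pct`, `fpkm_max`.
#'   The pipeline builds this table ([nat_analysis()] stores it as
#'   `$features`).
#' @return Tibble: `category`, `n`, `median_length_nt`, `median_gc_pct`,
#'   `median_fpkm`.  Medians are over non-missing values only.
#' @export
summarize_categories <- function(features) {
  if (nrow(features) == 0) abort("validation error: empty feature table")
  features |>
    group_by(.data$category) |>
    summarise(
      n = n(),
      median_length_nt = median(.data$length_nt, na.rm = TRUE),
      median_gc_pct = median(.data$gc_pct, na.rm = TRUE),
      median_fpkm = median(.data$fpkm_max, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Compare a numeric feature between two transcript groups
#'
#' The groups (e.g. NAT versus mRNA lengths) are unmatched and of unequal
#' size, so no pairing exists; Welch's unequal-variance t-test and the
#' two-sided Mann-Whitney U test are both computed, assessing the same
#' scientific claim (the distributions differ) parametrically and by rank.
#'
#' @param a,b Numeric series, each of length at least 2.
#' @return One-row tibble: `t_statistic`, `t_p`, `u_statistic`, `u_p`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("validation error: each group needs at least 2 values")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  ut <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  tibble(
    t_statistic = unname(tt$statistic), t_p = tt$p.value,
    u_statistic = unname(ut$statistic), u_p = ut$p.value
  )
}

#' Count tables over labels, overlap classes, response patterns and pairs
#'
#' Emits the tallies that make a run auditable: candidates per label, NATs
#' per overlap class, responsive transcripts per category and pattern, DE
#' transcripts per category, and pairs by concordance and overlap class.
#' Every table is a partition of its parent total.
#'
#' @param classification Output of [classify_candidates()].
#' @param responses Output of [classify_pi_response()] (optional).
#' @param pairs Output of [detect_nat_pairs()] (optional).
#' @param de_calls Long DE-call tibble (optional; any row set of
#'   [call_de()] outputs with a `status` column).
#' @return Named list of tibbles: `labels`, `overlap_classes`, `responses`,
#'   `pairs`, `de`.
#' @export
category_counts <- function(classification, responses = NULL, pairs = NULL,
                            de_calls = NULL) {
  out <- list()
  out$labels <- classification |>
    count(.data$label, name = "n") |>
    arrange(.data$label)
  out$overlap_classes <- classification |>
    filter(.data$label == "NAT") |>
    count(.data$overlap_class, name = "n") |>
    arrange(.data$overlap_class)
  if (!is.null(responses)) {
    cat_of <- classification |>
      transmute(.data$transcript_id,
                category = case_when(
                  .data$label == "NAT" ~ "NAT",
                  .data$label == "LINCRNA" ~ "LINCRNA",
                  .data$label == "REJECT_ANNOTATED" ~ "MRNA",
                  TRUE ~ "OTHER"
                ))
    out$responses <- responses |>
      left_join(cat_of, by = "transcript_id") |>
      mutate(category = if_else(is.na(.data$category), "OTHER", .data$category)) |>
      count(.data$category, .data$pattern, name = "n") |>
      arrange(.data$category, .data$pattern)
  }
  if (!is.null(pairs)) {
    out$pairs <- pairs |>
      count(.data$concordance, .data$overlap_class, name = "n") |>
      arrange(.data$concordance, .data$overlap_class)
  }
  if (!is.null(de_calls)) {
    out$de <- de_calls |>
      filter(.data$status != "UNCHANGED") |>
      distinct(.data$transcript_id) |>
      summarise(n_de = n())
  }
  out
}
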