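# End-to-end orchestration: classify -> differential expression -> response
# patterns -> pairs -> summaries, with every intermediate table kept on the
# result object so each tally is auditable.

DE_CONTRASTS <- list(c("C4", "P4"), c("C8", "P8"), c("C4", "R4"), c("P4", "R4"))

#' Run the NAT identification and pairing analysis on in-memory inputs
#'
#' @param transcripts Exon-level transcript tibble ([read_gtf()]):
#'   assembled candidates, plus annotated transcripts if present.
#' @param genes Exon-level gene-model tibble ([read_gene_models()]).
#' @param genome Genome sequences ([read_genome()]).
#' @param expression Long expression tibble ([read_expression_table()]).
#' @param thresholds A [nat_thresholds()] object.
#' @param overlap_mode `"exonic"` (default) or `"span"`.
#' @param log_fpkm Correlate pairs on `log2(FPKM + 1)`.
#' @param bh Benjamini-Hochberg-adjust p-values per contrast before gating.
#' @return A `nat_analysis` object: a list with `profiles`,
#'   `classification`, `de_calls`, `responses`, `pairs`, `features`,
#'   `summary`, `counts`, `coverage_pct` and `params`.  See
#'   [tidy.nat_analysis()] and [glance.nat_analysis()].
#' @export
nat_analysis <- function(transcripts, genes, genome, expression,
                         thresholds = nat_thresholds(),
                         overlap_mode = c("exonic", "span"),
                         log_fpkm = FALSE, bh = FALSE) {
  overlap_mode <- match.arg(overlap_mode)
  thresholds <- as_nat_thresholds(thresholds)

  tx_spans <- transcript_spans(transcripts)
  lengths <- bind_rows(
    tx_spans |> select("transcript_id", "length_nt"),
    gene_spans(genes) |> select(transcript_id = "gene_id",
                                length_nt = "exonic_length_nt")
  ) |> distinct(.data$transcript_id, .keep_all = TRUE)

  profiles <- condition_profiles(expression, lengths)
  classification <- classify_candidates(transcripts, genes, profiles, genome,
                                        thresholds, mode = overlap_mode)
  de_calls <- map(DE_CONTRASTS, \(ct) call_de(profiles, ct, thresholds)) |>
    list_rbind()
  responses <- classify_pi_response(profiles, thresholds, bh = bh)
  pairs <- detect_nat_pairs(classification, profiles, responses, thresholds,
                            log_fpkm = log_fpkm)

  nat_ids <- classification$transcript_id[classification$label == "NAT"]
  nat_ov <- overlap_table(
    transcripts |> filter(.data$transcript_id %in% nat_ids),
    genes, mode = overlap_mode
  )
  coverage <- genome_nat_coverage(nat_ov, genes, thresholds$min_overlap_nt)

  features <- classification |>
    mutate(category = case_when(
      .data$label == "NAT" ~ "NAT",
      .data$label == "LINCRNA" ~ "LINCRNA",
      .data$label == "REJECT_ANNOTATED" ~ "MRNA",
      TRUE ~ "OTHER"
    )) |>
    select("transcript_id", "category", "length_nt", "gc_pct", "fpkm_max")

  depletion_de <- de_calls |>
    filter(.data$alt %in% c("P4", "P8"), .data$ref %in% c("C4", "C8"))
  counts <- category_counts(classification, responses, pairs, depletion_de)

  structure(list(
    profiles = profiles, classification = classification,
    de_calls = de_calls, responses = responses, pairs = pairs,
    features = features,
    summary = summarize_categories(
      features |> filter(.data$category != "OTHER")),
    counts = counts, coverage_pct = coverage,
    params = c(unclass(thresholds),
               list(overlap_mode = overlap_mode, log_fpkm = log_fpkm,
                    bh = bh))
  ), class = "nat_analysis")
}

#' @export
print.nat_analysis <- function(x, ...) {
  g <- glance(x)
  cat("<nat_analysis>\n")
  cat(sprintf("  Of the %d candidate transcripts, %d were identified as NATs\n",
              g$n_candidates, g$n_nat))
  cat(sprintf("    (%d fully overlapped, %d head-to-head, %d tail-to-tail)\n",
              g$n_full, g$n_head_to_head, g$n_tail_to_tail))
  cat(sprintf("  %d lincRNAs; NATs cover %.1f%% of annotated genes\n",
              g$n_lincrna, g$coverage_pct))
  cat(sprintf("  %d NATs differentially expressed under Pi depletion; %d Pi-responsive\n",
              g$n_de_nat, g$n_responsive_nat))
  cat(sprintf("  %d NAT-mRNA pairs: %d concordant, %d discordant\n",
              g$n_pairs, g$n_concordant, g$n_discordant))
  invisible(x)
}

#' Turn a NAT analysis into tidy tibbles
#'
#' `tidy()` returns the NAT-mRNA pair table (one row per detected pair);
#' `glance()` returns a one-row summary of every headline count.
#'
#' @param x A `nat_analysis` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nat_analysis <- function(x, ...) {
  x$pairs |>
    left_join(x$responses |> select(nat_id = "transcript_id", "pattern"),
              by = "nat_id")
}

#' @rdname tidy.nat_analysis
#' @export
glance.nat_analysis <- function(x, ...) {
  cls <- x$classification
  class_n <- function(cl) sum(cls$overlap_class == cl & cls$label == "NAT",
                              na.rm = TRUE)
  nat_ids <- cls$transcript_id[cls$label == "NAT"]
  de_nat <- x$de_calls |>
    filter(.data$alt %in% c("P4", "P8"), .data$ref %in% c("C4", "C8"),
           .data$status != "UNCHANGED",
           .data$transcript_id %in% nat_ids) |>
    distinct(.data$transcript_id)
  resp_nat <- x$responses |>
    filter(.data$pattern != "NONE", .data$transcript_id %in% nat_ids)
  tibble(
    n_candidates = nrow(cls),
    n_nat = length(nat_ids),
    n_full = class_n("FULL"),
    n_head_to_head = class_n("HEAD_TO_HEAD"),
    n_tail_to_tail = class_n("TAIL_TO_TAIL"),
    n_lincrna = sum(cls$label == "LINCRNA"),
    n_de_nat = nrow(de_nat),
    n_responsive_nat = nrow(resp_nat),
    n_pairs = nrow(x$pairs),
    n_concordant = sum(x$pairs$concordance == "CONCORDANT"),
    n_discordant = sum(x$pairs$concordance == "DISCORDANT"),
    coverage_pct = x$coverage_pct
  )
}

#' Validate and default a pipeline configuration file
#'
#' The config is a single declarative YAML mapping.  Every published cutoff
#' is overridable under `thresholds:`, but the defaults are exactly the
#' published values; unknown keys are rejected.
#'
#' @param path Path to a YAML file (an empty file yields all defaults).
#' @return A validated `nat_config` list: `inputs` (paths), `value_type`,
#'   `thresholds`, `overlap_mode`, `log_fpkm`, `bh`, `seed`, `out_dir`.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) %||% list() else path
  known <- c("inputs", "value_type", "thresholds", "overlap_mode",
             "log_fpkm", "bh", "seed", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("configuration error: unknown key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  known_inputs <- c("gtf", "annotation", "genome", "counts", "samples")
  bad_inputs <- setdiff(names(raw$inputs), known_inputs)
  if (length(bad_inputs) > 0) {
    abort(paste0("configuration error: unknown input key(s): ",
                 paste(bad_inputs, collapse = ", ")))
  }
  th <- tryCatch(do.call(nat_thresholds, raw$thresholds %||% list()),
                 error = function(e) {
                   abort(paste0("configuration error: ", conditionMessage(e)))
                 })
  overlap_mode <- raw$overlap_mode %||% "exonic"
  if (!overlap_mode %in% c("exonic", "span")) {
    abort("configuration error: overlap_mode must be 'exonic' or 'span'")
  }
  value_type <- raw$value_type %||% "count"
  if (!value_type %in% c("count", "fpkm")) {
    abort("configuration error: value_type must be 'count' or 'fpkm'")
  }
  structure(list(
    inputs = raw$inputs %||% list(),
    value_type = value_type,
    thresholds = th,
    overlap_mode = overlap_mode,
    log_fpkm = isTRUE(raw$log_fpkm),
    bh = isTRUE(raw$bh),
    seed = as.integer(raw$seed %||% 1L),
    out_dir = raw$out_dir %||% NULL
  ), class = "nat_config")
}

#' Run the full pipeline from files
#'
#' Reads the configured inputs, runs [nat_analysis()], and (when an output
#' directory is configured) writes every intermediate table plus a run
#' manifest (parameters, input checksums, per-gate counts).  Re-running on
#' identical inputs writes identical files.
#'
#' @param config A config file path, a `nat_config` (see
#'   [validate_config()]), or a named list with the same shape.
#' @param out_dir Output directory; overrides the config's `out_dir`.
#'   `NULL` skips writing.
#' @return The `nat_analysis` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "nat_config")) config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir
  inp <- config$inputs
  required <- c("gtf", "annotation", "genome", "counts", "samples")
  missing_keys <- setdiff(required, names(inp))
  if (length(missing_keys) > 0) {
    abort(paste0("configuration error: missing input path(s): ",
                 paste(missing_keys, collapse = ", ")))
  }
  absent <- unlist(inp)[!file.exists(unlist(inp))]
  if (length(absent) > 0) {
    abort(paste0("startup error: input file(s) not found: ",
                 paste(absent, collapse = ", ")))
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  transcripts <- stage("read_gtf", read_gtf(inp$gtf))
  genes <- stage("read_gene_models", read_gene_models(inp$annotation))
  genome <- stage("read_genome", read_genome(inp$genome))
  sample_map <- stage("read_sample_map",
                      readr::read_tsv(inp$samples, comment = "#",
                                      show_col_types = FALSE, progress = FALSE))
  expression <- stage("read_expression_table",
                      read_expression_table(inp$counts, sample_map,
                                            config$value_type))
  an <- stage("nat_analysis",
              nat_analysis(transcripts, genes, genome, expression,
                           thresholds = config$thresholds,
                           overlap_mode = config$overlap_mode,
                           log_fpkm = config$log_fpkm, bh = config$bh))

  if (!is.null(out_dir)) {
    write_analysis(an, out_dir, transcripts,
                   input_paths = unlist(inp))
  }
  invisible(an)
}

# Write every result table, the NAT GTF and the run manifest.
write_analysis <- function(an, out_dir, transcripts, input_paths = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- an$params
  write_result_tsv(an$classification, file.path(out_dir, "classification.tsv"),
                   params)
  write_result_tsv(an$de_calls, file.path(out_dir, "de_calls.tsv"), params)
  write_result_tsv(an$responses, file.path(out_dir, "response_patterns.tsv"),
                   params)
  write_result_tsv(an$pairs, file.path(out_dir, "nat_pairs.tsv"), params)
  write_result_tsv(an$summary, file.path(out_dir, "summary.tsv"), params)
  tallies <- imap(an$counts, \(tbl, nm) mutate(tbl, table = nm)) |>
    list_rbind() |>
    select("table", everything())
  write_result_tsv(tallies, file.path(out_dir, "counts.tsv"), params)
  writeLines(sprintf("%.6f", an$coverage_pct),
             file.path(out_dir, "coverage.txt"))

  nats <- an$classification |> filter(.data$label == "NAT")
  write_gtf(transcripts |>
              filter(.data$transcript_id %in% nats$transcript_id),
            file.path(out_dir, "nats.gtf"),
            extra_attributes = nats |>
              select("transcript_id", cognate_gene = "cognate_gene",
                     overlap_class = "overlap_class"))

  manifest <- list(
    package = paste0("natpairs ", utils::packageVersion("natpairs")),
    parameters = params,
    inputs = if (!is.null(input_paths)) {
      as.list(tools::md5sum(input_paths))
    } else {
      list()
    },
    gates = setNames(as.list(an$counts$labels$n), an$counts$labels$label),
    glance = as.list(glance(an))
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
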