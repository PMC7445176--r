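# The core taxonomy: antisense overlap computation, candidate filtering into
# NAT / lincRNA / reject classes, overlap-geometry classification
# (fully overlapped / head-to-head / tail-to-tail), cognate-gene assignment
# and genome NAT coverage.

#' Antisense overlap between a candidate transcript and a gene model
#'
#' Total per-base intersection between the candidate and the gene on the
#' opposite strand of the same chromosome; zero for same-strand or
#' different-chromosome inputs.  In `"exonic"` mode (default) candidate
#' exons are intersected with gene exons; in `"span"` mode with the gene
#' body hull.  Exons within a transcript are disjoint, so the result is a
#' plain sum of pairwise interval intersections.
#'
#' @param candidate Exon-level tibble rows for one transcript.
#' @param gene Exon-level tibble rows for one gene model (with `gene_id`).
#' @param mode `"exonic"` or `"span"`.
#' @return A single non-negative integer, in nucleotides.
#' @export
antisense_overlap_nt <- function(candidate, gene, mode = c("exonic", "span")) {
  mode <- match.arg(mode)
  if (candidate$chrom[1] != gene$chrom[1]) return(0L)
  if (candidate$strand[1] == gene$strand[1]) return(0L)
  gene_iv <- if (mode == "span") {
    tibble(start = min(gene$start), end = max(gene$end))
  } else {
    gene
  }
  interval_intersection_nt(candidate$start, candidate$end,
                           gene_iv$start, gene_iv$end)
}

# Summed pairwise intersection of two sets of disjoint intervals.
interval_intersection_nt <- function(a_start, a_end, b_start, b_end) {
  ov <- pmin(outer(a_end, b_end, pmin) - outer(a_start, b_start, pmax),
             Inf)
  sum(ov[ov > 0])
}

# All candidate x gene antisense (or sense) overlaps above zero, computed per
# chromosome.  Returns transcript_id, gene_id, overlap_nt.
overlap_table <- function(transcripts, genes, mode = c("exonic", "span"),
                          relation = c("antisense", "sense")) {
  mode <- match.arg(mode)
  relation <- match.arg(relation)
  tx_spans <- transcript_spans(transcripts)
  g_spans <- gene_spans(genes)
  empty <- tibble(transcript_id = character(), gene_id = character(),
                  overlap_nt = integer())
  if (nrow(tx_spans) == 0 || nrow(g_spans) == 0) return(empty)

  want_same_strand <- relation == "sense"
  pairs <- inner_join(
    tx_spans |> select("transcript_id", "chrom", tx_strand = "strand",
                       tx_start = "start", tx_end = "end"),
    g_spans |> select("gene_id", "chrom", g_strand = "strand",
                      g_start = "start", g_end = "end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter((.data$tx_strand == .data$g_strand) == want_same_strand,
           .data$tx_start < .data$g_end, .data$g_start < .data$tx_end)
  if (nrow(pairs) == 0) return(empty)

  tx_ex <- split(transcripts[c("start", "end")], transcripts$transcript_id)
  g_ex <- split(genes[c("start", "end")], genes$gene_id)
  pairs$overlap_nt <- map2_dbl(pairs$transcript_id, pairs$gene_id, function(t, g) {
    te <- tx_ex[[t]]
    ge <- if (mode == "span") {
      list(start = min(g_ex[[g]]$start), end = max(g_ex[[g]]$end))
    } else {
      g_ex[[g]]
    }
    interval_intersection_nt(te$start, te$end, ge$start, ge$end)
  })
  pairs |>
    filter(.data$overlap_nt > 0) |>
    select("transcript_id", "gene_id", "overlap_nt")
}

#' Classify the overlap geometry of an antisense transcript and its gene
#'
#' Geometry is a span property (it concerns transcript ends), so spans are
#' used even when overlap lengths are exonic.  A NAT whose span lies within
#' the gene span is `FULL`; the converse containment (gene inside NAT) is
#' collapsed into `FULL` and flagged.  Otherwise the overlap region contains
#' exactly one terminus of each transcript: both 5' termini gives
#' `HEAD_TO_HEAD` (divergent), both 3' termini `TAIL_TO_TAIL` (convergent).
#'
#' @param nat Exon-level tibble rows for one antisense transcript.
#' @param gene Exon-level tibble rows for its gene model (opposite strand,
#'   same chromosome, overlapping spans).
#' @return A one-row tibble: `overlap_class` and `contains_gene` (TRUE for
#'   the collapsed gene-inside-NAT case).
#' @export
overlap_class <- function(nat, gene) {
  ns <- min(nat$start); ne <- max(nat$end); nstr <- nat$strand[1]
  gs <- min(gene$start); ge <- max(gene$end); gstr <- gene$strand[1]
  if (nat$chrom[1] != gene$chrom[1] || nstr == gstr) {
    abort("overlap_class requires an antisense pair on one chromosome")
  }
  overlap_class_spans(ns, ne, nstr, gs, ge, gstr)
}

overlap_class_spans <- function(ns, ne, nstr, gs, ge, gstr) {
  if (ns >= gs && ne <= ge) {
    return(tibble(overlap_class = "FULL", contains_gene = FALSE))
  }
  if (gs >= ns && ge <= ne) {
    return(tibble(overlap_class = "FULL", contains_gene = TRUE))
  }
  os <- max(ns, gs); oe <- min(ne, ge)
  if (oe <= os) abort("overlap_class requires overlapping spans")
  # Terminal base of each transcript: 5' is the first transcribed base,
  # 3' the last, in genomic 0-based coordinates.
  p5 <- function(s, e, strand) if (strand == "+") s else e - 1L
  p3 <- function(s, e, strand) if (strand == "+") e - 1L else s
  inside <- function(p) p >= os && p < oe
  both5 <- inside(p5(gs, ge, gstr)) && inside(p5(ns, ne, nstr))
  both3 <- inside(p3(gs, ge, gstr)) && inside(p3(ns, ne, nstr))
  if (both5 && !both3) {
    return(tibble(overlap_class = "HEAD_TO_HEAD", contains_gene = FALSE))
  }
  if (both3 && !both5) {
    return(tibble(overlap_class = "TAIL_TO_TAIL", contains_gene = FALSE))
  }
  abort(paste0("internal assertion: partial antisense overlap must contain ",
               "both 5' or both 3' termini; coordinate bug upstream"))
}

#' Assign the cognate gene of a NAT
#'
#' The cognate is the qualifying gene (antisense overlap at or above the
#' minimum) with the largest overlap; ties break to the smaller distance
#' between span midpoints, then the lexicographically smallest `gene_id`.
#' Secondary overlaps are not classified.
#'
#' @param nat Exon-level tibble rows for one transcript.
#' @param genes Exon-level gene-model tibble (all genes).
#' @param thresholds A [nat_thresholds()] object.
#' @param mode Overlap mode, as in [antisense_overlap_nt()].
#' @return One-row tibble: `nat_id`, `cognate_gene_id`, `overlap_nt`,
#'   `overlap_class`, `contains_gene`.
#' @export
assign_cognate_gene <- function(nat, genes, thresholds = nat_thresholds(),
                                mode = c("exonic", "span")) {
  mode <- match.arg(mode)
  thresholds <- as_nat_thresholds(thresholds)
  ov <- overlap_table(nat, genes, mode = mode) |>
    filter(.data$overlap_nt >= thresholds$min_overlap_nt)
  if (nrow(ov) == 0) {
    abort("precondition violation: no gene with qualifying antisense overlap")
  }
  nspan <- transcript_spans(nat)
  gspan <- gene_spans(genes)
  pick <- ov |>
    left_join(gspan |> transmute(.data$gene_id,
                                 g_mid = (.data$start + .data$end) / 2),
              by = "gene_id") |>
    mutate(mid_dist = abs(.data$g_mid - (nspan$start + nspan$end) / 2)) |>
    arrange(desc(.data$overlap_nt), .data$mid_dist, .data$gene_id) |>
    slice(1)
  cls <- overlap_class(nat, genes |> filter(.data$gene_id == pick$gene_id))
  tibble(
    nat_id = nspan$transcript_id,
    cognate_gene_id = pick$gene_id,
    overlap_nt = pick$overlap_nt,
    overlap_class = cls$overlap_class,
    contains_gene = cls$contains_gene
  )
}

#' Filter and label lncRNA candidates
#'
#' Applies the published decision sequence to every transcript:
#' annotated coding transcripts are set aside first
#' (`REJECT_ANNOTATED`); then, in order, sense-strand exonic overlap with
#' any gene (`REJECT_SENSE_OVERLAP`), spliced length below the minimum
#' (`REJECT_SHORT`), predicted ORF above the maximum (`REJECT_ORF`),
#' maximum FPKM below the floor (`REJECT_LOW_FPKM`); survivors become `NAT`
#' when their best antisense overlap reaches the minimum, `LINCRNA` when
#' they overlap no gene at all, and `REJECT_SUBTHRESHOLD_OVERLAP` for
#' overlaps strictly between zero and the minimum.  Every gate is inclusive
#' exactly as published: length 200 passes, ORF 100 passes, overlap 50
#' passes, FPKMmax 1 passes.
#'
#' @param transcripts Exon-level transcript tibble (candidates plus any
#'   annotated transcripts).
#' @param genes Exon-level gene-model tibble.
#' @param profiles Per-condition expression profiles ([condition_profiles()])
#'   carrying an `fpkm` column; transcripts absent from the table are
#'   treated as expressionless (FPKMmax 0).  For annotated transcripts the
#'   lookup falls back to `gene_id` (gene-level quantification).
#' @param genome Genome sequences for ORF and GC computation.
#' @param thresholds A [nat_thresholds()] object.
#' @param mode Overlap mode, `"exonic"` (default) or `"span"`.
#' @return A tibble with one row per transcript: `transcript_id`, `label`,
#'   gate measurements (`length_nt`, `orf_aa`, `gc_pct`, `fpkm_max`,
#'   `sense_overlap_nt`, `overlap_nt`) and, for NATs, `cognate_gene`,
#'   `overlap_class`, `contains_gene`.
#' @export
classify_candidates <- function(transcripts, genes, profiles, genome,
                                thresholds = nat_thresholds(),
                                mode = c("exonic", "span")) {
  mode <- match.arg(mode)
  thresholds <- as_nat_thresholds(thresholds)
  spans <- transcript_spans(transcripts)

  seqs <- spliced_sequence(transcripts, genome)
  orf <- longest_orf_aa(seqs$sequence)
  seq_stats <- tibble(transcript_id = seqs$transcript_id,
                      orf_aa = orf$max_orf_aa,
                      gc_pct = gc_content(seqs$sequence))

  fpkm_max <- profiles |>
    group_by(.data$transcript_id) |>
    summarise(fpkm_max = max(.data$fpkm), .groups = "drop")
  lookup <- spans |>
    mutate(expr_id = if_else(
      .data$source_class == "annotated_coding" &
        !is.na(.data$gene_id) &
        !(.data$transcript_id %in% fpkm_max$transcript_id),
      .data$gene_id, .data$transcript_id))

  anti <- overlap_table(transcripts, genes, mode = mode,
                        relation = "antisense")
  sense <- overlap_table(transcripts, genes, mode = "exonic",
                         relation = "sense")
  best_anti <- anti |>
    group_by(.data$transcript_id) |>
    summarise(overlap_nt = max(.data$overlap_nt), .groups = "drop")
  sense_tot <- sense |>
    group_by(.data$transcript_id) |>
    summarise(sense_overlap_nt = sum(.data$overlap_nt), .groups = "drop")

  out <- lookup |>
    left_join(seq_stats, by = "transcript_id") |>
    left_join(fpkm_max |> rename(fpkm_max_val = "fpkm_max"),
              by = c(expr_id = "transcript_id")) |>
    left_join(best_anti, by = "transcript_id") |>
    left_join(sense_tot, by = "transcript_id") |>
    mutate(
      fpkm_max = if_else(is.na(.data$fpkm_max_val), 0, .data$fpkm_max_val),
      overlap_nt = if_else(is.na(.data$overlap_nt), 0, .data$overlap_nt),
      sense_overlap_nt = if_else(is.na(.data$sense_overlap_nt), 0,
                                 .data$sense_overlap_nt),
      label = case_when(
        .data$source_class == "annotated_coding" ~ "REJECT_ANNOTATED",
        .data$sense_overlap_nt > 0 ~ "REJECT_SENSE_OVERLAP",
        .data$length_nt < thresholds$min_length_nt ~ "REJECT_SHORT",
        .data$orf_aa > thresholds$max_orf_aa ~ "REJECT_ORF",
        .data$fpkm_max < thresholds$min_fpkm_max ~ "REJECT_LOW_FPKM",
        .data$overlap_nt >= thresholds$min_overlap_nt ~ "NAT",
        .data$overlap_nt == 0 ~ "LINCRNA",
        TRUE ~ "REJECT_SUBTHRESHOLD_OVERLAP"
      )
    )

  nat_ids <- out$transcript_id[out$label == "NAT"]
  cognates <- map(nat_ids, function(id) {
    assign_cognate_gene(transcripts |> filter(.data$transcript_id == id),
                        genes, thresholds, mode = mode)
  }) |> list_rbind()
  if (nrow(cognates) == 0) {
    cognates <- tibble(nat_id = character(), cognate_gene_id = character(),
                       overlap_nt = integer(), overlap_class = character(),
                       contains_gene = logical())
  }

  out |>
    left_join(cognates |>
                select(transcript_id = "nat_id",
                       cognate_gene = "cognate_gene_id",
                       cognate_overlap_nt = "overlap_nt",
                       "overlap_class", "contains_gene"),
              by = "transcript_id") |>
    mutate(overlap_nt = if_else(!is.na(.data$cognate_overlap_nt),
                                .data$cognate_overlap_nt, .data$overlap_nt)) |>
    select("transcript_id", "gene_id", "label", "length_nt", "orf_aa",
           "gc_pct", "fpkm_max", "sense_overlap_nt", "overlap_nt",
           "cognate_gene", "overlap_class", "contains_gene", "source_class")
}

#' Fraction of annotated genes covered by a NAT
#'
#' Percent of gene models having at least one antisense NAT at or above the
#' minimum overlap (as cognate or secondary overlap).
#'
#' @param nat_overlaps Tibble `transcript_id`, `gene_id`, `overlap_nt`
#'   restricted to transcripts labelled NAT (see [classify_candidates()]);
#'   a classification tibble also works (cognate genes only).
#' @param genes Exon-level gene-model tibble.
#' @param min_overlap_nt Minimum qualifying overlap, nucleotides.
#' @return Percent in `[0, 100]`.
#' @export
genome_nat_coverage <- function(nat_overlaps, genes, min_overlap_nt = 50) {
  n_genes <- dplyr::n_distinct(genes$gene_id)
  if (n_genes == 0) abort("validation error: empty gene list")
  if ("label" %in% names(nat_overlaps)) {
    covered <- nat_overlaps |>
      filter(.data$label == "NAT", !is.na(.data$cognate_gene)) |>
      pull("cognate_gene")
  } else {
    covered <- nat_overlaps |>
      filter(.data$overlap_nt >= min_overlap_nt) |>
      pull("gene_id")
  }
  100 * dplyr::n_distinct(covered) / n_genes
}
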