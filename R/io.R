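# Readers and writers for the standard formats the pipeline touches.
#
# Internal coordinate convention: 0-based half-open intervals on a named
# chromosome with strand "+" or "-".  GTF/GFF3 files are 1-based inclusive;
# conversion happens at the I/O boundary and nowhere else, so an overlap
# length is always max(0, min(end) - max(start)) with no off-by-one cases.

#' Read assembled transcripts from a GTF file
#'
#' Parses exon features, groups them by `transcript_id`, converts coordinates
#' to the internal 0-based half-open convention and validates the result.
#' Transcripts with unstranded exons (strand `.`) are rejected rather than
#' guessed: the pipeline is strand-specific by construction.
#'
#' @param path Path to a GTF file (1-based inclusive coordinates, strand in
#'   column 7, `transcript_id` attribute on every exon feature).
#'
#' @return A tibble with one row per exon: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `source_class`
#'   (`"assembled_novel"` unless the file carries a `source_class`
#'   attribute).  Exons are sorted by start within each transcript.
#' @seealso [write_gtf()], [transcript_spans()]
#' @export
read_gtf <- function(path) {
  validate_feature_lines(path, min_fields = 9)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- as.data.frame(gr)
  mc <- mc[tolower(mc$type) == "exon", , drop = FALSE]
  cols <- colnames(mc)
  if (nrow(mc) > 0 && !"transcript_id" %in% cols) {
    abort(paste0("GTF file has exon features without a transcript_id ",
                 "attribute: ", path))
  }
  tx <- tibble(
    transcript_id = if (nrow(mc)) as.character(mc$transcript_id) else character(),
    gene_id = if ("gene_id" %in% cols) as.character(mc$gene_id) else
      rep(NA_character_, nrow(mc)),
    chrom = as.character(mc$seqnames),
    start = as.integer(mc$start) - 1L,
    end = as.integer(mc$end),
    strand = as.character(mc$strand),
    source_class = if ("source_class" %in% cols)
      as.character(mc$source_class) else rep(NA_character_, nrow(mc))
  )
  tx <- tx |>
    mutate(source_class = if_else(is.na(.data$source_class),
                                  "assembled_novel", .data$source_class)) |>
    arrange(.data$transcript_id, .data$start)
  if (anyNA(tx$transcript_id)) {
    abort("exon feature without transcript_id attribute")
  }
  validate_transcripts(tx)
  tx
}

#' Write transcripts to a GTF file
#'
#' Emits one exon feature per exon row, converting back to 1-based inclusive
#' coordinates.  `write_gtf()` then [read_gtf()] reproduces ids, strands and
#' exon coordinates exactly.
#'
#' @param transcripts Exon-level transcript tibble as returned by
#'   [read_gtf()].
#' @param path Output file path.
#' @param extra_attributes Optional tibble keyed by `transcript_id` whose
#'   remaining columns are written as additional GTF attributes on every exon
#'   of that transcript (e.g. `overlap_class`, `cognate_gene`).
#' @param source Value for the GTF source column.
#' @return The path, invisibly.
#' @export
write_gtf <- function(transcripts, path, extra_attributes = NULL,
                      source = "natpairs") {
  validate_transcripts(transcripts)
  header <- sprintf("# natpairs %s exon features; 1-based inclusive coordinates",
                    utils::packageVersion("natpairs"))
  if (nrow(transcripts) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  tx <- transcripts
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; source_class "%s";',
                      if_else(is.na(tx$gene_id), tx$transcript_id, tx$gene_id),
                      tx$transcript_id, tx$source_class)
  if (!is.null(extra_attributes)) {
    stopifnot("transcript_id" %in% names(extra_attributes))
    extra <- extra_attributes
    for (col in setdiff(names(extra), "transcript_id")) {
      val <- extra[[col]][match(tx$transcript_id, extra$transcript_id)]
      add <- sprintf(' %s "%s";', col, val)
      add[is.na(val)] <- ""
      attr_str <- paste0(attr_str, add)
    }
  }
  lines <- sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                   tx$chrom, source, tx$start + 1L, tx$end, tx$strand,
                   attr_str)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read protein-coding gene models from a GFF3 or GTF annotation
#'
#' Accepts either dialect (GFF3 `ID`/`Parent` linkage or GTF
#' `gene_id`/`transcript_id` attributes).  Features whose
#' `biotype`/`gene_biotype` attribute is present and differs from
#' `protein_coding` are excluded.  The gene span is the hull of its exons.
#'
#' @param path Path to a GFF3 or GTF annotation.
#' @param format `"gff3"`, `"gtf"`, or `NULL` to guess from the file
#'   extension and content.
#' @return A tibble with one row per exon: `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, sorted by gene and start.
#' @export
read_gene_models <- function(path, format = NULL) {
  format <- format %||% guess_annotation_format(path)
  validate_feature_lines(path, min_fields = 9)
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  df$type <- tolower(as.character(df$type))

  if (format == "gff3") {
    exons <- gff3_gene_exons(df)
  } else {
    keep <- df$type == "exon"
    if (any(keep) && !"gene_id" %in% colnames(df)) {
      abort("GTF annotation has exon features without gene_id")
    }
    exons <- df[keep, , drop = FALSE]
    if ("gene_biotype" %in% colnames(exons)) {
      exons <- exons[is.na(exons$gene_biotype) |
                       exons$gene_biotype == "protein_coding", , drop = FALSE]
    }
    exons$.gene <- as.character(exons$gene_id)
  }

  genes <- tibble(
    gene_id = exons$.gene,
    chrom = as.character(exons$seqnames),
    start = as.integer(exons$start) - 1L,
    end = as.integer(exons$end),
    strand = as.character(exons$strand)
  ) |>
    arrange(.data$gene_id, .data$start)
  validate_gene_models(genes)
  genes
}

# Resolve exon -> (mRNA ->) gene parentage in a GFF3 data frame, applying the
# protein_coding biotype filter at the gene level, and flagging duplicate or
# exon-less genes.
gff3_gene_exons <- function(df) {
  id_of <- function(rows) as.character(rows$ID)
  parent_of <- function(rows) {
    vapply(rows$Parent, function(p) {
      p <- as.character(p)
      if (length(p) == 0) NA_character_ else p[[1]]
    }, character(1))
  }
  genes <- df[df$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) abort("GFF3 annotation contains no gene features")
  gid <- id_of(genes)
  if (anyDuplicated(gid)) {
    abort(paste0("duplicate gene_id in annotation: ",
                 paste(unique(gid[duplicated(gid)]), collapse = ", ")))
  }
  biotype <- rep(NA_character_, nrow(genes))
  for (col in c("biotype", "gene_biotype")) {
    if (col %in% colnames(genes)) biotype <- as.character(genes[[col]])
  }
  coding <- gid[is.na(biotype) | biotype == "protein_coding"]

  rnas <- df[df$type %in% c("mrna", "transcript"), , drop = FALSE]
  rna_gene <- setNames(parent_of(rnas), id_of(rnas))

  exons <- df[df$type == "exon", , drop = FALSE]
  ep <- parent_of(exons)
  exons$.gene <- if_else(ep %in% names(rna_gene),
                         unname(rna_gene[ep]), ep)
  orphan <- setdiff(coding, exons$.gene)
  if (length(orphan) > 0) {
    abort(paste0("gene without exons in annotation: ",
                 paste(orphan, collapse = ", ")))
  }
  exons[exons$.gene %in% coding, , drop = FALSE]
}

guess_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "gtf") return("gtf")
  first <- readLines(path, n = 1)
  if (length(first) && grepl("^##gff-version", first)) "gff3" else "gtf"
}

# Light line-level validation with line numbers, ahead of the rtracklayer
# parse whose errors do not name lines.  Checks field count, numeric and
# ordered coordinates, and a definite strand.
validate_feature_lines <- function(path, min_fields = 9) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < min_fields) {
      abort(sprintf("parse error at line %d: expected %d tab-separated fields, found %d",
                    i, min_fields, length(fields)))
    }
    start <- suppressWarnings(as.numeric(fields[4]))
    end <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("parse error at line %d: non-numeric coordinates", i))
    }
    if (end < start) {
      abort(sprintf("validation error at line %d: end (%s) < start (%s)",
                    i, fields[5], fields[4]))
    }
    if (!fields[7] %in% c("+", "-")) {
      abort(sprintf(paste0("validation error at line %d: strand must be '+' or ",
                           "'-' (strand-specific data required), found '%s'"),
                    i, fields[7]))
    }
  }
  invisible(TRUE)
}

validate_transcripts <- function(tx) {
  required <- c("transcript_id", "chrom", "start", "end", "strand")
  missing <- setdiff(required, names(tx))
  if (length(missing) > 0) {
    abort(paste0("transcript table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(tx) == 0) return(invisible(tx))
  if (any(tx$end <= tx$start)) {
    bad <- tx$transcript_id[tx$end <= tx$start][1]
    abort(paste0("validation error: exon with end <= start in transcript ", bad))
  }
  if (!all(tx$strand %in% c("+", "-"))) {
    bad <- unique(tx$transcript_id[!tx$strand %in% c("+", "-")])
    abort(paste0("validation error: unstranded or invalid strand for transcript(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  chk <- tx |>
    group_by(.data$transcript_id) |>
    summarise(
      n_chrom = dplyr::n_distinct(.data$chrom),
      n_strand = dplyr::n_distinct(.data$strand),
      overlapping = {
        o <- order(.data$start)
        s <- .data$start[o]
        e <- .data$end[o]
        length(s) > 1 && any(s[-1] < e[-length(e)])
      },
      .groups = "drop"
    )
  if (any(chk$n_chrom > 1) || any(chk$n_strand > 1)) {
    bad <- chk$transcript_id[chk$n_chrom > 1 | chk$n_strand > 1]
    abort(paste0("validation error: exons on mixed chromosomes/strands for ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (any(chk$overlapping)) {
    bad <- chk$transcript_id[chk$overlapping]
    abort(paste0("validation error: overlapping exons within transcript(s) ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(tx)
}

validate_gene_models <- function(genes) {
  if (nrow(genes) == 0) abort("annotation yielded no protein-coding gene models")
  if (any(genes$end <= genes$start)) abort("gene exon with end <= start")
  chk <- genes |>
    group_by(.data$gene_id) |>
    summarise(n_chrom = dplyr::n_distinct(.data$chrom),
              n_strand = dplyr::n_distinct(.data$strand), .groups = "drop")
  if (any(chk$n_chrom > 1) || any(chk$n_strand > 1)) {
    bad <- chk$gene_id[chk$n_chrom > 1 | chk$n_strand > 1]
    abort(paste0("gene model on mixed chromosomes/strands: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  invisible(genes)
}

#' Collapse exon-level tables to one row per transcript or gene
#'
#' @param transcripts Exon-level transcript tibble ([read_gtf()]).
#' @return A tibble with one row per transcript: span coordinates (hull of
#'   exons), spliced length (sum of exon lengths), exon count and metadata.
#' @export
transcript_spans <- function(transcripts) {
  transcripts |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      # spliced length before start/end are collapsed: summarise exposes
      # already-summarised columns to later expressions
      length_nt = sum(.data$end - .data$start),
      n_exons = n(),
      source_class = first(.data$source_class),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    select("transcript_id", "gene_id", "chrom", "strand", "start", "end",
           "length_nt", "n_exons", "source_class")
}

#' @rdname transcript_spans
#' @param genes Exon-level gene-model tibble ([read_gene_models()]).
#' @export
gene_spans <- function(genes) {
  genes |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      exonic_length_nt = sum(.data$end - .data$start),
      n_exons = n(),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    select("gene_id", "chrom", "strand", "start", "end",
           "exonic_length_nt", "n_exons")
}

#' Read a genome FASTA file
#'
#' @param path Multi-record, possibly line-wrapped FASTA.  Record names are
#'   trimmed at the first whitespace.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Read a per-sample expression table
#'
#' Reads a TSV whose first column holds transcript identifiers and remaining
#' columns one sample each, and joins the sample annotation.  No imputation:
#' missing or negative values are errors.
#'
#' @param path TSV file path (lines starting `#` are ignored).
#' @param sample_map Tibble with columns `sample`, `condition` (one of
#'   C4, P4, P8, R4, C8), `replicate`, and -- when `value_type` is
#'   `"count"` -- `library_total` (total mapped fragments per sample).
#' @param value_type `"count"` (fragment counts) or `"fpkm"`.
#' @return A long tibble: `transcript_id`, `sample`, `condition`,
#'   `replicate`, `value`, `value_type`, `library_total` (NA in FPKM mode).
#' @export
read_expression_table <- function(path, sample_map,
                                  value_type = c("count", "fpkm")) {
  value_type <- match.arg(value_type)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tab)[1] <- "transcript_id"
  build_expression_table(tab, sample_map, value_type)
}

#' @rdname read_expression_table
#' @param values Wide tibble (`transcript_id` column plus one column per
#'   sample), already in memory.
#' @export
build_expression_table <- function(values, sample_map,
                                   value_type = c("count", "fpkm")) {
  value_type <- match.arg(value_type)
  sample_map <- as_tibble(sample_map)
  required <- c("sample", "condition", "replicate")
  missing <- setdiff(required, names(sample_map))
  if (length(missing) > 0) {
    abort(paste0("sample_map lacks columns: ", paste(missing, collapse = ", ")))
  }
  bad_cond <- setdiff(unique(sample_map$condition), PI_CONDITIONS)
  if (length(bad_cond) > 0) {
    abort(paste0("configuration error: unknown condition tag(s): ",
                 paste(bad_cond, collapse = ", "),
                 " (expected ", paste(PI_CONDITIONS, collapse = "/"), ")"))
  }
  sample_cols <- setdiff(names(values), "transcript_id")
  unmapped <- setdiff(sample_cols, sample_map$sample)
  if (length(unmapped) > 0) {
    abort(paste0("configuration error: sample column(s) not in sample_map: ",
                 paste(unmapped, collapse = ", ")))
  }
  absent <- setdiff(sample_map$sample, sample_cols)
  if (length(absent) > 0) {
    abort(paste0("configuration error: sample_map entries missing from table: ",
                 paste(absent, collapse = ", ")))
  }
  if (value_type == "count") {
    if (!"library_total" %in% names(sample_map)) {
      abort("count tables require `library_total` in sample_map")
    }
    if (any(is.na(sample_map$library_total) | sample_map$library_total <= 0)) {
      abort("library_total must be positive for every sample")
    }
  } else if (!"library_total" %in% names(sample_map)) {
    sample_map$library_total <- NA_real_
  }

  long <- values |>
    pivot_longer(all_of(sample_cols), names_to = "sample",
                 values_to = "value") |>
    left_join(sample_map, by = "sample") |>
    mutate(value_type = value_type) |>
    select("transcript_id", "sample", "condition", "replicate", "value",
           "value_type", "library_total")
  if (anyNA(long$value)) {
    bad <- long$transcript_id[is.na(long$value)][1]
    abort(paste0("validation error: missing expression value (no imputation), ",
                 "first offender: ", bad))
  }
  if (any(long$value < 0)) {
    bad <- long$transcript_id[long$value < 0][1]
    abort(paste0("validation error: negative expression value for ", bad))
  }
  long
}

# Tab-delimited result writer with a commented parameter header, shared by
# every pipeline output.
write_result_tsv <- function(df, path, params = NULL) {
  header <- sprintf("# natpairs %s", utils::packageVersion("natpairs"))
  if (!is.null(params)) {
    kv <- vapply(names(params), function(k) sprintf("%s=%s", k, params[[k]]),
                 character(1))
    header <- c(header, paste0("# ", paste(kv, collapse = "; ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
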