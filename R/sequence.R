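# Sequence-level computations feeding the lncRNA filters: spliced transcript
# extraction, GC content, and longest-ORF prediction.
#
# The ORF scanner deliberately replaces a trained gene-finder: the coding
# filter only needs an upper bound on coding potential, so a deterministic
# longest-ORF scan (ATG ... in-frame stop, sense strand, three frames) is
# both sufficient and exactly testable against brute-force enumeration.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates exon sequences in genomic order and reverse-complements the
#' whole for minus-strand transcripts, yielding the 5'-to-3' sequence in
#' transcript orientation.
#'
#' @param transcripts Exon-level transcript tibble ([read_gtf()]).
#' @param genome A [Biostrings::DNAStringSet] (or named character vector) of
#'   chromosome sequences.
#' @return A tibble: `transcript_id`, `sequence` (uppercase character).
#' @export
spliced_sequence <- function(transcripts, genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  validate_transcripts(transcripts)
  missing_chrom <- setdiff(unique(transcripts$chrom), names(genome))
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  widths <- setNames(Biostrings::width(genome), names(genome))
  oob <- transcripts$end > widths[transcripts$chrom] | transcripts$start < 0
  if (any(oob)) {
    bad <- transcripts$transcript_id[oob][1]
    abort(paste0("validation error: exon out of chromosome bounds in ", bad))
  }
  transcripts |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      sequence = {
        chrom_seq <- genome[[first(.data$chrom)]]
        pieces <- as.character(Biostrings::DNAStringSet(
          chrom_seq, start = .data$start + 1L, end = .data$end))
        s <- paste(pieces, collapse = "")
        if (first(.data$strand) == "-") {
          s <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        }
        toupper(s)
      },
      .groups = "drop"
    )
}

#' GC content of nucleotide sequences
#'
#' Percent G+C among called bases; `N` is excluded from both numerator and
#' denominator, so the value is invariant under reverse complement.
#'
#' @param sequence Character vector of sequences over `A`, `C`, `G`, `T`,
#'   `N` (case-insensitive).
#' @return Numeric vector of percentages in `[0, 100]`.
#' @export
gc_content <- function(sequence) {
  sequence <- str_to_upper(sequence)
  check_nucleotides(sequence)
  gc <- str_count(sequence, "[GC]")
  acgt <- str_count(sequence, "[ACGT]")
  if (any(acgt == 0)) {
    abort("undefined GC content: empty or all-N sequence")
  }
  100 * gc / acgt
}

#' Longest open reading frame, in amino acids
#'
#' Scans the given (sense) strand in all three frames for spans starting at
#' `ATG` and ending at the first in-frame stop codon (`TAA`/`TAG`/`TGA`),
#' and reports the longest, counted in coding codons excluding the stop.
#' Codons containing `N` match neither `ATG` nor a stop.  Antisense frames
#' are not scanned: with strand-specific data an antisense ORF belongs to
#' the transcript on the opposite strand.
#'
#' @param sequence Character vector of nucleotide sequences.
#' @param require_stop When `TRUE` (default) an ORF must terminate at an
#'   in-frame stop within the sequence; when `FALSE`, open-ended ORFs are
#'   counted up to the sequence end (sensitivity analysis).
#' @return A tibble with one row per input sequence: `max_orf_aa`
#'   (0 when no ORF exists), `frame` (0/1/2), `start_offset` (0-based
#'   position of the ATG); `frame` and `start_offset` are `NA` when
#'   `max_orf_aa` is 0.  Ties resolve to the smallest frame, then the
#'   smallest offset.
#' @export
longest_orf_aa <- function(sequence, require_stop = TRUE) {
  sequence <- str_to_upper(sequence)
  check_nucleotides(sequence)
  res <- map(sequence, orf_scan_one, require_stop = require_stop)
  tibble(
    max_orf_aa = map_int(res, "aa"),
    frame = map_int(res, "frame"),
    start_offset = map_int(res, "offset")
  )
}

orf_scan_one <- function(seq, require_stop) {
  n <- nchar(seq)
  best <- list(aa = 0L, frame = NA_integer_, offset = NA_integer_)
  if (n < 3) return(best)
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3
    if (n_codons < 1) next
    codon_starts <- frame + 3L * (seq_len(n_codons) - 1L)  # 0-based
    codons <- substring(seq, codon_starts + 1L, codon_starts + 3L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0) next
    stops <- which(codons %in% STOP_CODONS)
    for (i in atg) {
      nxt <- stops[stops > i]
      if (length(nxt) > 0) {
        aa <- nxt[1] - i
      } else if (!require_stop) {
        aa <- n_codons - i + 1L
      } else {
        next
      }
      if (aa > best$aa) {
        best <- list(aa = as.integer(aa), frame = frame,
                     offset = codon_starts[i])
      }
    }
  }
  best
}

check_nucleotides <- function(sequence) {
  bad <- str_detect(sequence, "[^ACGTN]")
  if (any(bad)) {
    abort(paste0("validation error: sequence contains characters outside ",
                 "A/C/G/T/N (first offender index ", which(bad)[1], ")"))
  }
  invisible(sequence)
}
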