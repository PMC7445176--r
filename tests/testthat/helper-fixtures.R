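# Builders for tiny in-code fixtures and the independent oracles used to
# cross-check the package's interval, ORF and exact-test computations.

make_tx <- function(id, exons, strand = "+", chrom = "chr1",
                    gene_id = NA_character_,
                    source_class = "assembled_novel") {
  tibble::tibble(
    transcript_id = id,
    gene_id = gene_id,
    chrom = chrom,
    start = vapply(exons, `[[`, numeric(1), 1),
    end = vapply(exons, `[[`, numeric(1), 2),
    strand = strand,
    source_class = source_class
  )
}

make_gene <- function(id, exons, strand = "+", chrom = "chr1") {
  tibble::tibble(
    gene_id = id,
    chrom = chrom,
    start = vapply(exons, `[[`, numeric(1), 1),
    end = vapply(exons, `[[`, numeric(1), 2),
    strand = strand
  )
}

# Minimal pooled profile table from a named list of per-condition FPKM
# vectors (names are transcript ids).
make_profiles <- function(fpkm_by_condition) {
  purrr::imap(fpkm_by_condition, function(v, id) {
    tibble::tibble(
      transcript_id = id,
      condition = names(v),
      count = NA_real_, library_total = NA_real_,
      fpkm = unname(v)
    )
  }) |> purrr::list_rbind()
}

# Pooled profiles from per-condition counts at a fixed library total and
# length, so Fisher p-values are available.
profiles_from_counts <- function(counts_by_id, library_total = 2e6,
                                 length_nt = 1000) {
  purrr::imap(counts_by_id, function(cnt, id) {
    tibble::tibble(
      transcript_id = id, condition = names(cnt),
      count = unname(cnt), library_total = library_total,
      fpkm = unname(cnt) * 1e9 / (library_total * length_nt)
    )
  }) |> purrr::list_rbind()
}

# --- independent oracles -------------------------------------------------

# Per-base boolean-array intersection of two exon sets on one chromosome.
oracle_overlap_perbase <- function(a, b, limit = 20000) {
  av <- logical(limit); bv <- logical(limit)
  for (i in seq_len(nrow(a))) av[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) bv[(b$start[i] + 1):b$end[i]] <- TRUE
  sum(av & bv)
}

# Brute-force longest ORF: every ATG position, walk codons to the first
# stop; no frame bookkeeping shared with the implementation.
oracle_orf_brute <- function(seq, require_stop = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  best <- 0L
  i <- 1L
  while (i + 2 <= n) {
    if (substr(seq, i, i + 2) == "ATG") {
      j <- i + 3L
      aa <- 1L
      found <- FALSE
      while (j + 2 <= n) {
        if (substr(seq, j, j + 2) %in% stops) {
          found <- TRUE
          break
        }
        aa <- aa + 1L
        j <- j + 3L
      }
      len <- if (found) aa else if (!require_stop) {
        1L + (n - (i + 3L) + 1L) %/% 3L  # codons to sequence end
      } else {
        0L
      }
      # when no stop is found `aa` overcounts a trailing partial codon;
      # recompute cleanly for the open-ended case
      if (!found && !require_stop) len <- (n - i + 1L) %/% 3L
      best <- max(best, len)
    }
    i <- i + 1L
  }
  best
}

# Exact two-sided Fisher p by explicit choose() arithmetic (independent of
# stats::dhyper), using the point-probability rule.
oracle_fisher <- function(c1, n1, c2, n2) {
  t <- c1 + c2
  k <- max(0, t - n2):min(n1, t)
  probs <- exp(lchoose(n1, k) + lchoose(n2, t - k) - lchoose(n1 + n2, t))
  p_obs <- probs[k == c1]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random disjoint sorted exon set within [0, limit).
random_exons <- function(max_exons = 4, limit = 10000) {
  k <- sample(seq_len(max_exons), 1)
  cuts <- sort(sample(0:(limit - 1), 2 * k))
  starts <- cuts[seq(1, 2 * k, 2)]
  ends <- cuts[seq(2, 2 * k, 2)]
  keep <- ends > starts
  if (!any(keep)) return(tibble::tibble(start = 0, end = 1))
  tibble::tibble(start = starts[keep], end = ends[keep])
}
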