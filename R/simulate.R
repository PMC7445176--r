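# Seeded synthetic stranded-transcriptome generator with planted ground
# truth: genome FASTA, protein-coding annotation, assembled-transcript GTF
# and count tables over the five phosphate conditions, such that every
# pipeline stage has a known right answer.
#
# Layout strategy: genes are placed left to right on one chromosome with
# generous intergenic padding; each planted NAT is drawn on the opposite
# strand of its designated gene with the geometry of its class (containment
# for FULL, 5'/5' partial overlap for HEAD_TO_HEAD, 3'/3' for
# TAIL_TO_TAIL).  Planted noncoding transcripts are kept shorter than one
# ORF-threshold window (<= 300 nt < 3 x (100 + 2) nt), so their coding
# potential is decided by construction, not by the base composition of the
# random background; coding ORFs (genes, and the ORF-decoy's 120 aa frame)
# are written explicitly into the genome sequence.

#' Configuration for the synthetic dataset
#'
#' Defaults describe the reference validation design: 20 genes, ten NATs
#' (4 fully overlapped, 3 head-to-head, 3 tail-to-tail), five lincRNAs,
#' eight decoys (two per reject class), all ten NATs Pi-responsive (7 up,
#' 3 down), six concordant and three discordant NAT-mRNA pairs, two
#' replicates per condition at one million mapped fragments, fourfold
#' planted effects and negative-binomial dispersion 10.
#'
#' @param seed Integer seed; a fixed seed makes every emitted file
#'   byte-identical across runs.
#' @param n_genes Number of protein-coding genes.
#' @param n_nats Named counts per overlap class
#'   (`FULL`, `HEAD_TO_HEAD`, `TAIL_TO_TAIL`).
#' @param n_lincrnas Number of intergenic lncRNAs (no gene overlap).
#' @param n_decoys Named counts per reject class (`short`: 150 nt;
#'   `orf`: planted 120 aa frame; `low_fpkm`: FPKMmax 0.5;
#'   `subthreshold`: 30 nt antisense overlap).
#' @param gc_target Genome GC percent for the i.i.d. background.
#' @param replicates Replicates per condition (>= 2).
#' @param library_size Total mapped fragments per sample.
#' @param dispersion Negative-binomial size parameter for replicate counts.
#' @param n_responsive_up,n_responsive_down Planted UP-/DOWN-Pi-responsive
#'   NAT counts (assigned to the first NATs in class order).
#' @param n_pairs_concordant,n_pairs_discordant Planted pair counts among
#'   the responsive NATs (cognate mRNA follows / opposes the NAT pattern).
#' @param effect_fold Planted fold change at the depleted time points.
#' @param noise_free Debug mode: replicate counts are the rounded planted
#'   means (no sampling noise).
#' @param multi_exon Plant a two-exon structure (60 nt intron) on each gene
#'   model, clear of every planted overlap window, to exercise
#'   exonic-overlap mode.
#' @param chrom_name Chromosome name for all features.
#' @return A validated `sim_config` object (named list).
#' @export
sim_config <- function(seed = 1, n_genes = 20,
                       n_nats = c(FULL = 4, HEAD_TO_HEAD = 3, TAIL_TO_TAIL = 3),
                       n_lincrnas = 5,
                       n_decoys = c(short = 2, orf = 2, low_fpkm = 2,
                                    subthreshold = 2),
                       gc_target = 48, replicates = 2, library_size = 1e6,
                       dispersion = 10, n_responsive_up = 7,
                       n_responsive_down = 3, n_pairs_concordant = 6,
                       n_pairs_discordant = 3, effect_fold = 4,
                       noise_free = FALSE, multi_exon = FALSE,
                       chrom_name = "chr1") {
  n_nats <- fill_named(n_nats, c("FULL", "HEAD_TO_HEAD", "TAIL_TO_TAIL"))
  n_decoys <- fill_named(n_decoys, c("short", "orf", "low_fpkm", "subthreshold"))
  cfg <- list(
    seed = as.integer(seed), n_genes = n_genes, n_nats = n_nats,
    n_lincrnas = n_lincrnas, n_decoys = n_decoys, gc_target = gc_target,
    replicates = replicates, library_size = library_size,
    dispersion = dispersion, n_responsive_up = n_responsive_up,
    n_responsive_down = n_responsive_down,
    n_pairs_concordant = n_pairs_concordant,
    n_pairs_discordant = n_pairs_discordant, effect_fold = effect_fold,
    noise_free = noise_free, multi_exon = multi_exon,
    chrom_name = chrom_name
  )
  n_nat <- sum(cfg$n_nats)
  n_resp <- cfg$n_responsive_up + cfg$n_responsive_down
  n_pairs <- cfg$n_pairs_concordant + cfg$n_pairs_discordant
  if (n_resp > n_nat) abort("configuration error: more responsive NATs than NATs")
  if (n_pairs > n_resp) {
    abort("configuration error: planted pairs exceed planted responsive NATs")
  }
  if (cfg$n_genes < n_nat + cfg$n_decoys[["subthreshold"]]) {
    abort(paste0("configuration error: need at least ",
                 n_nat + cfg$n_decoys[["subthreshold"]],
                 " genes to host all antisense features"))
  }
  if (cfg$replicates < 2) abort("configuration error: need >= 2 replicates")
  if (cfg$gc_target <= 0 || cfg$gc_target >= 100) {
    abort("configuration error: gc_target must be a percent in (0, 100)")
  }
  if (cfg$effect_fold <= 1) abort("configuration error: effect_fold must exceed 1")
  structure(cfg, class = "sim_config")
}

fill_named <- function(x, keys) {
  out <- setNames(rep(0, length(keys)), keys)
  if (is.null(names(x))) {
    if (length(x) != length(keys)) abort("counts must be named")
    names(x) <- keys
  }
  bad <- setdiff(names(x), keys)
  if (length(bad) > 0) {
    abort(paste0("configuration error: unknown count name(s): ",
                 paste(bad, collapse = ", ")))
  }
  out[names(x)] <- x
  if (any(out < 0)) abort("configuration error: counts must be >= 0")
  out
}

#' Simulate the annotation: gene models, candidate transcripts, ground truth
#'
#' Deterministic given the config (uses its own RNG substream, so it can be
#' called independently of [simulate_genome()]).
#'
#' @param config A [sim_config()] object.
#' @return A list: `genes` (exon tibble), `transcripts` (exon tibble of
#'   mRNAs plus all planted candidates), `truth` (one row per transcript
#'   with planted category, expected classification label, overlap class,
#'   cognate gene, response pattern, pair concordance and the id under
#'   which it appears in the count table), `layout` (coding-frame planting
#'   instructions for [simulate_genome()]), `genome_length`.
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chrom <- config$chrom_name
  cursor <- 500L
  genes <- list(); tx <- list(); truth <- list(); cds_plan <- list()

  n_nat <- sum(config$n_nats)
  nat_class_seq <- rep(names(config$n_nats), config$n_nats)
  n_sub <- config$n_decoys[["subthreshold"]]
  # genes 1..n_nat host NATs; the next n_sub host subthreshold decoys
  host_of <- c(nat_class_seq, rep("subthreshold", n_sub),
               rep("none", config$n_genes - n_nat - n_sub))

  nat_i <- 0L; sub_i <- 0L
  for (i in seq_len(config$n_genes)) {
    gene_id <- sprintf("g%03d", i)
    gene_len <- sample(900:1500, 1)
    gstrand <- sample(c("+", "-"), 1)
    gs <- cursor + 400L
    ge <- gs + gene_len
    cursor <- ge + 400L
    hosted <- host_of[i]

    # gene exons (optionally split by a 60 nt intron placed clear of every
    # planted overlap window)
    if (config$multi_exon) {
      ifrac <- if (hosted == "FULL") 0.75 else 0.5
      istart <- gs + as.integer(floor(gene_len * ifrac))
      gene_ex <- tibble(start = c(gs, istart + 60L), end = c(istart, ge))
    } else {
      gene_ex <- tibble(start = gs, end = ge)
    }
    genes[[gene_id]] <- gene_ex |>
      mutate(gene_id = gene_id, chrom = chrom, strand = gstrand)

    # coding frame: planted inside the longest exon
    aa_len <- sample(110:140, 1)
    cds_len <- 3L * (aa_len + 1L)
    big <- which.max(gene_ex$end - gene_ex$start)
    cds_plan[[gene_id]] <- tibble(
      start = gene_ex$start[big] + 30L, length = cds_len,
      aa = aa_len, strand = gstrand
    )

    mrna_id <- paste0(gene_id, ".t1")
    tx[[mrna_id]] <- genes[[gene_id]] |>
      transmute(transcript_id = mrna_id, gene_id = gene_id,
                chrom = .data$chrom, start = .data$start, end = .data$end,
                strand = .data$strand, source_class = "annotated_coding")
    truth[[mrna_id]] <- tibble(
      transcript_id = mrna_id, category = "mRNA",
      expected_label = "REJECT_ANNOTATED", cognate_gene = NA_character_,
      overlap_class = NA_character_, expr_id = gene_id,
      length_nt = sum(gene_ex$end - gene_ex$start)
    )

    if (hosted %in% c("FULL", "HEAD_TO_HEAD", "TAIL_TO_TAIL")) {
      nat_i <- nat_i + 1L
      nat_id <- sprintf("nat_%03d", nat_i)
      geom <- nat_geometry(hosted, gs, ge, gstrand, gene_len,
                           full_frac = if (config$multi_exon) 0.6 else 1)
      tx[[nat_id]] <- tibble(
        transcript_id = nat_id, gene_id = NA_character_, chrom = chrom,
        start = geom$start, end = geom$end,
        strand = flip_strand(gstrand), source_class = "assembled_novel"
      )
      truth[[nat_id]] <- tibble(
        transcript_id = nat_id, category = "NAT", expected_label = "NAT",
        cognate_gene = gene_id, overlap_class = hosted, expr_id = nat_id,
        length_nt = geom$end - geom$start
      )
    } else if (hosted == "subthreshold") {
      sub_i <- sub_i + 1L
      d_id <- sprintf("decoy_subthr_%02d", sub_i)
      geom <- nat_geometry("HEAD_TO_HEAD", gs, ge, gstrand, gene_len,
                           overlap_nt = 30L)
      tx[[d_id]] <- tibble(
        transcript_id = d_id, gene_id = NA_character_, chrom = chrom,
        start = geom$start, end = geom$end,
        strand = flip_strand(gstrand), source_class = "assembled_novel"
      )
      truth[[d_id]] <- tibble(
        transcript_id = d_id, category = "decoy_subthreshold",
        expected_label = "REJECT_SUBTHRESHOLD_OVERLAP",
        cognate_gene = NA_character_, overlap_class = NA_character_,
        expr_id = d_id, length_nt = geom$end - geom$start
      )
    }
  }

  # intergenic features: lincRNAs and the remaining decoy classes
  add_intergenic <- function(id, category, expected_label, len) {
    start <- cursor + 400L
    end <- start + len
    cursor <<- end
    tx[[id]] <<- tibble(
      transcript_id = id, gene_id = NA_character_, chrom = chrom,
      start = start, end = end, strand = sample(c("+", "-"), 1),
      source_class = "assembled_novel"
    )
    truth[[id]] <<- tibble(
      transcript_id = id, category = category,
      expected_label = expected_label, cognate_gene = NA_character_,
      overlap_class = NA_character_, expr_id = id, length_nt = len
    )
  }
  for (j in seq_len(config$n_lincrnas)) {
    add_intergenic(sprintf("linc_%03d", j), "lincRNA", "LINCRNA",
                   sample(210:300, 1))
  }
  for (j in seq_len(config$n_decoys[["short"]])) {
    add_intergenic(sprintf("decoy_short_%02d", j), "decoy_short",
                   "REJECT_SHORT", 150L)
  }
  for (j in seq_len(config$n_decoys[["orf"]])) {
    id <- sprintf("decoy_orf_%02d", j)
    add_intergenic(id, "decoy_orf", "REJECT_ORF", 390L)
    cds_plan[[id]] <- tibble(
      start = tx[[id]]$start + 12L, length = 3L * 121L, aa = 120L,
      strand = tx[[id]]$strand
    )
  }
  for (j in seq_len(config$n_decoys[["low_fpkm"]])) {
    add_intergenic(sprintf("decoy_lowfpkm_%02d", j), "decoy_low_fpkm",
                   "REJECT_LOW_FPKM", sample(220:300, 1))
  }

  genes_tbl <- if (length(genes)) {
    list_rbind(map(genes, \(g) select(g, "gene_id", "chrom", "start",
                                      "end", "strand")))
  } else {
    tibble(gene_id = character(), chrom = character(), start = integer(),
           end = integer(), strand = character())
  }
  tx_tbl <- if (length(tx)) list_rbind(unname(tx)) else
    tibble(transcript_id = character(), gene_id = character(),
           chrom = character(), start = integer(), end = integer(),
           strand = character(), source_class = character())
  truth_tbl <- if (length(truth)) list_rbind(unname(truth)) else
    tibble(transcript_id = character(), category = character(),
           expected_label = character(), cognate_gene = character(),
           overlap_class = character(), expr_id = character(),
           length_nt = integer())
  truth_tbl <- assign_response_plan(truth_tbl, config)

  list(
    genes = genes_tbl, transcripts = tx_tbl, truth = truth_tbl,
    layout = cds_plan,
    genome_length = max(cursor + 500L, 10000L)
  )
}

# Antisense geometry for one planted feature against its host gene.
# FULL: containment; HEAD_TO_HEAD: overlap covering the gene's 5' terminus;
# TAIL_TO_TAIL: covering its 3' terminus.  `full_frac` confines FULL NATs
# to the 5'-most fraction of the gene (keeps them clear of a planted
# intron); `overlap_nt` overrides the sampled overlap (subthreshold decoys).
nat_geometry <- function(class, gs, ge, gstrand, gene_len,
                         full_frac = 1, overlap_nt = NULL) {
  len <- sample(220:300, 1)
  if (class == "FULL") {
    hi <- as.integer(floor(gene_len * full_frac)) - len - 50L
    off <- sample(50:max(50L, hi), 1)
    return(list(start = gs + off, end = gs + off + len))
  }
  ov <- overlap_nt %||% sample(60:150, 1)
  head_end <- if (class == "HEAD_TO_HEAD") {
    if (gstrand == "+") "left" else "right"
  } else {
    if (gstrand == "+") "right" else "left"
  }
  if (head_end == "left") {
    list(start = gs + ov - len, end = gs + ov)
  } else {
    list(start = ge - ov, end = ge - ov + len)
  }
}

flip_strand <- function(s) if_else(s == "+", "-", "+")

# Deterministic (RNG-free) assignment of planted response patterns and
# pairs: the first n_responsive_up NATs (in class order) are UP, the next
# n_responsive_down DOWN; the first pairs are concordant, then discordant.
# Cognate mRNAs inherit (concordant) or mirror (discordant) the pattern.
assign_response_plan <- function(truth, config) {
  truth$response_pattern <- "NONE"
  truth$concordance <- NA_character_
  nat_ids <- truth$transcript_id[truth$category == "NAT"]
  n_up <- config$n_responsive_up; n_down <- config$n_responsive_down
  up_ids <- head(nat_ids, n_up)
  down_ids <- head(setdiff(nat_ids, up_ids), n_down)
  truth$response_pattern[truth$transcript_id %in% up_ids] <- "UP_PI_RESPONSIVE"
  truth$response_pattern[truth$transcript_id %in% down_ids] <- "DOWN_PI_RESPONSIVE"

  resp_ids <- c(up_ids, down_ids)
  conc_ids <- head(resp_ids, config$n_pairs_concordant)
  disc_ids <- head(setdiff(resp_ids, conc_ids), config$n_pairs_discordant)
  truth$concordance[truth$transcript_id %in% conc_ids] <- "CONCORDANT"
  truth$concordance[truth$transcript_id %in% disc_ids] <- "DISCORDANT"

  # propagate to cognate mRNA rows (keyed by gene id in the count table)
  for (nid in c(conc_ids, disc_ids)) {
    row <- truth[truth$transcript_id == nid, ]
    mrna <- which(truth$category == "mRNA" & truth$expr_id == row$cognate_gene)
    pat <- row$response_pattern
    if (truth$concordance[truth$transcript_id == nid] == "DISCORDANT") {
      pat <- if (pat == "UP_PI_RESPONSIVE") "DOWN_PI_RESPONSIVE" else "UP_PI_RESPONSIVE"
    }
    truth$response_pattern[mrna] <- pat
    truth$concordance[mrna] <- row$concordance
  }
  truth
}

#' Simulate the genome sequence
#'
#' An i.i.d. background at the configured GC, with coding frames (gene CDS
#' and ORF-decoy frames) written in explicitly, strand-aware.
#'
#' @param config A [sim_config()] object.
#' @param annotation Output of [simulate_annotation()]; computed from the
#'   config when omitted.
#' @return A [Biostrings::DNAStringSet] with one chromosome.
#' @export
simulate_genome <- function(config, annotation = NULL) {
  stopifnot(inherits(config, "sim_config"))
  annotation <- annotation %||% simulate_annotation(config)
  gc <- config$gc_target / 100
  set.seed(config$seed)
  bases <- sample(c("A", "C", "G", "T"), annotation$genome_length,
                  replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  set.seed(config$seed + 2L)
  for (plan in annotation$layout) {
    cds <- random_cds(plan$aa)
    if (plan$strand == "-") {
      cds <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds)))
    }
    idx <- (plan$start + 1L):(plan$start + plan$length)
    bases[idx] <- strsplit(cds, "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(bases, collapse = ""))
  names(genome) <- config$chrom_name
  genome
}

# ATG + (aa - 1) random non-stop codons + stop: an ORF of exactly `aa`
# amino acids (possibly extended by an upstream in-frame ATG, which only
# lengthens it).
random_cds <- function(aa) {
  all_codons <- as.vector(outer(outer(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"), paste0),
                                c("A", "C", "G", "T"), paste0))
  sense <- setdiff(all_codons, STOP_CODONS)
  paste0("ATG",
         paste(sample(sense, aa - 1, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}

#' Simulate the count table over the five phosphate conditions
#'
#' Per-transcript baseline means are drawn log-uniform (200 to 2000
#' fragments per replicate at the reference library size); condition means
#' multiply the baseline by the planted fold pattern (`effect_fold` at P4
#' and P8 for UP-responsive transcripts, its reciprocal for DOWN; flat
#' elsewhere, so resupply returns exactly to control level).  Replicate
#' counts are negative-binomial around the condition mean, or the rounded
#' means in `noise_free` mode.  The low-FPKM decoys instead target a
#' maximum FPKM of 0.5, below the abundance floor.
#'
#' @param truth Truth table from [simulate_annotation()].
#' @param config A [sim_config()] object.
#' @return A list: `expression` (long tibble as from
#'   [read_expression_table()]), `sample_map`, `lengths` (tibble
#'   `transcript_id`, `length_nt` keyed like the count rows).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  # force `truth` before seeding: a lazily evaluated truth expression could
  # otherwise consume or reset the RNG stream after set.seed()
  rows <- truth |>
    distinct(.data$expr_id, .keep_all = TRUE) |>
    select("expr_id", "category", "response_pattern", "length_nt")
  set.seed(config$seed + 3L)
  sample_map <- crossing(condition = factor(PI_CONDITIONS,
                                            levels = PI_CONDITIONS),
                         replicate = seq_len(config$replicates)) |>
    mutate(condition = as.character(.data$condition),
           sample = sprintf("%s_r%d", .data$condition, .data$replicate),
           library_total = config$library_size) |>
    select("sample", "condition", "replicate", "library_total")

  if (nrow(rows) == 0) {
    empty <- tibble(transcript_id = character(), sample = character(),
                    condition = character(), replicate = integer(),
                    value = numeric(), value_type = character(),
                    library_total = numeric())
    return(list(expression = empty, sample_map = sample_map,
                lengths = tibble(transcript_id = character(),
                                 length_nt = integer())))
  }
  f <- config$effect_fold
  scale <- config$library_size / 1e6
  # all baselines are drawn before any count noise, so noise-free and noisy
  # runs of the same config share identical planted means
  bases <- exp(runif(nrow(rows), log(200), log(2000))) * scale
  low <- rows$category == "decoy_low_fpkm"
  bases[low] <- 0.5 * rows$length_nt[low] * config$library_size / 1e9
  counts <- map(seq_len(nrow(rows)), function(i) {
    row <- rows[i, ]
    base <- bases[i]
    mult <- switch(row$response_pattern,
                   UP_PI_RESPONSIVE = c(C4 = 1, P4 = f, P8 = f, R4 = 1, C8 = 1),
                   DOWN_PI_RESPONSIVE = c(C4 = 1, P4 = 1 / f, P8 = 1 / f,
                                          R4 = 1, C8 = 1),
                   c(C4 = 1, P4 = 1, P8 = 1, R4 = 1, C8 = 1))
    vals <- map(PI_CONDITIONS, function(cond) {
      mu <- base * mult[[cond]]
      if (config$noise_free) {
        rep(round(mu), config$replicates)
      } else {
        rnbinom(config$replicates, mu = mu, size = config$dispersion)
      }
    })
    setNames(unlist(vals), sample_map$sample)
  })
  wide <- bind_cols(tibble(transcript_id = rows$expr_id),
                    as_tibble(do.call(rbind, counts)))
  expression <- build_expression_table(wide, sample_map, "count")
  lengths <- rows |> select(transcript_id = "expr_id", "length_nt")
  list(expression = expression, sample_map = sample_map, lengths = lengths)
}

#' Simulate a complete synthetic input set
#'
#' @param config A [sim_config()] object (or arguments passed to
#'   [sim_config()] via `...` when `config` is `NULL`).
#' @param ... Arguments forwarded to [sim_config()] when `config` is NULL.
#' @return A list with `genome`, `genes`, `transcripts`, `truth`,
#'   `expression`, `sample_map`, `lengths`, and the `config`.
#' @export
simulate_nat_dataset <- function(config = NULL, ...) {
  config <- config %||% sim_config(...)
  ann <- simulate_annotation(config)
  genome <- simulate_genome(config, ann)
  cnt <- simulate_counts(ann$truth, config)
  list(
    genome = genome, genes = ann$genes, transcripts = ann$transcripts,
    truth = ann$truth, expression = cnt$expression,
    sample_map = cnt$sample_map, lengths = cnt$lengths, config = config
  )
}

#' Write a simulated dataset to disk
#'
#' Emits `genome.fa`, `genes.gff3`, `transcripts.gtf`, `counts.tsv`,
#' `samples.tsv` and `truth.tsv` into a directory; with a fixed seed the
#' files are byte-identical across runs.
#'
#' @param sim Output of [simulate_nat_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"),
                              width = 70)
  write_gff3_genes(sim$genes, file.path(dir, "genes.gff3"))
  write_gtf(sim$transcripts, file.path(dir, "transcripts.gtf"))
  wide <- sim$expression |>
    select("transcript_id", "sample", "value") |>
    pivot_wider(names_from = "sample", values_from = "value")
  write_result_tsv(wide, file.path(dir, "counts.tsv"))
  write_result_tsv(sim$sample_map, file.path(dir, "samples.tsv"))
  write_result_tsv(sim$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

write_gff3_genes <- function(genes, path) {
  lines <- "##gff-version 3"
  spans <- gene_spans(genes)
  for (i in seq_len(nrow(spans))) {
    g <- spans[i, ]
    ex <- genes |> filter(.data$gene_id == g$gene_id) |> arrange(.data$start)
    lines <- c(
      lines,
      sprintf("%s\tnatpairs\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=protein_coding",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id),
      sprintf("%s\tnatpairs\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tnatpairs\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
              ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
              seq_len(nrow(ex)), ex$gene_id)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
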