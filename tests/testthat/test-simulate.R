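small_cfg <- function(...) {
  sim_config(seed = 17, n_genes = 12,
             n_nats = c(FULL = 2, HEAD_TO_HEAD = 2, TAIL_TO_TAIL = 2),
             n_lincrnas = 2,
             n_decoys = c(short = 1, orf = 1, low_fpkm = 1, subthreshold = 1),
             n_responsive_up = 4, n_responsive_down = 2,
             n_pairs_concordant = 3, n_pairs_discordant = 2, ...)
}

test_that("the generator is deterministic given the seed", {
  s1 <- simulate_nat_dataset(small_cfg())
  s2 <- simulate_nat_dataset(small_cfg())
  expect_identical(s1$transcripts, s2$transcripts)
  expect_identical(s1$truth, s2$truth)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$expression, s2$expression)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_dataset(s1, d1)
  write_sim_dataset(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("the genome hits the configured GC within sampling error", {
  sim <- simulate_nat_dataset(sim_config(seed = 23))
  seq <- as.character(sim$genome[[1]])
  expect_gt(nchar(seq), 1e4)
  expect_lt(abs(gc_content(seq) - 48), 2)
})

test_that("an empty design still emits a genome and empty annotation", {
  cfg <- sim_config(seed = 1, n_genes = 0, n_nats = c(0, 0, 0),
                    n_lincrnas = 0, n_decoys = c(0, 0, 0, 0),
                    n_responsive_up = 0, n_responsive_down = 0,
                    n_pairs_concordant = 0, n_pairs_discordant = 0)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(nrow(ann$transcripts), 0)
  genome <- simulate_genome(cfg, ann)
  expect_gte(Biostrings::width(genome)[1], 10000)
})

test_that("infeasible designs are rejected at configuration time", {
  expect_error(sim_config(n_genes = 5), "at least")
  expect_error(sim_config(n_responsive_up = 11), "responsive")
  expect_error(sim_config(n_pairs_concordant = 9), "pairs")
  expect_error(sim_config(replicates = 1), "replicates")
})

test_that("planted geometry is sound: overlaps and classes match truth", {
  sim <- simulate_nat_dataset(small_cfg())
  truth_nat <- dplyr::filter(sim$truth, category == "NAT")
  for (i in seq_len(nrow(truth_nat))) {
    nat <- dplyr::filter(sim$transcripts,
                         transcript_id == truth_nat$transcript_id[i])
    gene <- dplyr::filter(sim$genes, gene_id == truth_nat$cognate_gene[i])
    expect_gte(antisense_overlap_nt(nat, gene), 50)
    expect_equal(overlap_class(nat, gene)$overlap_class,
                 truth_nat$overlap_class[i])
  }
  for (id in sim$truth$transcript_id[sim$truth$category == "lincRNA"]) {
    linc <- dplyr::filter(sim$transcripts, transcript_id == id)
    ovs <- purrr::map_dbl(unique(sim$genes$gene_id), function(g) {
      antisense_overlap_nt(linc, dplyr::filter(sim$genes, gene_id == g))
    })
    expect_equal(sum(ovs), 0)
  }
})

test_that("planted coding frames give mRNAs long ORFs and NATs short ones", {
  sim <- simulate_nat_dataset(small_cfg())
  seqs <- spliced_sequence(sim$transcripts, sim$genome)
  orfs <- longest_orf_aa(seqs$sequence)
  cat_of <- sim$truth$category[match(seqs$transcript_id,
                                     sim$truth$transcript_id)]
  expect_true(all(orfs$max_orf_aa[cat_of == "mRNA"] > 100))
  expect_true(all(orfs$max_orf_aa[cat_of == "decoy_orf"] > 100))
  expect_true(all(orfs$max_orf_aa[cat_of %in% c("NAT", "lincRNA")] <= 100))
})

test_that("written datasets read back equal to the in-memory objects", {
  sim <- simulate_nat_dataset(small_cfg())
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  tx <- read_gtf(file.path(dir, "transcripts.gtf"))
  expect_equal(
    dplyr::arrange(tx, transcript_id, start) |>
      dplyr::mutate(start = as.numeric(start), end = as.numeric(end)),
    dplyr::arrange(sim$transcripts, transcript_id, start) |>
      dplyr::mutate(start = as.numeric(start), end = as.numeric(end),
                    gene_id = dplyr::coalesce(gene_id, transcript_id))
  )
  genes <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(gene_spans(genes), gene_spans(sim$genes))
  genome <- read_genome(file.path(dir, "genome.fa"))
  expect_equal(as.character(genome), as.character(sim$genome),
               ignore_attr = TRUE)
  sm <- readr::read_tsv(file.path(dir, "samples.tsv"), comment = "#",
                        show_col_types = FALSE)
  expr <- read_expression_table(file.path(dir, "counts.tsv"), sm)
  expect_equal(
    dplyr::arrange(expr, transcript_id, sample)$value,
    dplyr::arrange(sim$expression, transcript_id, sample)$value
  )
})

test_that("replicate counts concentrate on the planted means in the Poisson limit", {
  cfg <- small_cfg(dispersion = 1e9, replicates = 8)
  sim <- simulate_nat_dataset(cfg)
  nf <- simulate_counts(simulate_annotation(small_cfg(replicates = 8,
                                                      noise_free = TRUE))$truth,
                        small_cfg(replicates = 8, noise_free = TRUE))
  means <- nf$expression |>
    dplyr::group_by(transcript_id, condition) |>
    dplyr::summarise(mu = mean(value), .groups = "drop")
  obs <- sim$expression |>
    dplyr::group_by(transcript_id, condition) |>
    dplyr::summarise(m = mean(value), .groups = "drop") |>
    dplyr::inner_join(means, by = c("transcript_id", "condition")) |>
    dplyr::filter(mu > 10)
  # sample mean within 3 standard errors of the planted mean (Poisson SE)
  dev <- abs(obs$m - obs$mu) / sqrt(obs$mu / 8)
  expect_lt(mean(dev > 3), 0.05)
})

test_that("noise-free counts reproduce the planted response patterns exactly", {
  cfg <- small_cfg(noise_free = TRUE)
  sim <- simulate_nat_dataset(cfg)
  profiles <- condition_profiles(sim$expression, sim$lengths)
  pat <- classify_pi_response(profiles)
  truth_pat <- sim$truth |>
    dplyr::distinct(expr_id, .keep_all = TRUE) |>
    dplyr::select(expr_id, response_pattern)
  joined <- dplyr::inner_join(pat, truth_pat,
                              by = c(transcript_id = "expr_id"))
  expect_equal(joined$pattern, joined$response_pattern)
})
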