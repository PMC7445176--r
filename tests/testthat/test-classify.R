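# A plain-C background contains no ATG and no stop codons, so planted ORFs
# are fully controlled.
flat_genome <- function(n = 20000) {
  Biostrings::DNAStringSet(c(chr1 = paste(rep("C", n), collapse = "")))
}

uniform_profiles <- function(ids, fpkm = 5) {
  make_profiles(setNames(
    lapply(ids, function(i) setNames(rep(fpkm, 5), c("C4", "P4", "P8", "R4", "C8"))),
    ids
  ))
}

test_that("antisense overlap is the exonic per-base intersection", {
  gene <- make_gene("g", list(c(100, 300), c(400, 600)), "+")
  cand <- make_tx("c", list(c(250, 450)), "-")
  expect_equal(antisense_overlap_nt(cand, gene), 100)           # 50 + 50
  expect_equal(antisense_overlap_nt(cand, gene, mode = "span"), 200)
  expect_equal(antisense_overlap_nt(make_tx("c", list(c(250, 450)), "+"),
                                    gene), 0)                   # same strand
  expect_equal(antisense_overlap_nt(make_tx("c", list(c(700, 900)), "-"),
                                    gene), 0)                   # disjoint
  expect_equal(antisense_overlap_nt(make_tx("c", list(c(250, 450)), "-",
                                            chrom = "chr2"), gene), 0)
})

test_that("antisense overlap equals a per-base boolean-array oracle", {
  set.seed(13)
  for (i in 1:150) {
    a <- random_exons(4, 10000)
    b <- random_exons(4, 10000)
    cand <- make_tx("c", purrr::map2(a$start, a$end, c), "-")
    gene <- make_gene("g", purrr::map2(b$start, b$end, c), "+")
    expect_equal(antisense_overlap_nt(cand, gene),
                 oracle_overlap_perbase(a, b))
  }
})

test_that("overlap geometry classifies containment, head-to-head, tail-to-tail", {
  gene <- make_gene("g", list(c(1000, 2000)), "+")
  expect_equal(overlap_class(make_tx("n", list(c(1200, 1800)), "-"),
                             gene)$overlap_class, "FULL")
  hh <- overlap_class(make_tx("n", list(c(800, 1300)), "-"), gene)
  expect_equal(hh$overlap_class, "HEAD_TO_HEAD")
  tt <- overlap_class(make_tx("n", list(c(1700, 2300)), "-"), gene)
  expect_equal(tt$overlap_class, "TAIL_TO_TAIL")
  # gene contained in the NAT collapses into FULL, flagged
  big <- overlap_class(make_tx("n", list(c(900, 2100)), "-"), gene)
  expect_equal(big$overlap_class, "FULL")
  expect_true(big$contains_gene)
  # minus-strand gene: the same genomic geometry flips head/tail
  gene_m <- make_gene("g", list(c(1000, 2000)), "-")
  expect_equal(overlap_class(make_tx("n", list(c(800, 1300)), "+"),
                             gene_m)$overlap_class, "TAIL_TO_TAIL")
  expect_equal(overlap_class(make_tx("n", list(c(1700, 2300)), "+"),
                             gene_m)$overlap_class, "HEAD_TO_HEAD")
  expect_error(overlap_class(make_tx("n", list(c(1200, 1800)), "+"), gene),
               "antisense")
})

test_that("classification and geometry are invariant under coordinate reflection", {
  reflect <- function(df, pivot = 50000) {
    df |> dplyr::mutate(
      tmp = pivot - end, end = pivot - start, start = tmp,
      strand = ifelse(strand == "+", "-", "+")
    ) |> dplyr::select(-tmp) |> dplyr::arrange(start)
  }
  set.seed(29)
  gene <- make_gene("g", list(c(1000, 2000)), "+")
  for (i in 1:40) {
    s <- sample(500:2400, 1)
    nat <- make_tx("n", list(c(s, s + sample(150:900, 1))), "-")
    ov <- antisense_overlap_nt(nat, gene)
    if (ov < 50) next
    cls <- overlap_class(nat, gene)$overlap_class
    cls_r <- overlap_class(reflect(nat), reflect(gene))$overlap_class
    expect_equal(cls_r, cls)
    expect_equal(antisense_overlap_nt(reflect(nat), reflect(gene)), ov)
  }
})

test_that("cognate assignment takes max overlap with deterministic tie-breaks", {
  genes <- dplyr::bind_rows(
    make_gene("geneA", list(c(1000, 2000)), "+"),
    make_gene("geneB", list(c(2500, 3500)), "+")
  )
  nat <- make_tx("n", list(c(1600, 2700)), "-")  # A: 400 nt, B: 200 nt
  call <- assign_cognate_gene(nat, genes)
  expect_equal(call$cognate_gene_id, "geneA")
  expect_equal(call$overlap_nt, 400)

  # equal overlaps: nearer midpoint wins
  genes2 <- dplyr::bind_rows(
    make_gene("geneA", list(c(900, 2000)), "+"),
    make_gene("geneB", list(c(2500, 3500)), "+")
  )
  nat2 <- make_tx("n", list(c(1800, 2700)), "-")  # 200 nt each
  call2 <- assign_cognate_gene(nat2, genes2)
  mid <- (1800 + 2700) / 2
  nearer <- if (abs((900 + 2000) / 2 - mid) < abs((2500 + 3500) / 2 - mid))
    "geneA" else "geneB"
  expect_equal(call2$cognate_gene_id, nearer)

  # perfect tie: lexicographically smaller id
  genes3 <- dplyr::bind_rows(
    make_gene("geneB", list(c(1000, 2000)), "+"),
    make_gene("geneA", list(c(3000, 4000)), "+")
  )
  nat3 <- make_tx("n", list(c(1900, 3100)), "-")  # 100 nt each, symmetric
  expect_equal(assign_cognate_gene(nat3, genes3)$cognate_gene_id, "geneA")

  expect_error(assign_cognate_gene(make_tx("n", list(c(9000, 9100)), "-"),
                                   genes), "precondition")
})

test_that("the candidate decision sequence applies gates in the published order", {
  genome <- flat_genome()
  gene <- make_gene("g1", list(c(1000, 2000)), "+")
  profiles <- uniform_profiles(c("short", "nat", "linc", "sense", "sub",
                                 "orf_cand"))

  cands <- dplyr::bind_rows(
    make_tx("short", list(c(1100, 1250)), "-"),          # 150 nt, overlaps
    make_tx("nat", list(c(1200, 1500)), "-"),            # all gates pass
    make_tx("linc", list(c(5000, 5300)), "-"),           # no gene anywhere
    make_tx("sense", list(c(1200, 1500)), "+"),          # sense overlap
    make_tx("sub", list(c(730, 1030)), "-"),             # 300 nt, 30 nt overlap
    make_tx("annot", list(c(1000, 2000)), "+",
            gene_id = "g1", source_class = "annotated_coding")
  )
  cls <- classify_candidates(cands, gene, profiles, genome)
  got <- setNames(cls$label, cls$transcript_id)
  expect_equal(got[["short"]], "REJECT_SHORT")
  expect_equal(got[["nat"]], "NAT")
  expect_equal(got[["linc"]], "LINCRNA")
  expect_equal(got[["sense"]], "REJECT_SENSE_OVERLAP")
  expect_equal(got[["sub"]], "REJECT_SUBTHRESHOLD_OVERLAP")
  expect_equal(got[["annot"]], "REJECT_ANNOTATED")
  expect_equal(cls$cognate_gene[cls$transcript_id == "nat"], "g1")
  expect_equal(cls$overlap_class[cls$transcript_id == "nat"], "FULL")

  # every candidate gets exactly one label: the labels partition the set
  expect_equal(sum(table(cls$label)), nrow(cands))
})

test_that("coding potential and abundance gates reject candidates", {
  # plant a 120 aa frame inside an otherwise ORF-free background
  orf <- paste0("ATG", paste(rep("GCT", 119), collapse = ""), "TAA")
  chrom <- paste0(paste(rep("C", 5000), collapse = ""), orf,
                  paste(rep("C", 5000), collapse = ""))
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  gene <- make_gene("g1", list(c(100, 900)), "+")
  cands <- dplyr::bind_rows(
    make_tx("orfy", list(c(4990, 5400)), "+"),   # carries the planted ORF
    make_tx("faint", list(c(200, 500)), "-")     # NAT-like but FPKMmax 0.5
  )
  profiles <- make_profiles(list(
    orfy = setNames(rep(5, 5), c("C4", "P4", "P8", "R4", "C8")),
    faint = setNames(rep(0.5, 5), c("C4", "P4", "P8", "R4", "C8"))
  ))
  cls <- classify_candidates(cands, gene, profiles, genome)
  expect_equal(cls$label[cls$transcript_id == "orfy"], "REJECT_ORF")
  expect_gt(cls$orf_aa[cls$transcript_id == "orfy"], 100)
  expect_equal(cls$label[cls$transcript_id == "faint"], "REJECT_LOW_FPKM")

  # a transcript missing from the expression table is expressionless
  cands2 <- make_tx("ghost", list(c(200, 500)), "-")
  cls2 <- classify_candidates(cands2, gene, uniform_profiles("other"), genome)
  expect_equal(cls2$label, "REJECT_LOW_FPKM")
})

test_that("genome NAT coverage is the percent of genes with a qualifying NAT", {
  genes <- dplyr::bind_rows(
    make_gene("g1", list(c(0, 1000))), make_gene("g2", list(c(2000, 3000))),
    make_gene("g3", list(c(4000, 5000))), make_gene("g4", list(c(6000, 7000)))
  )
  ov <- tibble::tibble(transcript_id = c("n1", "n2", "n3"),
                       gene_id = c("g1", "g2", "g2"),
                       overlap_nt = c(120, 500, 49))
  expect_equal(genome_nat_coverage(ov, genes), 50)
  expect_equal(genome_nat_coverage(ov[0, ], genes), 0)
  expect_equal(genome_nat_coverage(
    tibble::tibble(transcript_id = paste0("n", 1:4),
                   gene_id = paste0("g", 1:4), overlap_nt = 60),
    genes), 100)
  expect_error(genome_nat_coverage(ov, genes[0, ]), "empty")
})
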