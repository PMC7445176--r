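Package: natpairs
Title: Identification of Long Noncoding Natural Antisense Transcripts and
    Sense-Antisense Expression Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A strand-aware pipeline for genome-wide identification of long
    noncoding natural antisense transcripts (NATs) from assembled
    strand-specific transcriptomes.  Filters assembled transcripts by length,
    coding potential (longest open reading frame) and abundance (FPKM),
    classifies antisense overlap geometry with annotated protein-coding genes
    (fully overlapped, head-to-head, tail-to-tail), calls differential
    expression across a five-state phosphate-fluctuation design with fold
    change and Fisher's exact test, labels phosphate-responsive expression
    patterns, and detects concordant and discordant NAT-mRNA sense-antisense
    pairs by Pearson correlation.  Includes a seeded synthetic-transcriptome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
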