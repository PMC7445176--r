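---
title: "Identifying natural antisense transcripts and phosphate-responsive NAT-mRNA pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying natural antisense transcripts and phosphate-responsive NAT-mRNA pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natpairs)
library(dplyr)
```

## The problem

Strand-specific RNA-seq makes it possible to see transcription from *both*
strands of a locus. A long noncoding **natural antisense transcript (NAT)**
is a transcript on the strand opposite an annotated protein-coding gene,
overlapping it by at least a minimum number of bases; a **lincRNA** is a
long noncoding transcript overlapping no gene at all. In nutrient-stressed
phytoplankton such as diatoms, NATs respond sharply to phosphate (Pi)
availability, and a NAT's expression is often coupled — positively or
negatively — to its overlapping ("cognate") mRNA.

`natpairs` implements the full desk side of that analysis as a reusable,
tested pipeline. It consumes an assembled transcriptome (GTF), a
protein-coding annotation (GFF3 or GTF), a genome (FASTA) and per-sample
fragment counts or FPKM over five physiological states:

| tag | state |
|-----|-------|
| C4  | control, day 4 |
| P4  | Pi-depleted, day 4 |
| P8  | Pi-depleted, day 8 |
| R4  | Pi resupplied for 4 days after 4 days of depletion |
| C8  | control, day 8 |

## The classification procedure

Candidates are assembled transcripts not annotated as protein coding. Each
candidate passes through a fixed decision sequence
(`classify_candidates()`), every gate inclusive exactly as published:

1. annotated coding transcript → `REJECT_ANNOTATED`;
2. any sense-strand exonic overlap with a gene → `REJECT_SENSE_OVERLAP`;
3. spliced length < 200 nt → `REJECT_SHORT` (exactly 200 passes);
4. longest predicted ORF > 100 aa → `REJECT_ORF` (exactly 100 passes);
5. maximum FPKM over all samples < 1 → `REJECT_LOW_FPKM` (exactly 1 passes);
6. best antisense overlap ≥ 50 nt → `NAT` (exactly 50 passes);
7. no antisense overlap at all → `LINCRNA`;
8. otherwise (overlap in 1–49 nt) → `REJECT_SUBTHRESHOLD_OVERLAP`.

The labels partition the candidate set, so the per-gate tallies in the run
manifest always sum to the input count.

**Coding potential.** The ORF filter uses a deterministic longest-ORF
scanner (`longest_orf_aa()`): all three frames of the spliced sense strand
are searched for ATG…stop spans and the longest is reported in amino acids,
stop codon excluded. Only the sense strand is scanned — transcript
orientation is known from strand-specific data, and an antisense ORF
belongs to the transcript on the other strand. Codons containing `N` never
match ATG or a stop. A `require_stop = FALSE` mode counts open-ended ORFs
to the sequence end for sensitivity analysis. This is intentionally an
upper bound on coding potential, not a trained gene model: the published
criterion is a hard 100 aa rule, which a scanner applies exactly and
reproducibly.

**Overlap arithmetic.** Coordinates are 0-based half-open internally, so an
overlap is `max(0, min(end) - max(start))` with no ±1 corrections;
GTF/GFF3 I/O converts at the boundary and round-trips exactly. Overlap
*length* is exonic by default (candidate exons × gene exons), with a
`span` mode that intersects against the gene-body hull instead; physical
sense-antisense pairing happens between mature transcripts, so the exonic
reading is the stricter default and both are exposed.

**Overlap geometry** (`overlap_class()`) is a span property, because
head/tail vocabulary concerns transcript *ends*:

- NAT span inside the gene span → `FULL`;
- gene span inside the NAT span → also `FULL`, flagged `contains_gene`
  (the rarer containment direction is collapsed rather than given a
  fourth class, and stays countable through the flag);
- otherwise the overlap region holds exactly one terminus of each
  transcript: both 5′ termini → `HEAD_TO_HEAD` (divergent), both 3′
  termini → `TAIL_TO_TAIL` (convergent). Any other configuration is
  geometrically impossible for an antisense pair on a line and raises an
  assertion, which has caught real coordinate bugs in development.

When several genes qualify, the cognate is the gene with the largest
antisense overlap; ties break to the smaller span-midpoint distance, then
the lexicographically smallest `gene_id` — arbitrary but deterministic, so
reruns are identical.

## Expression statistics

**FPKM.** `fpkm(count, library_total, exonic_length) = count × 10⁹ /
(library_total × exonic_length)`.

**Replicate handling.** Within each condition the two most mutually
consistent replicates (highest Pearson correlation across transcripts) are
pooled — counts summed, totals summed — before any testing
(`select_robust_replicates()`). Pooling trades replicate-level variance
estimation for depth, which is what low-abundance noncoding transcripts
need; a warning fires when even the best pair correlates below 0.9.

**Differential expression.** A contrast is called `UP` when fold change ≥ 2
and p < 0.05, `DOWN` when fold change ≤ 0.5 and p < 0.05, else
`UNCHANGED`. The p-value is a two-sided Fisher exact test on the 2×2 table
`[[c₁, N₁−c₁], [c₂, N₂−c₂]]` (pooled fragment count against the library
remainder), computed by direct hypergeometric enumeration with the
point-probability rule: the p-value sums all tables with fixed margins
whose probability does not exceed the observed table's. The test suite
checks this against independent `choose()`-based enumeration exhaustively
for all margins up to 30, and against `stats::fisher.test` on random
tables. With FPKM-only input and no library totals the p gate is disabled
with a loud warning and calls reduce to fold change alone. No
multiple-testing correction is applied by default (an optional
Benjamini–Hochberg flag exists): the published procedure gates on raw
p-values, and matching it is the point.

**Fold-change pseudocount.** 0.1 FPKM is added to both terms, but only
when either term falls below 0.1. This leaves ordinary ratios untouched
while bounding the fold change of transcripts at the detection floor
(which the FPKMmax ≥ 1 filter keeps rare). Both terms zero with a zero
pseudocount is an error, not an `Inf`.

**Pi-response patterns** (`classify_pi_response()`). A transcript is
`UP_PI_RESPONSIVE` when it is UP under depletion (P4 vs C4 *or* P8 vs C8)
*and* reverts on resupply — DOWN in R4 vs P4, *or* "back to control",
operationalised as UNCHANGED in R4 vs C4. The OR accepts both published
readings of "return to control levels", and both underlying statuses are
kept in the output so either reading can be audited.
`DOWN_PI_RESPONSIVE` mirrors this. A depletion arm that fires without the
resupply criterion gives `UP_/DOWN_DEPLETION_ONLY`. In the contrived case
where one depletion time point is UP and the other DOWN, the up arm is
evaluated first; the four statuses in the output disambiguate.

**NAT–mRNA pairs** (`detect_nat_pairs()`). For each Pi-responsive NAT, the
Pearson correlation between its five pooled per-condition FPKM values and
its cognate mRNA's is computed on raw FPKM (a `log2(FPKM+1)` mode exists).
Pairs with r² ≥ 0.6 (inclusive) are kept; r > 0 is `CONCORDANT`, r < 0
`DISCORDANT`. Five points is few for a correlation — that is a property of
the five-state design, not a free choice — which is why the r² threshold
is high and the responsiveness prefilter comes first. Constant profiles
make r undefined; such pairs are skipped with a logged message rather than
guessed.

## The synthetic-data generator

`simulate_nat_dataset()` emulates the study design so every stage has a
planted right answer: 20 protein-coding genes on one chromosome; ten NATs
(4 fully overlapped, 3 head-to-head, 3 tail-to-tail) drawn opposite their
designated genes with class-correct geometry and ≥ 50 nt overlap; five
lincRNAs clear of all genes; eight decoys that each violate exactly one
filter (150 nt length; a planted 120 aa ORF; FPKMmax 0.5; 30 nt overlap);
all ten NATs Pi-responsive (7 up, 3 down); six concordant and three
discordant pairs whose cognate mRNAs follow or oppose the NAT's pattern.
Counts are negative-binomial (dispersion 10) around planted means at one
million mapped fragments per sample, two replicates per condition;
baseline means are log-uniform between 200 and 2000 fragments; planted
effects are fourfold at P4 and P8 with exact return to baseline at R4.
A `noise_free` mode emits the rounded means themselves, giving sharp
expectations (correlations of exactly ±1, fold changes of exactly 4).

Design choices worth stating:

- **Noncoding feature lengths are drawn between 220 and 300 nt** (decoys
  excepted). A sequence shorter than 306 nt cannot contain a 100 aa ORF,
  so the coding-potential of every planted noncoding transcript is decided
  by construction and ground-truth recovery is exact for *every* seed — in
  a random-background genome, a 700 nt transcript has a non-trivial chance
  of a spurious long ORF, which would make the generator's own truth table
  wrong. Biologically this sits at the short end of the NAT length
  spectrum; NATs are the shortest transcript class in this system.
- Coding frames (gene CDS of 110–140 aa, and the ORF decoys' 120 aa
  frames) are written explicitly into the genome, strand-aware, inside the
  host exon; the rest of the genome is i.i.d. at 48% GC, the genomic GC
  of the organism modelled.
- Baselines are drawn before any count noise, so noise-free and noisy runs
  of one config share identical planted means, and every emitted file is
  byte-identical for a fixed seed.
- A `multi_exon` flag plants a two-exon structure (60 nt intron) on each
  gene, positioned clear of every planted overlap window, to exercise the
  exonic-overlap path; planted NATs stay single-exon.

What the generator does **not** emulate: read-level artefacts (it plants
counts, not reads), positional coverage bias, transcript-assembly errors,
overdispersion heterogeneity across transcripts, overlapping gene models,
and trans-acting correlation structure. Passing tests therefore show the
*logic* of classification, testing and pairing is right under the stated
noise model — not that any particular biological dataset will be called
perfectly.

## Validation strategy and problem sizes

The test suite validates each primitive against an independent oracle:
interval overlap against per-base boolean arrays (1000 random instances),
the exact test against full hypergeometric enumeration (all margins ≤ 30;
245,025 tables), the ORF scanner against brute-force ATG enumeration
(1000 random sequences ≤ 300 nt), the U test against rank-sum enumeration
(n ≤ 8 per group). End-to-end, the noise-free design must be recovered
*exactly* on every axis, and ten noisy replicates must average ≥ 90%
response-pattern recall and pair-concordance accuracy. Gate boundaries
(200 nt, 100 aa, 50 nt, FPKM 1, fold 2, the r² threshold) are probed one
unit either side. These sizes keep the whole suite under a few minutes on
one core while leaving each check statistically meaningful.

## Known limitations

- Fisher's exact test on pooled counts ignores biological replicate
  variance; it answers "is this shift larger than counting noise", not
  "larger than replicate variance". Replicate-aware negative-binomial
  testing is deliberately out of scope — the pipeline reproduces a
  specific published procedure.
- With FPKM-only input the p gate disappears entirely (warned loudly).
- Correlation over five pooled points cannot distinguish pattern shapes
  beyond sign and strength; a replicate-level correlation mode exists but
  the pooled five-point mode is the default and the published reading.
- One cognate gene per NAT: secondary overlaps are reported in the overlap
  table but not classified or paired.
- Intronic lncRNAs and trans-NATs are out of scope.

## A worked run

```{r example}
sim <- simulate_nat_dataset(sim_config(seed = 5, noise_free = TRUE))
an <- nat_analysis(sim$transcripts, sim$genes, sim$genome, sim$expression)
an
glance(an)
tidy(an)
```

```{r plots, fig.width = 7, fig.height = 4}
plot_category_distributions(an)
plot_response_heatmap(an)
```
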