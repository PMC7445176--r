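#' Filtering and calling thresholds for NAT identification
#'
#' Bundles every cutoff used along the pipeline in one validated record.
#' Defaults are the published criteria for this class of analysis: candidate
#' lncRNAs must be at least 200 nt long with a predicted ORF of at most
#' 100 amino acids and at least 50 nt of antisense overlap with an annotated
#' gene model; low-abundance transcripts (maximum FPKM below 1) are excluded;
#' differential expression requires a twofold change at Fisher-exact
#' p < 0.05; sense-antisense pairs require a squared Pearson correlation of
#' at least 0.6.
#'
#' @param min_length_nt Minimum spliced transcript length in nucleotides
#'   (inclusive gate: exactly 200 passes).
#' @param max_orf_aa Maximum predicted ORF length in amino acids, stop codon
#'   excluded (inclusive: exactly 100 passes).
#' @param min_overlap_nt Minimum antisense overlap with a gene model in
#'   nucleotides (inclusive: exactly 50 passes).
#' @param min_fpkm_max Abundance floor: transcripts are dropped only when
#'   their maximum FPKM over all samples is strictly below this value.
#' @param de_fold Fold-change cutoff for differential expression (UP when
#'   fold change >= `de_fold`, DOWN when <= `1/de_fold`).
#' @param de_p P-value cutoff for the Fisher exact test (strict: p < `de_p`).
#' @param pair_r2 Minimum squared Pearson correlation for a NAT-mRNA pair
#'   (inclusive: exactly 0.6 passes).
#' @param fc_pseudocount Pseudocount (FPKM units) added to both terms of a
#'   fold change when either term falls below it; guards against division by
#'   zero at the detection floor.
#'
#' @return An object of class `nat_thresholds` (a named list).
#' @examples
#' nat_thresholds()
#' nat_thresholds(min_overlap_nt = 100)
#' @export
nat_thresholds <- function(min_length_nt = 200, max_orf_aa = 100,
                           min_overlap_nt = 50, min_fpkm_max = 1,
                           de_fold = 2, de_p = 0.05, pair_r2 = 0.6,
                           fc_pseudocount = 0.1) {
  th <- list(
    min_length_nt = min_length_nt, max_orf_aa = max_orf_aa,
    min_overlap_nt = min_overlap_nt, min_fpkm_max = min_fpkm_max,
    de_fold = de_fold, de_p = de_p, pair_r2 = pair_r2,
    fc_pseudocount = fc_pseudocount
  )
  bad <- names(th)[!vapply(th, function(x) is.numeric(x) && length(x) == 1 &&
                             is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("thresholds must be single positive numbers; offending: ",
                 paste(bad, collapse = ", ")))
  }
  if (th$de_fold <= 1) abort("`de_fold` must exceed 1")
  if (th$de_p >= 1) abort("`de_p` must lie in (0, 1)")
  if (th$pair_r2 > 1) abort("`pair_r2` must lie in (0, 1]")
  structure(th, class = "nat_thresholds")
}

#' @export
print.nat_thresholds <- function(x, ...) {
  cat("<nat_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %g\n", nm, x[[nm]]))
  invisible(x)
}

as_nat_thresholds <- function(th) {
  if (inherits(th, "nat_thresholds")) return(th)
  if (is.list(th)) return(do.call(nat_thresholds, th))
  abort("`thresholds` must be a nat_thresholds object or a named list")
}
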