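# Expression-side statistics: FPKM, replicate handling and pooling, Fisher
# exact differential expression, phosphate-responsiveness patterns, and
# NAT-mRNA pair detection by Pearson correlation.

#' Fragments per kilobase of exon per million mapped fragments
#'
#' @param count Fragment count(s), non-negative.
#' @param library_total Total mapped fragments in the library, positive.
#' @param exonic_length Spliced (exonic) transcript length in nucleotides,
#'   positive.
#' @return `count * 1e9 / (library_total * exonic_length)`, vectorised.
#' @examples
#' fpkm(100, 1e6, 1000)  # 100
#' @export
fpkm <- function(count, library_total, exonic_length) {
  if (any(library_total <= 0)) abort("validation error: library_total must be positive")
  if (any(exonic_length <= 0)) abort("validation error: exonic_length must be positive")
  if (any(count < 0)) abort("validation error: negative count")
  count * 1e9 / (library_total * exonic_length)
}

#' Choose and pool the two most mutually consistent replicates
#'
#' Computes all pairwise Pearson correlations (across transcripts) between
#' the replicate columns of one condition and pools the best pair: counts
#' are summed (with their library totals), FPKM values averaged.  Pooling
#' ahead of testing increases effective depth for low-abundance noncoding
#' transcripts.  A warning is raised when even the best pair correlates
#' below 0.9, the conventional reproducibility bar.
#'
#' @param expression Long expression tibble ([read_expression_table()]).
#' @param condition Condition tag (one of C4, P4, P8, R4, C8).
#' @return A list: `samples` (the chosen pair), `correlation`, and `pooled`
#'   (tibble `transcript_id`, `value`, `library_total`).
#' @export
select_robust_replicates <- function(expression, condition) {
  cond <- expression |> filter(.data$condition == !!condition)
  if (nrow(cond) == 0) {
    abort(paste0("validation error: no samples for condition ", condition))
  }
  wide <- cond |>
    select("transcript_id", "sample", "value") |>
    pivot_wider(names_from = "sample", values_from = "value")
  samples <- setdiff(names(wide), "transcript_id")
  if (length(samples) < 2) {
    abort(paste0("validation error: condition ", condition,
                 " has fewer than 2 replicates"))
  }
  mat <- as.matrix(wide[samples])
  pairs <- utils::combn(samples, 2, simplify = FALSE)
  cors <- map_dbl(pairs, function(p) {
    suppressWarnings(cor(mat[, p[1]], mat[, p[2]]))
  })
  cors[is.na(cors)] <- -Inf  # degenerate constant columns sort last
  best <- order(-cors, map_chr(pairs, 1), map_chr(pairs, 2))[1]
  chosen <- pairs[[best]]
  if (is.finite(cors[best]) && cors[best] < 0.9) {
    warn(sprintf("condition %s: best replicate pair correlates at %.3f (< 0.9)",
                 condition, cors[best]))
  }
  totals <- cond |> distinct(.data$sample, .data$library_total)
  vtype <- cond$value_type[1]
  pooled <- wide |>
    transmute(
      .data$transcript_id,
      value = if (vtype == "count") {
        .data[[chosen[1]]] + .data[[chosen[2]]]
      } else {
        (.data[[chosen[1]]] + .data[[chosen[2]]]) / 2
      },
      library_total = if (vtype == "count") {
        sum(totals$library_total[totals$sample %in% chosen])
      } else {
        NA_real_
      }
    )
  list(samples = chosen, correlation = cors[best], pooled = pooled)
}

#' Pooled per-condition expression profiles
#'
#' Applies [select_robust_replicates()] to every condition and derives FPKM
#' from pooled counts, spliced lengths and pooled library totals (or
#' averages supplied FPKM values directly).
#'
#' @param expression Long expression tibble ([read_expression_table()]).
#' @param lengths Tibble `transcript_id`, `length_nt`; required when the
#'   table carries counts.
#' @return Tibble: `transcript_id`, `condition`, `count` (NA in FPKM mode),
#'   `library_total`, `fpkm`.
#' @export
condition_profiles <- function(expression, lengths = NULL) {
  vtype <- expression$value_type[1]
  conds <- intersect(PI_CONDITIONS, unique(expression$condition))
  pooled <- map(conds, function(cond) {
    select_robust_replicates(expression, cond)$pooled |>
      mutate(condition = cond)
  }) |> list_rbind()
  if (vtype == "count") {
    if (is.null(lengths)) {
      abort("count-based profiles require spliced `lengths`")
    }
    pooled <- pooled |>
      left_join(lengths |> select("transcript_id", "length_nt"),
                by = "transcript_id")
    if (anyNA(pooled$length_nt)) {
      bad <- pooled$transcript_id[is.na(pooled$length_nt)][1]
      abort(paste0("no spliced length for expression row ", bad))
    }
    pooled |>
      transmute(.data$transcript_id, .data$condition,
                count = .data$value, .data$library_total,
                fpkm = fpkm(.data$value, .data$library_total, .data$length_nt))
  } else {
    pooled |>
      transmute(.data$transcript_id, .data$condition,
                count = NA_real_, library_total = NA_real_,
                fpkm = .data$value)
  }
}

#' Two-sided Fisher exact test for a count contrast
#'
#' Exact two-sided p-value for the 2x2 table `[[c1, n1 - c1], [c2, n2 - c2]]`
#' (fragment count versus library remainder in each sample), computed by
#' direct enumeration of the hypergeometric distribution with fixed
#' margins: the p-value sums the probabilities of all tables whose point
#' probability does not exceed that of the observed table.
#'
#' @param c1,c2 Fragment counts in samples 1 and 2.
#' @param n1,n2 Library totals (counts must not exceed them).
#' @return P-value(s) in `(0, 1]`, vectorised over the inputs.
#' @export
fisher_de <- function(c1, n1, c2, n2) {
  args <- vctrs_recycle(c1, n1, c2, n2)
  with(args, {
    if (any(c1 < 0 | c2 < 0 | c1 > n1 | c2 > n2)) {
      abort("validation error: counts must satisfy 0 <= c <= n")
    }
    pmap_dbl(list(c1, n1, c2, n2), fisher_one)
  })
}

fisher_one <- function(c1, n1, c2, n2) {
  t <- c1 + c2
  k <- max(0, t - n2):min(n1, t)
  probs <- dhyper(k, n1, n2, t)
  p_obs <- probs[k == c1]
  # 1 + 1e-7 relative tolerance guards against ties lost to floating point,
  # matching the convention of standard exact-test implementations.
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

vctrs_recycle <- function(c1, n1, c2, n2) {
  n <- max(length(c1), length(n1), length(c2), length(n2))
  list(c1 = rep_len(c1, n), n1 = rep_len(n1, n),
       c2 = rep_len(c2, n), n2 = rep_len(n2, n))
}

#' Fold change between two expression values
#'
#' Plain ratio `alt / ref`; when either term falls below the pseudocount,
#' the pseudocount is added to both terms, which bounds fold changes at the
#' detection floor instead of letting zeros produce infinities.
#'
#' @param fpkm_ref,fpkm_alt Non-negative expression values (reference and
#'   alternative condition).
#' @param pseudocount Pseudocount in FPKM units; 0 is allowed only when both
#'   terms are positive.
#' @return Positive fold change(s), vectorised.
#' @export
fold_change <- function(fpkm_ref, fpkm_alt, pseudocount = 0.1) {
  if (any(fpkm_ref < 0 | fpkm_alt < 0)) abort("negative expression value")
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  if (pseudocount == 0 && any(fpkm_ref == 0 & fpkm_alt == 0)) {
    abort("undefined fold change: both values zero with zero pseudocount")
  }
  needs <- fpkm_ref < pseudocount | fpkm_alt < pseudocount
  if_else(needs,
          (fpkm_alt + pseudocount) / (fpkm_ref + pseudocount),
          fpkm_alt / fpkm_ref)
}

#' Differential-expression calls for one condition contrast
#'
#' Status is `UP` when fold change (alt over ref) is at least `de_fold` and
#' p < `de_p`, `DOWN` when fold change is at most `1/de_fold` and
#' p < `de_p`, otherwise `UNCHANGED`.  The p-value comes from [fisher_de()]
#' on pooled counts; with FPKM-only input (no counts, no totals) the p gate
#' is disabled with a warning and the call reduces to fold change alone.
#'
#' @param profiles Pooled profiles ([condition_profiles()]).
#' @param contrast Character pair `c(ref, alt)` of condition tags.
#' @param thresholds A [nat_thresholds()] object.
#' @return Tibble: `transcript_id`, `ref`, `alt`, `fold_change`, `p_value`
#'   (NA when the gate is disabled), `status`.
#' @export
call_de <- function(profiles, contrast, thresholds = nat_thresholds()) {
  thresholds <- as_nat_thresholds(thresholds)
  stopifnot(length(contrast) == 2)
  ref <- profiles |> filter(.data$condition == contrast[1])
  alt <- profiles |> filter(.data$condition == contrast[2])
  if (nrow(ref) == 0 || nrow(alt) == 0) {
    abort(paste0("validation error: missing condition in contrast ",
                 contrast[1], " vs ", contrast[2]))
  }
  de <- inner_join(
    ref |> select("transcript_id", ref_count = "count",
                  ref_total = "library_total", ref_fpkm = "fpkm"),
    alt |> select("transcript_id", alt_count = "count",
                  alt_total = "library_total", alt_fpkm = "fpkm"),
    by = "transcript_id"
  ) |>
    mutate(fold_change = fold_change(.data$ref_fpkm, .data$alt_fpkm,
                                     thresholds$fc_pseudocount))
  if (all(is.na(de$ref_count))) {
    warn(paste0("no counts or library totals available: Fisher p gate ",
                "disabled, DE calls use fold change only"))
    de$p_value <- NA_real_
    p_pass <- TRUE
  } else {
    de$p_value <- fisher_de(de$ref_count, de$ref_total,
                            de$alt_count, de$alt_total)
    p_pass <- de$p_value < thresholds$de_p
  }
  de |>
    mutate(
      status = case_when(
        .data$fold_change >= thresholds$de_fold & p_pass ~ "UP",
        .data$fold_change <= 1 / thresholds$de_fold & p_pass ~ "DOWN",
        TRUE ~ "UNCHANGED"
      ),
      ref = contrast[1], alt = contrast[2]
    ) |>
    select("transcript_id", "ref", "alt", "fold_change", "p_value", "status")
}

#' Phosphate-responsiveness pattern of each transcript
#'
#' A transcript is `UP_PI_RESPONSIVE` when it is up-regulated under Pi
#' depletion (UP in P4 vs C4 or in P8 vs C8) and reverts on resupply
#' (DOWN in R4 vs P4, or back to control: UNCHANGED in R4 vs C4);
#' `DOWN_PI_RESPONSIVE` is the mirrored pattern.  When the depletion arm
#' fires but the resupply criterion fails the transcript is
#' `UP_DEPLETION_ONLY` / `DOWN_DEPLETION_ONLY`; otherwise `NONE`.  Should a
#' transcript fire both depletion arms (UP at one depletion time point,
#' DOWN at the other), the up arm takes precedence.
#'
#' @param profiles Pooled profiles ([condition_profiles()]) containing all
#'   five conditions.
#' @param thresholds A [nat_thresholds()] object.
#' @param bh Apply Benjamini-Hochberg correction to each contrast's
#'   p-values before gating (off by default).
#' @return Tibble: `transcript_id`, `pattern`, plus the four underlying
#'   statuses (`status_p4_c4`, `status_p8_c8`, `status_r4_c4`,
#'   `status_r4_p4`).
#' @export
classify_pi_response <- function(profiles, thresholds = nat_thresholds(),
                                 bh = FALSE) {
  thresholds <- as_nat_thresholds(thresholds)
  have <- unique(profiles$condition)
  missing <- setdiff(PI_CONDITIONS, have)
  if (length(missing) > 0) {
    abort(paste0("validation error: missing condition(s): ",
                 paste(missing, collapse = ", ")))
  }
  contrasts <- list(p4_c4 = c("C4", "P4"), p8_c8 = c("C8", "P8"),
                    r4_c4 = c("C4", "R4"), r4_p4 = c("P4", "R4"))
  de <- imap(contrasts, function(ct, nm) {
    d <- call_de(profiles, ct, thresholds)
    if (bh && !all(is.na(d$p_value))) {
      d$p_value <- p.adjust(d$p_value, method = "BH")
      p_pass <- d$p_value < thresholds$de_p
      d$status <- case_when(
        d$fold_change >= thresholds$de_fold & p_pass ~ "UP",
        d$fold_change <= 1 / thresholds$de_fold & p_pass ~ "DOWN",
        TRUE ~ "UNCHANGED"
      )
    }
    d |> select("transcript_id", !!paste0("status_", nm) := "status")
  })
  wide <- purrr::reduce(de, left_join, by = "transcript_id")
  wide |>
    mutate(
      up_dep = .data$status_p4_c4 == "UP" | .data$status_p8_c8 == "UP",
      down_dep = .data$status_p4_c4 == "DOWN" | .data$status_p8_c8 == "DOWN",
      up_resupply = .data$status_r4_p4 == "DOWN" | .data$status_r4_c4 == "UNCHANGED",
      down_resupply = .data$status_r4_p4 == "UP" | .data$status_r4_c4 == "UNCHANGED",
      pattern = case_when(
        .data$up_dep & .data$up_resupply ~ "UP_PI_RESPONSIVE",
        .data$up_dep ~ "UP_DEPLETION_ONLY",
        .data$down_dep & .data$down_resupply ~ "DOWN_PI_RESPONSIVE",
        .data$down_dep ~ "DOWN_DEPLETION_ONLY",
        TRUE ~ "NONE"
      )
    ) |>
    select("transcript_id", "pattern", "status_p4_c4", "status_p8_c8",
           "status_r4_c4", "status_r4_p4")
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over [stats::cor()]: series must have equal
#' length of at least 3 and neither may be constant.
#'
#' @param x,y Numeric series.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("series lengths differ")
  if (length(x) < 3) abort("validation error: need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: constant series")
  }
  cor(x, y)
}

#' Detect concordant and discordant NAT-mRNA pairs
#'
#' For every Pi-responsive NAT (pattern other than `NONE`), correlates its
#' five pooled per-condition FPKM values with those of its cognate mRNA
#' (looked up by gene id).  Pairs with squared correlation at or above the
#' threshold are kept; positive correlation is `CONCORDANT`, negative
#' `DISCORDANT`.  Pairs whose members have constant profiles are skipped
#' with a message (correlation undefined).
#'
#' @param nat_calls Classification rows labelled NAT (must carry
#'   `cognate_gene` and `overlap_class`), e.g. filtered from
#'   [classify_candidates()] output; a `transcript_id` or `nat_id` column
#'   identifies the NAT.
#' @param profiles Pooled profiles ([condition_profiles()]) covering NATs
#'   and their cognate genes.
#' @param responses Output of [classify_pi_response()].
#' @param thresholds A [nat_thresholds()] object.
#' @param log_fpkm Correlate `log2(FPKM + 1)` instead of raw FPKM.
#' @return Tibble: `nat_id`, `gene_id`, `overlap_class`, `r`, `r2`,
#'   `concordance`.
#' @export
detect_nat_pairs <- function(nat_calls, profiles, responses,
                             thresholds = nat_thresholds(),
                             log_fpkm = FALSE) {
  thresholds <- as_nat_thresholds(thresholds)
  id_col <- if ("nat_id" %in% names(nat_calls)) "nat_id" else "transcript_id"
  nats <- nat_calls |>
    rename(nat_id = all_of(id_col)) |>
    filter(is.na(.data$label) | .data$label == "NAT") |>
    select("nat_id", gene_id = "cognate_gene", "overlap_class") |>
    inner_join(responses |> filter(.data$pattern != "NONE") |>
                 select(nat_id = "transcript_id"),
               by = "nat_id")
  if (nrow(nats) == 0) {
    return(tibble(nat_id = character(), gene_id = character(),
                  overlap_class = character(), r = numeric(),
                  r2 = numeric(), concordance = character()))
  }
  fpkm_series <- function(id) {
    p <- profiles |> filter(.data$transcript_id == id)
    v <- p$fpkm[match(PI_CONDITIONS, p$condition)]
    if (anyNA(v)) abort(paste0("incomplete condition profile for ", id))
    if (log_fpkm) log2(v + 1) else v
  }
  res <- pmap(nats, function(nat_id, gene_id, overlap_class) {
    x <- fpkm_series(nat_id)
    y <- fpkm_series(gene_id)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      inform(paste0("skipping pair ", nat_id, " / ", gene_id,
                    ": constant expression profile"))
      return(NULL)
    }
    r <- cor(x, y)
    tibble(nat_id, gene_id, overlap_class, r = r, r2 = r^2)
  }) |> list_rbind()
  if (nrow(res) == 0) {
    return(tibble(nat_id = character(), gene_id = character(),
                  overlap_class = character(), r = numeric(),
                  r2 = numeric(), concordance = character()))
  }
  res |>
    filter(.data$r2 >= thresholds$pair_r2) |>
    mutate(concordance = if_else(.data$r > 0, "CONCORDANT", "DISCORDANT"))
}
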