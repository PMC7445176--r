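PI <- c("C4", "P4", "P8", "R4", "C8")

test_that("fpkm follows the count * 1e9 / (total * length) formula", {
  expect_equal(fpkm(100, 1e6, 1000), 100)
  expect_equal(fpkm(0, 1e6, 1000), 0)
  # scale invariance: doubling count and total together changes nothing
  expect_equal(fpkm(200, 2e6, 1000), fpkm(100, 1e6, 1000))
  expect_error(fpkm(10, 0, 1000), "library_total")
  expect_error(fpkm(10, 1e6, 0), "exonic_length")
  expect_error(fpkm(-1, 1e6, 1000), "negative")
})

make_expr <- function(mat, library_total = 1e6, value_type = "count") {
  sm <- tibble::tibble(
    sample = colnames(mat),
    condition = sub("_r.*", "", colnames(mat)),
    replicate = as.integer(sub(".*_r", "", colnames(mat))),
    library_total = library_total
  )
  wide <- dplyr::bind_cols(tibble::tibble(transcript_id = rownames(mat)),
                           tibble::as_tibble(mat))
  build_expression_table(wide, sm, value_type)
}

test_that("replicate selection pools the most correlated pair", {
  mat <- cbind(C4_r1 = c(10, 20, 30, 40),
               C4_r2 = c(10, 20, 30, 40),
               C4_r3 = c(40, 30, 11, 5))
  rownames(mat) <- paste0("t", 1:4)
  sel <- select_robust_replicates(make_expr(mat), "C4")
  expect_equal(sel$samples, c("C4_r1", "C4_r2"))
  expect_equal(sel$correlation, 1)
  expect_equal(sel$pooled$value, c(20, 40, 60, 80))  # counts are summed
  expect_equal(unique(sel$pooled$library_total), 2e6)

  # two replicates: that pair, trivially; counts {10, 20} pool to 30
  mat2 <- cbind(C4_r1 = c(10, 5), C4_r2 = c(20, 8))
  rownames(mat2) <- c("a", "b")
  sel2 <- suppressWarnings(select_robust_replicates(make_expr(mat2), "C4"))
  expect_equal(sel2$pooled$value[sel2$pooled$transcript_id == "a"], 30)

  # FPKM mode averages instead of summing
  sel3 <- select_robust_replicates(make_expr(mat2, value_type = "fpkm"), "C4")
  expect_equal(sel3$pooled$value, c(15, 6.5))

  expect_error(
    select_robust_replicates(make_expr(mat[, 1, drop = FALSE]), "C4"),
    "fewer than 2")
  # poorly correlated best pair warns
  mat4 <- cbind(C4_r1 = c(1, 2, 3, 4), C4_r2 = c(4, 1, 2, 2))
  rownames(mat4) <- paste0("t", 1:4)
  expect_warning(select_robust_replicates(make_expr(mat4), "C4"), "0.9")
})

test_that("fisher_de enumerates the two-sided hypergeometric exactly", {
  # table [[2,0],[0,2]]: probabilities 1/6, 4/6, 1/6 -> p = 1/3
  expect_equal(fisher_de(2, 2, 0, 2), 1 / 3)
  expect_equal(fisher_de(5, 100, 5, 100), 1)  # symmetric observed mode
  expect_equal(fisher_de(3, 50, 9, 60), fisher_de(9, 60, 3, 50))  # swap
  expect_error(fisher_de(5, 3, 1, 10), "0 <= c <= n")
  # independent checks against R's reference implementation
  set.seed(3)
  for (i in 1:200) {
    n1 <- sample(1:40, 1); n2 <- sample(1:40, 1)
    c1 <- sample(0:n1, 1); c2 <- sample(0:n2, 1)
    ref <- stats::fisher.test(matrix(c(c1, n1 - c1, c2, n2 - c2), 2,
                                     byrow = TRUE))$p.value
    expect_equal(fisher_de(c1, n1, c2, n2), ref, tolerance = 1e-9)
  }
})

test_that("fold_change applies the pseudocount only near the detection floor", {
  expect_equal(fold_change(10, 20, 0), 2)
  expect_equal(fold_change(0, 1, 0.1), 11)      # (1 + 0.1) / (0 + 0.1)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(10, 20, 0.1), 2)     # both above the floor: raw ratio
  expect_error(fold_change(0, 0, 0), "undefined")
})

test_that("DE status requires both the fold gate and the p gate", {
  prof <- profiles_from_counts(list(
    up = c(C4 = 1000, P4 = 4000, P8 = 1000, R4 = 1000, C8 = 1000),
    weak_p = c(C4 = 2, P4 = 4, P8 = 2, R4 = 2, C8 = 2),
    weak_fc = c(C4 = 1000, P4 = 1900, P8 = 1000, R4 = 1000, C8 = 1000),
    down = c(C4 = 4000, P4 = 1000, P8 = 4000, R4 = 4000, C8 = 4000)
  ))
  de <- call_de(prof, c("C4", "P4"))
  status <- setNames(de$status, de$transcript_id)
  expect_equal(status[["up"]], "UP")           # FC 4, p tiny
  expect_equal(status[["weak_p"]], "UNCHANGED")  # FC 2 but p large
  expect_gt(de$p_value[de$transcript_id == "weak_p"], 0.05)
  expect_equal(status[["weak_fc"]], "UNCHANGED") # p tiny but FC 1.9
  expect_equal(status[["down"]], "DOWN")
  expect_error(call_de(prof, c("C4", "X1")), "missing condition")
})

test_that("DE status is monotone in fold change at fixed significance", {
  # large counts keep p tiny throughout; status must step DOWN ->
  # UNCHANGED -> UP as the fold change rises
  folds <- c(0.25, 0.5, 0.8, 1, 1.5, 2, 4)
  status <- vapply(folds, function(f) {
    prof <- profiles_from_counts(list(
      t = c(C4 = 20000, P4 = round(20000 * f), P8 = 20000, R4 = 20000,
            C8 = 20000)))
    call_de(prof, c("C4", "P4"))$status
  }, character(1))
  expect_equal(status, c("DOWN", "DOWN", "UNCHANGED", "UNCHANGED",
                         "UNCHANGED", "UP", "UP"))
})

test_that("FPKM-only input disables the p gate with a warning", {
  prof <- make_profiles(list(
    t = setNames(c(10, 40, 10, 10, 10), PI)))
  expect_warning(de <- call_de(prof, c("C4", "P4")), "fold change only")
  expect_equal(de$status, "UP")
  expect_true(is.na(de$p_value))
})

test_that("Pi response patterns distinguish reversible and sustained shifts", {
  prof <- profiles_from_counts(list(
    resp = c(C4 = 1000, P4 = 4000, P8 = 4000, R4 = 1000, C8 = 1000),
    sustained = c(C4 = 1000, P4 = 4000, P8 = 4000, R4 = 4500, C8 = 1000),
    down = c(C4 = 4000, P4 = 1000, P8 = 1000, R4 = 4000, C8 = 4000),
    flat = c(C4 = 1000, P4 = 1000, P8 = 1000, R4 = 1000, C8 = 1000)
  ))
  pat <- classify_pi_response(prof)
  got <- setNames(pat$pattern, pat$transcript_id)
  expect_equal(got[["resp"]], "UP_PI_RESPONSIVE")
  expect_equal(got[["sustained"]], "UP_DEPLETION_ONLY")
  expect_equal(got[["down"]], "DOWN_PI_RESPONSIVE")
  expect_equal(got[["flat"]], "NONE")
  expect_error(classify_pi_response(dplyr::filter(prof, condition != "R4")),
               "missing condition")
})

test_that("response labels are stable under uniform FPKM rescaling", {
  prof <- profiles_from_counts(list(
    resp = c(C4 = 1000, P4 = 4000, P8 = 4000, R4 = 1000, C8 = 1000),
    flat = c(C4 = 500, P4 = 500, P8 = 500, R4 = 500, C8 = 500)
  ))
  scaled <- prof |> dplyr::mutate(fpkm = fpkm * 37)
  expect_equal(classify_pi_response(scaled)$pattern,
               classify_pi_response(prof)$pattern)
})

test_that("pearson_r validates its inputs and matches known series", {
  expect_equal(pearson_r(1:5, seq(2, 10, 2)), 1)
  expect_equal(pearson_r(1:5, seq(10, 2, -2)), -1)
  expect_error(pearson_r(1:5, rep(3, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:5), "lengths differ")
  # affine invariance / sign flip
  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(pearson_r(2 * x + 3, y), pearson_r(x, y))
  expect_equal(pearson_r(-2 * x + 3, y), -pearson_r(x, y))
})

test_that("pair detection keeps responsive NATs with strong correlation", {
  nat_calls <- tibble::tibble(
    transcript_id = c("n1", "n2", "n3"), label = "NAT",
    cognate_gene = c("g1", "g2", "g3"),
    overlap_class = c("FULL", "HEAD_TO_HEAD", "TAIL_TO_TAIL")
  )
  prof <- make_profiles(list(
    n1 = setNames(c(10, 40, 45, 12, 11), PI),
    g1 = setNames(c(20, 85, 90, 22, 25), PI),
    n2 = setNames(c(10, 40, 45, 12, 11), PI),
    g2 = setNames(c(50, 12, 10, 48, 49), PI),
    n3 = setNames(c(10, 40, 45, 12, 11), PI),
    g3 = setNames(c(30, 31, 14, 40, 5), PI)   # weak correlation
  ))
  responses <- tibble::tibble(
    transcript_id = c("n1", "n2", "n3"),
    pattern = c("UP_PI_RESPONSIVE", "UP_PI_RESPONSIVE", "UP_PI_RESPONSIVE")
  )
  pairs <- detect_nat_pairs(nat_calls, prof, responses)
  expect_setequal(pairs$nat_id, c("n1", "n2"))
  p1 <- pairs[pairs$nat_id == "n1", ]
  expect_gt(p1$r, 0.9)
  expect_equal(p1$concordance, "CONCORDANT")
  p2 <- pairs[pairs$nat_id == "n2", ]
  expect_lt(p2$r, -0.9)
  expect_equal(p2$concordance, "DISCORDANT")
  expect_true(all(pairs$r2 >= 0.6))
  # the weak pair was excluded by the r2 gate, not by an error
  expect_false("n3" %in% pairs$nat_id)

  # non-responsive NATs never form pairs
  responses_none <- responses |> dplyr::mutate(pattern = "NONE")
  expect_equal(nrow(detect_nat_pairs(nat_calls, prof, responses_none)), 0)

  # constant cognate profile: pair skipped with a message
  prof_const <- prof |>
    dplyr::mutate(fpkm = ifelse(transcript_id == "g1", 7, fpkm))
  expect_message(out <- detect_nat_pairs(nat_calls, prof_const, responses),
                 "constant")
  expect_false("n1" %in% out$nat_id)
})
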