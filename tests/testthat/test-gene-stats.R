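gm_values_for_test <- function(m) {
  v <- as.matrix(tibble::as_tibble(m)[-1]); rownames(v) <- m$symbol; v
}

test_that("gene_test handles standard and degenerate two-group inputs", {
  expect_equal(gene_test(c(1, 2, 3), c(1, 2, 3)), 1)  # t = 0
  # well separated groups: closed-form Welch t gives a vanishing p
  p <- gene_test(c(0, 0.1, -0.1, 0.05), c(10, 10.1, 9.9, 10.05))
  expect_lt(p, 1e-6)
  expect_error(gene_test(1, c(1, 2)), "at least 2")
  expect_equal(gene_test(c(2, 2, 2), c(2, 2)), 1)  # constant and equal
  expect_warning(p <- gene_test(c(1, 1), c(2, 2)), "constant")
  expect_gt(p, 0); expect_lt(p, 1e-300)
  # rank test is exercised through the same interface
  expect_lt(gene_test(1:5, 11:15, method = "rank"), 0.05)
})

test_that("gene_test agrees with a hand-computed Welch statistic", {
  a <- c(1.2, 0.8, 1.5, 1.1); b <- c(2.3, 2.6, 1.9, 2.8, 2.2)
  se <- sqrt(var(a) / 4 + var(b) / 5)
  tstat <- (mean(a) - mean(b)) / se
  df <- se^4 / ((var(a) / 4)^2 / 3 + (var(b) / 5)^2 / 4)
  expect_equal(gene_test(a, b), 2 * pt(abs(tstat), df, lower.tail = FALSE))
})

test_that("BH q-values match the brute-force step-up definition", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(0.03), 0.03)
  set.seed(15)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(adjust_pvalues(p), bh_brute(p))
  }
  expect_error(adjust_pvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("bonferroni returns the family-wise threshold alpha/n", {
  expect_equal(adjust_pvalues(runif(1000, 0.01, 1), "bonferroni"), 5e-5)
  expect_equal(adjust_pvalues(c(0.2, 0.4), "bonferroni", alpha = 0.1), 0.05)
})

test_that("storey q-values shrink BH by the estimated null proportion", {
  set.seed(16)
  p <- c(runif(180), runif(20, 0, 1e-4))
  q <- adjust_pvalues(p, "storey")
  expect_true(all(q <= adjust_pvalues(p) + 1e-12))
  expect_true(all(q > 0 & q <= 1))
})

test_that("directional sign follows the baseline rule", {
  expect_equal(directional_sign(1, 2), -1)
  expect_equal(directional_sign(2, 1), +1)
  expect_equal(directional_sign(1, 1), 0)
})

null_matrix <- function(n_genes, n1, n2, seed) {
  set.seed(seed)
  gene_matrix(dplyr::bind_cols(
    tibble::tibble(symbol = sprintf("G%04d", seq_len(n_genes))),
    tibble::as_tibble(matrix(rnorm(n_genes * (n1 + n2)), n_genes,
                             dimnames = list(NULL, sprintf("s%03d", seq_len(n1 + n2)))))),
    "cnv")
}

test_that("manhattan q-values stay honest on null data and find a spike", {
  m <- null_matrix(500, 10, 10, seed = 17)
  ga <- matrix_samples(m)[1:10]; gb <- matrix_samples(m)[11:20]
  res <- manhattan_stats(m, ga, gb)
  expect_equal(nrow(res), 500)
  expect_lte(sum(res$q_value < 0.05), 0.05 * 500)
  expect_true(all(res$direction == 1))  # regular mode

  # spike one gene by 5 sd: it tops the -log10 q ranking
  spiked <- tibble::as_tibble(m)
  spiked[spiked$symbol == "G0001", ga] <- spiked[spiked$symbol == "G0001", ga] + 5
  res2 <- manhattan_stats(gene_matrix(spiked, "cnv"), ga, gb,
                          directional = TRUE)
  expect_equal(res2$symbol[which.max(res2$neg_log10_q)], "G0001")
  expect_equal(res2$direction[res2$symbol == "G0001"], 1)

  expect_error(manhattan_stats(m, ga, ga), "disjoint")
})

test_that("manhattan q-values are invariant to gene order", {
  m <- null_matrix(100, 5, 5, seed = 18)
  ga <- matrix_samples(m)[1:5]; gb <- matrix_samples(m)[6:10]
  res <- manhattan_stats(m, ga, gb)
  shuf <- gene_matrix(tibble::as_tibble(m)[sample(100), ], "cnv")
  res2 <- manhattan_stats(shuf, ga, gb)
  expect_equal(res2$q_value[match(res$symbol, res2$symbol)], res$q_value)
})

test_that("deflection amplitudes carry the tumor-vs-normal median sign", {
  set.seed(19)
  mk <- function(shift, prefix, n = 6) {
    vals <- matrix(rnorm(40 * n, 0, 0.2), 40)
    vals[1:10, ] <- vals[1:10, ] + shift  # first 10 genes altered
    gene_matrix(dplyr::bind_cols(
      tibble::tibble(symbol = sprintf("G%02d", 1:40)),
      tibble::as_tibble(`colnames<-`(vals, paste0(prefix, seq_len(n))))), "cnv")
  }
  rec <- deflection_stats(mk(2, "ta"), mk(0, "na"), mk(-2, "tb"), mk(0, "nb"))
  altered <- rec[rec$symbol %in% sprintf("G%02d", 1:10), ]
  expect_true(all(altered$amplitude_a > 0))   # tumor median above normal
  expect_true(all(altered$amplitude_b < 0))   # deletion: below baseline

  # sign(amplitude) == sign(median difference) over randomized inputs
  for (rep in 1:10) {
    ta <- mk(rnorm(1), "ta"); na <- mk(0, "na")
    rec <- deflection_stats(ta, na, mk(0, "tb"), mk(0, "nb"))
    med_diff <- apply(gm_values_for_test(ta), 1, median) -
      apply(gm_values_for_test(na), 1, median)
    nz <- rec$amplitude_a != 0
    expect_equal(sign(rec$amplitude_a[nz]), sign(med_diff[nz]))
  }
})

test_that("deflection winner takes the larger absolute amplitude", {
  # constructed from known q-values via two-point groups
  set.seed(20)
  strong <- gene_matrix(tibble::tibble(symbol = "G", a1 = 0, a2 = 0.01,
                                       a3 = -0.01), "cnv")
  strong_t <- gene_matrix(tibble::tibble(symbol = "G", b1 = 5, b2 = 5.01,
                                         b3 = 4.99), "cnv")
  weak_t <- gene_matrix(tibble::tibble(symbol = "G", c1 = 0.05, c2 = 0.2,
                                       c3 = -0.1), "cnv")
  rec <- deflection_stats(strong_t, strong, weak_t, strong)
  expect_equal(rec$winner, "type_a")
  expect_gt(abs(rec$amplitude_a), abs(rec$amplitude_b))
})

test_that("volcano stats use raw p, pseudo-counted ratios and strict cutoff", {
  set.seed(22)
  n <- 6
  e1 <- matrix(rexp(20 * n, 1 / 100), 20)
  expr <- gene_matrix(dplyr::bind_cols(
    tibble::tibble(symbol = sprintf("G%02d", 1:20)),
    tibble::as_tibble(`colnames<-`(cbind(2 * e1, e1),
                                   sprintf("s%02d", 1:(2 * n))))), "expression")
  ga <- sprintf("s%02d", 1:n); gb <- sprintf("s%02d", (n + 1):(2 * n))
  res <- volcano_stats(expr, ga, gb)
  # mean1 = 2*mean2 with negligible pseudo-count -> log2FC near 1
  expect_true(all(abs(res$log2_fold_change - 1) < 0.1))
  expect_equal(res$neg_log10_p, -log10(res$p_value))

  # equal groups -> log2FC exactly 0; p = 1 boundary is not significant
  eq <- gene_matrix(tibble::tibble(symbol = "G", a = 1, b = 2, c = 1, d = 2),
                    "expression")
  res <- volcano_stats(eq, c("a", "b"), c("c", "d"))
  expect_equal(res$log2_fold_change, 0)
  expect_false(res$significant)

  neg <- gene_matrix(tibble::tibble(symbol = "G", a = -1, b = 2, c = 1, d = 2),
                     "expression")
  expect_error(volcano_stats(neg, c("a", "b"), c("c", "d")), "negative")
})

test_that("volcano fold change is antisymmetric under group swap", {
  m <- null_matrix(50, 4, 4, seed = 23)
  ga <- matrix_samples(m)[1:4]; gb <- matrix_samples(m)[5:8]
  r1 <- volcano_stats(m, ga, gb)
  r2 <- volcano_stats(m, gb, ga)
  expect_equal(r1$log2_fold_change, -r2$log2_fold_change)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("CNV-expression correlation recovers exact linear relations", {
  cnv <- gene_matrix(tibble::tibble(symbol = "EGFR", s1 = 0, s2 = 1, s3 = 2,
                                    s4 = 3), "cnv")
  expr <- gene_matrix(tibble::tibble(symbol = "EGFR", s1 = 1, s2 = 3, s3 = 5,
                                     s4 = 7), "expression")
  res <- cnv_expression_correlation("EGFR", cnv, expr)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(res$n, 4)

  anti <- gene_matrix(tibble::tibble(symbol = "EGFR", s1 = 0, s2 = -1,
                                     s3 = -2, s4 = -3), "expression")
  expect_equal(cnv_expression_correlation("EGFR", cnv, anti)$pearson_r, -1)

  const <- gene_matrix(tibble::tibble(symbol = "EGFR", s1 = 5, s2 = 5, s3 = 5,
                                      s4 = 5), "expression")
  expect_error(cnv_expression_correlation("EGFR", cnv, const),
               "undefined correlation")
})

test_that("type-I error of the gene test sits near nominal on null data", {
  set.seed(24)
  p <- vapply(1:2000, function(i) gene_test(rnorm(10), rnorm(10)), double(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03); expect_lte(rate, 0.07)
})
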