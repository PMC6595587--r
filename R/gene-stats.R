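#' Two-group test for one gene
#'
#' Two-sided test of a location difference between two sample groups of one
#' gene's values. The default is Welch's unequal-variance t-test (group
#' variances differ markedly across cancer cohorts, so the pooled-variance
#' form is avoided); `method = "rank"` selects the Wilcoxon rank-sum test.
#' Degenerate inputs are handled explicitly: two constant, equal groups give
#' `p = 1`; two constant but different groups have a zero-variance statistic
#' and give the smallest representable positive p with a warning.
#'
#' @param values_a,values_b numeric vectors (NA allowed, dropped), each with
#'   at least 2 non-missing values.
#' @param method `"t"` (Welch) or `"rank"` (Wilcoxon).
#' @return two-sided p-value in `(0, 1]`.
#' @export
#' @examples
#' gene_test(c(1, 2, 3), c(1, 2, 3))
gene_test <- function(values_a, values_b, method = c("t", "rank")) {
  method <- match.arg(method)
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop_mcv("each group needs at least 2 non-missing values", "validation_error")
  }
  const_a <- diff(range(values_a)) == 0
  const_b <- diff(range(values_b)) == 0
  if (const_a && const_b) {
    if (values_a[1] == values_b[1]) return(1)
    warn("both groups constant with different values; p set to smallest positive")
    return(.Machine$double.xmin)
  }
  if (method == "t") {
    t.test(values_a, values_b, var.equal = FALSE)$p.value
  } else {
    suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE)$p.value)
  }
}

#' Multiple-testing adjustment
#'
#' `method = "BH"` returns Benjamini–Hochberg step-up q-values
#' (`q_i = min_{j >= i} p_(j) * n / j` in sorted order, capped at 1), the
#' default false-discovery-rate control behind the Manhattan and Deflection
#' statistics. `method = "storey"` scales the BH q-values by a fixed-lambda
#' (0.5) estimate of the null proportion pi0. `method = "bonferroni"`
#' returns the single family-wise significance threshold `alpha / n` instead
#' of a vector (the most conservative option).
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @param method `"BH"`, `"storey"` or `"bonferroni"`.
#' @param alpha family-wise level for the Bonferroni threshold.
#' @return q-value vector (BH/storey) or a single threshold (bonferroni).
#' @export
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.04))
#' adjust_pvalues(rep(0.01, 1000), method = "bonferroni")
adjust_pvalues <- function(p, method = c("BH", "storey", "bonferroni"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop_mcv("p-values must lie in (0, 1]", "validation_error")
  }
  switch(method,
    BH = p.adjust(p, method = "BH"),
    storey = {
      lambda <- 0.5
      pi0 <- min(1, mean(p > lambda) / (1 - lambda))
      pmin(1, pi0 * p.adjust(p, method = "BH"))
    },
    bonferroni = alpha / length(p)
  )
}

#' Direction of a group-median difference
#'
#' Sign convention of the directional Manhattan plot: a gene whose median in
#' group 1 is smaller than in group 2 sits under the baseline (`-1`), larger
#' sits above (`+1`), equal medians sit on the baseline (`0`).
#'
#' @param median_a,median_b finite group medians.
#' @return `-1`, `0` or `+1` (vectorized).
#' @export
directional_sign <- function(median_a, median_b) {
  sign(median_a - median_b)
}

test_gene_rows <- function(x, group_a, group_b, method) {
  vals_a <- gm_values(x, group_a)
  vals_b <- gm_values(x, group_b)
  ok <- rowSums(!is.na(vals_a)) >= 2 & rowSums(!is.na(vals_b)) >= 2
  if (any(!ok)) {
    warn(paste0(sum(!ok), " gene(s) with < 2 observed values per group skipped"))
  }
  idx <- which(ok)
  tibble::tibble(
    symbol = x$symbol[idx],
    median_a = unname(apply(vals_a[idx, , drop = FALSE], 1, median, na.rm = TRUE)),
    median_b = unname(apply(vals_b[idx, , drop = FALSE], 1, median, na.rm = TRUE)),
    mean_a = unname(rowMeans(vals_a[idx, , drop = FALSE], na.rm = TRUE)),
    mean_b = unname(rowMeans(vals_b[idx, , drop = FALSE], na.rm = TRUE)),
    p_value = vapply(idx, function(i) {
      gene_test(vals_a[i, ], vals_b[i, ], method)
    }, double(1))
  )
}

#' Per-gene Manhattan statistics
#'
#' Gene-level analogue of the GWAS Manhattan plot: every gene is tested
#' between two disjoint sample groups, p-values are converted to q-values
#' over exactly the tested gene set, and the plotted amplitude is
#' `-log10(q)`. In regular mode all amplitudes point up (`direction = +1`);
#' in directional mode each gene carries [directional_sign()] of its group
#' medians.
#'
#' @param x a `gene_matrix`.
#' @param group_a,group_b disjoint sample id vectors, each of size >= 2.
#' @param directional carry the median-difference sign?
#' @param test `"t"` or `"rank"`, see [gene_test()].
#' @param fdr `"BH"` or `"storey"`, see [adjust_pvalues()].
#' @return tibble `symbol`, `median_a`, `median_b`, `p_value`, `q_value`,
#'   `neg_log10_q`, `direction`.
#' @export
manhattan_stats <- function(x, group_a, group_b, directional = FALSE,
                            test = c("t", "rank"), fdr = c("BH", "storey")) {
  test <- match.arg(test); fdr <- match.arg(fdr)
  if (length(intersect(group_a, group_b))) {
    stop_mcv("sample groups must be disjoint", "validation_error")
  }
  res <- test_gene_rows(x, group_a, group_b, test)
  res$q_value <- adjust_pvalues(res$p_value, fdr)
  res$neg_log10_q <- -log10(res$q_value)
  res$direction <- if (directional) {
    directional_sign(res$median_a, res$median_b)
  } else rep(1, nrow(res))
  res[c("symbol", "median_a", "median_b", "p_value", "q_value",
        "neg_log10_q", "direction")]
}

#' Per-gene Deflection statistics for two cancer types
#'
#' For each gene and each cancer type, the deflection amplitude is the
#' signed `-log10` q-value of the tumor-vs-nonmalignant test: positive when
#' the tumor median exceeds the nonmalignant median, negative when it is
#' below it. The `winner` column names the type with the larger absolute
#' amplitude (the more strongly deflected one), which drives the two-color
#' rendering.
#'
#' @param tumor_a,normal_a `gene_matrix` of cancer type 1's tumor and
#'   nonmalignant samples.
#' @param tumor_b,normal_b same for cancer type 2.
#' @param test,fdr see [manhattan_stats()].
#' @return tibble `symbol`, `amplitude_a`, `amplitude_b`, `winner`
#'   (`"type_a"`, `"type_b"` or `"tie"`).
#' @export
deflection_stats <- function(tumor_a, normal_a, tumor_b, normal_b,
                             test = c("t", "rank"), fdr = c("BH", "storey")) {
  test <- match.arg(test); fdr <- match.arg(fdr)
  one_type <- function(tum, nor) {
    common <- intersect(tum$symbol, nor$symbol)
    merged <- gene_matrix(
      dplyr::inner_join(tibble::as_tibble(tum), tibble::as_tibble(nor),
                        by = "symbol"),
      value_kind(tum))
    res <- test_gene_rows(merged, matrix_samples(tum), matrix_samples(nor), test)
    res$q_value <- adjust_pvalues(res$p_value, fdr)
    res$amplitude <- directional_sign(res$median_a, res$median_b) *
      (-log10(res$q_value))
    res[c("symbol", "amplitude")]
  }
  a <- one_type(tumor_a, normal_a)
  b <- one_type(tumor_b, normal_b)
  both <- dplyr::inner_join(a, b, by = "symbol", suffix = c("_a", "_b"))
  if (!nrow(both)) {
    stop_mcv("empty common gene set between the two cancer types",
             "validation_error")
  }
  both$winner <- dplyr::case_when(
    abs(both$amplitude_a) > abs(both$amplitude_b) ~ "type_a",
    abs(both$amplitude_a) < abs(both$amplitude_b) ~ "type_b",
    .default = "tie")
  both
}

#' Per-gene volcano statistics
#'
#' Significance versus fold change: the y axis is `-log10` of the raw
#' p-value (the conventional choice for this display, unlike the
#' q-value-based Manhattan/Deflection amplitudes) and the x axis is the
#' effect size. For expression matrices the effect is
#' `log2((mean_a + 1) / (mean_b + 1))` — a pseudo-count of 1 on normalized
#' counts avoids division by zero; negative expression values are an error.
#' For CNV matrices, whose values are already log2-scale ratios, the effect
#' is the difference of group means. Significance uses a strict `p < cutoff`.
#'
#' @param x a `gene_matrix` (its `value_kind` selects the effect size).
#' @param group_a,group_b sample id vectors, each >= 2.
#' @param cutoff p-value cutoff for the `significant` flag (default 0.05).
#' @param test `"t"` or `"rank"`.
#' @param pseudo_count pseudo-count for the expression ratio.
#' @return tibble `symbol`, `log2_fold_change`, `p_value`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_stats <- function(x, group_a, group_b, cutoff = 0.05,
                          test = c("t", "rank"), pseudo_count = 1) {
  test <- match.arg(test)
  kind <- value_kind(x)
  if (kind == "expression" && any(gm_values(x) < 0, na.rm = TRUE)) {
    stop_mcv("negative values in an expression matrix", "validation_error")
  }
  res <- test_gene_rows(x, group_a, group_b, test)
  res$log2_fold_change <- if (kind == "expression") {
    log2((res$mean_a + pseudo_count) / (res$mean_b + pseudo_count))
  } else {
    res$mean_a - res$mean_b
  }
  res$neg_log10_p <- -log10(res$p_value)
  res$significant <- res$p_value < cutoff
  res[c("symbol", "log2_fold_change", "p_value", "neg_log10_p", "significant")]
}

#' CNV-expression correlation and regression for one gene
#'
#' Pearson correlation coefficient and ordinary least-squares fit of a
#' gene's expression on its copy-number value across the samples present in
#' both matrices with non-missing values.
#'
#' @param symbol HUGO gene symbol.
#' @param cnv,expr `gene_matrix` objects containing the gene.
#' @param sample_ids optional restriction to a sample set.
#' @return one-row tibble `symbol`, `pearson_r`, `slope`, `intercept`, `n`.
#' @export
cnv_expression_correlation <- function(symbol, cnv, expr, sample_ids = NULL) {
  samples <- intersect(matrix_samples(cnv), matrix_samples(expr))
  if (!is.null(sample_ids)) samples <- intersect(samples, sample_ids)
  i <- match(symbol, cnv$symbol); j <- match(symbol, expr$symbol)
  if (is.na(i) || is.na(j)) {
    stop_mcv(paste0("gene not present in both matrices: ", symbol),
             "validation_error")
  }
  xv <- as.numeric(cnv[i, samples])
  yv <- as.numeric(expr[j, samples])
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) {
    stop_mcv("need at least 3 paired non-missing samples", "validation_error")
  }
  if (diff(range(xv)) == 0 || diff(range(yv)) == 0) {
    stop_mcv("undefined correlation: one of the vectors is constant",
             "validation_error")
  }
  fit <- lm(yv ~ xv)
  tibble::tibble(symbol = symbol,
                 pearson_r = cor(xv, yv),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(xv))
}
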