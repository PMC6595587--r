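test_that("synthetic layouts place the configured genes deterministically", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_arm = 10, seed = 3)
  g1 <- generate_layout(cfg)
  g2 <- generate_layout(cfg)
  expect_identical(g1, g2)
  expect_equal(nrow(g1$annotation), 40)  # 2 chromosomes x 2 arms x 10 genes
  # genes are non-overlapping within a chromosome
  ann <- dplyr::arrange(g1$annotation, chromosome, start)
  by_chr <- split(ann, ann$chromosome)
  for (tbl in by_chr) {
    expect_true(all(tbl$start[-1] > tbl$end[-nrow(tbl)]))
  }
  # acrocentric chromosomes carry q genes only
  cfg22 <- sim_config(n_chromosomes = 22, genes_per_arm = 2)
  ann22 <- generate_layout(cfg22)$annotation
  for (chrom in c("13", "14", "15", "21", "22")) {
    expect_false(any(grepl("P", ann22$symbol[ann22$chromosome == chrom])))
  }
  expect_error(sim_config(genes_per_arm = 10, arm_length = 1e4), "fit")
})

test_that("segment generation honors noise, alterations and the seed", {
  cfg0 <- sim_config(n_chromosomes = 1, genes_per_arm = 5, n_tumor = 2,
                     n_normal = 2, noise_sd = 0, seed = 4)
  gen0 <- generate_segments(cfg0)
  expect_true(all(gen0$segments$segment_mean == 0))

  # same seed -> byte-identical SEG output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  cfg <- sim_config(n_chromosomes = 2, genes_per_arm = 5, n_tumor = 3,
                    n_normal = 3, seed = 5,
                    alterations = alteration("1", "q", "broad", 0.5))
  write_seg_file(generate_segments(cfg)$segments, f1)
  write_seg_file(generate_segments(cfg)$segments, f2)
  expect_identical(readLines(f1), readLines(f2))

  # broad +0.5 on 1q with full penetrance: tumor mean within sampling bounds
  cfg_b <- sim_config(n_chromosomes = 1, genes_per_arm = 10, n_tumor = 50,
                      n_normal = 2, noise_sd = 0.1, seed = 6,
                      alterations = alteration("1", "q", "broad", 0.5))
  gen <- generate_segments(cfg_b)
  cnv <- map_segments_to_genes(gen$segments, gen$annotation)
  tumors <- grep("-01$", matrix_samples(cnv), value = TRUE)
  q_genes <- strsplit(gen$truth$genes, ",")[[1]]
  q_mean <- mean(as.matrix(tibble::as_tibble(cnv)[cnv$symbol %in% q_genes,
                                                  tumors]))
  expect_lt(abs(q_mean - 0.5), 3 * 0.1 / sqrt(50))
})

test_that("the truth record names the affected genes and samples", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_arm = 6, n_tumor = 10,
                    n_normal = 2, seed = 8,
                    alterations = list(
                      alteration("2", "p", "broad", 1, affected_fraction = 0.5),
                      alteration("1", "q", "focal", 2, focal_span = c(2, 3))))
  gen <- generate_segments(cfg)
  expect_equal(nrow(gen$truth), 2)
  broad <- gen$truth[gen$truth$kind == "broad", ]
  expect_equal(length(strsplit(broad$samples, ",")[[1]]), 5)  # half the tumors
  expect_equal(length(strsplit(broad$genes, ",")[[1]]), 6)
  focal <- gen$truth[gen$truth$kind == "focal", ]
  expect_equal(strsplit(focal$genes, ",")[[1]], c("G1Q002", "G1Q003"))
  # all tumor samples are -01 barcodes, normals -11
  expect_true(all(grepl("-01$", strsplit(broad$samples, ",")[[1]])))
})

test_that("expression follows the linear CNV model with clamping", {
  cnv <- gene_matrix(tibble::tibble(symbol = c("A", "B"),
                                    s1 = c(0.5, -10), s2 = c(0, NA)), "cnv")
  cfg <- sim_config(expression_baseline = 10, expression_slope = 2,
                    expression_noise_sd = 0, seed = 9)
  expr <- generate_expression(cfg, cnv)
  expect_equal(value_kind(expr), "expression")
  expect_equal(expr$s1[expr$symbol == "A"], 11)  # 10 + 2*0.5
  expect_equal(expr$s1[expr$symbol == "B"], 0)   # clamped at 0
  expect_true(is.na(expr$s2[expr$symbol == "B"]))

  # slope 0: expression is independent of CNV; with n = 200 samples a null
  # Pearson r has sd ~ 1/sqrt(200), so check the average over 10 genes
  set.seed(10)
  big <- gene_matrix(dplyr::bind_cols(
    tibble::tibble(symbol = sprintf("G%02d", 1:10)),
    tibble::as_tibble(matrix(rnorm(2000), 10,
                             dimnames = list(NULL, sprintf("s%03d", 1:200))))),
    "cnv")
  cfg0 <- sim_config(expression_slope = 0, expression_noise_sd = 1, seed = 11)
  e0 <- generate_expression(cfg0, big)
  r <- vapply(1:10, function(i) {
    cor(as.numeric(tibble::as_tibble(big)[i, -1]),
        as.numeric(tibble::as_tibble(e0)[i, -1]))
  }, double(1))
  expect_lt(mean(abs(r)), 0.1)
  expect_lt(max(abs(r)), 0.25)
})

test_that("generated cohorts re-parse through the readers without warnings", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_chromosomes = 3, genes_per_arm = 4, n_tumor = 4,
                    n_normal = 4, seed = 12,
                    alterations = alteration("3", "q", "broad", 1))
  out <- simulate_cohort(cfg, dir)
  expect_no_warning({
    seg <- read_seg_file(out$segments)
    ann <- read_gene_annotation(out$annotation)
    lay <- read_genome_layout(out$layout)
    expr <- read_gene_matrix(out$expression, "expression")
  })
  expect_equal(seg, out$segments_tbl)
  expect_equal(ann, out$annotation_tbl)
  expect_equal(nrow(expr), nrow(out$cnv))
})

test_that("an end-to-end fixture recovers broad and focal events", {
  cfg <- sim_config(
    n_chromosomes = 4, genes_per_arm = 12, n_tumor = 12, n_normal = 12,
    noise_sd = 0.1, seed = 13,
    alterations = list(
      alteration("2", "q", "broad", 1),
      alteration("3", "p", "focal", 2, focal_span = c(5, 5))))
  gen <- generate_segments(cfg)
  cnv <- map_segments_to_genes(gen$segments, gen$annotation)
  tumors <- grep("-01$", matrix_samples(cnv), value = TRUE)
  normals <- grep("-11$", matrix_samples(cnv), value = TRUE)

  rep <- similarity_report(cnv, gen$annotation, gen$layout, tumors, normals,
                           n_boot = 199, seed = 14)
  arm_rows <- rep[rep$chromosome != "genome-wide", ]
  amp <- which(arm_rows$chromosome == "2" & arm_rows$arm == "q")
  expect_equal(which.min(arm_rows$dtw_score), amp)
  expect_lte(arm_rows$boot_p[amp], 0.05)

  # the focal gene tops its arm's tumor Mountain curve
  smry <- summarize_group(cnv, tumors)
  curve <- build_arm_curve(smry, gen$annotation, gen$layout, "3", "p")
  expect_equal(curve$symbol[which.max(curve$value)], "G3P005")
})
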