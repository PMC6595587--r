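#' Describe one simulated copy-number alteration
#'
#' An alteration adds `magnitude` to the segment means of affected tumor
#' samples: `kind = "broad"` hits a whole arm (the arm-scale gains/losses
#' that dominate many cancer genomes), `kind = "focal"` hits only the genes
#' in `focal_span` (1-based gene indices within the arm, e.g. a one-gene
#' amplicon).
#'
#' @param chromosome chromosome label.
#' @param arm `"p"`, `"q"` or `"whole"` (both arms).
#' @param kind `"broad"` or `"focal"`.
#' @param magnitude value added to affected segment means (log2-ratio scale).
#' @param focal_span for focal events, `c(first, last)` gene index on the arm.
#' @param affected_fraction fraction of tumor samples carrying the event,
#'   in (0, 1].
#' @return an `alteration_spec` list.
#' @export
alteration <- function(chromosome, arm = c("q", "p", "whole"),
                       kind = c("broad", "focal"),
                       magnitude = 1, focal_span = NULL,
                       affected_fraction = 1) {
  arm <- match.arg(arm); kind <- match.arg(kind)
  if (!is.finite(magnitude)) stop_mcv("magnitude must be finite", "validation_error")
  if (affected_fraction <= 0 || affected_fraction > 1) {
    stop_mcv("affected_fraction must be in (0, 1]", "validation_error")
  }
  if (kind == "focal" && (is.null(focal_span) || length(focal_span) != 2)) {
    stop_mcv("a focal alteration needs focal_span = c(first, last)",
             "validation_error")
  }
  structure(list(chromosome = normalize_chromosome(chromosome), arm = arm,
                 kind = kind, magnitude = magnitude,
                 focal_span = focal_span,
                 affected_fraction = affected_fraction),
            class = "alteration_spec")
}

#' Configuration of a synthetic CNV cohort
#'
#' The generator emulates a TCGA-style cohort at desk scale: a genome of
#' `n_chromosomes` chromosomes (those labelled 13, 14, 15, 21, 22 are
#' acrocentric — no genes on their p arms), arms tiled by abutting segments
#' whose means are baseline 0 (a log2-ratio scale) plus Gaussian noise, with
#' broad and/or focal alterations added to a fraction of tumor samples.
#' Tumor samples carry `-01` barcodes, nonmalignant controls `-11`, so the
#' barcode filters are exercised end to end. Defaults — 30 tumors, 30
#' normals, segment noise sd 0.1, 25 genes per arm — are the cohort scale
#' at which the package's group-comparison machinery is meant to operate.
#'
#' @param n_chromosomes number of chromosomes (1..22).
#' @param genes_per_arm genes placed on each non-acrocentric arm.
#' @param gene_length,gene_spacing gene body length and inter-gene gap (bp).
#' @param segments_per_arm uniform tiling granularity per arm.
#' @param arm_length optional explicit arm length; must fit the genes.
#' @param n_tumor,n_normal group sizes.
#' @param noise_sd Gaussian sd of segment means around baseline.
#' @param baseline baseline segment mean (0 = log2-ratio scale; 2 gives
#'   absolute-copy-number style fixtures).
#' @param alterations list of [alteration()] specs.
#' @param expression_baseline,expression_slope,expression_noise_sd linear
#'   CNV->expression model: `max(0, baseline + slope * cnv + noise)`.
#' @param seed integer seed; every generated artifact is deterministic
#'   under it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 22, genes_per_arm = 25,
                       gene_length = 1e4, gene_spacing = 9e4,
                       segments_per_arm = 10, arm_length = NULL,
                       n_tumor = 30, n_normal = 30, noise_sd = 0.1,
                       baseline = 0, alterations = list(),
                       expression_baseline = 8, expression_slope = 2,
                       expression_noise_sd = 1, seed = 1) {
  stopifnot(n_chromosomes >= 1, n_chromosomes <= 22, genes_per_arm >= 1,
            segments_per_arm >= 1, n_tumor >= 1, n_normal >= 1,
            noise_sd >= 0, expression_noise_sd >= 0)
  if (inherits(alterations, "alteration_spec")) alterations <- list(alterations)
  needed <- genes_per_arm * (gene_length + gene_spacing)
  if (is.null(arm_length)) {
    arm_length <- needed
  } else if (arm_length < needed) {
    stop_mcv("genes_per_arm does not fit in arm_length", "validation_error")
  }
  structure(list(
    n_chromosomes = n_chromosomes, genes_per_arm = genes_per_arm,
    gene_length = gene_length, gene_spacing = gene_spacing,
    segments_per_arm = segments_per_arm, arm_length = arm_length,
    n_tumor = n_tumor, n_normal = n_normal, noise_sd = noise_sd,
    baseline = baseline, alterations = alterations,
    expression_baseline = expression_baseline,
    expression_slope = expression_slope,
    expression_noise_sd = expression_noise_sd,
    centromere_width = 3e6, seed = seed), class = "sim_config")
}

sim_sample_ids <- function(config) {
  c(sprintf("TCGA-SIM-%04d-01", seq_len(config$n_tumor)),
    sprintf("TCGA-SIM-%04d-11", config$n_tumor + seq_len(config$n_normal)))
}

#' Generate the synthetic gene annotation and genome layout
#'
#' Places `genes_per_arm` non-overlapping genes on each arm (q arms only for
#' acrocentric chromosomes), with the centromere between the two arms.
#' Purely deterministic given the config.
#'
#' @param config a [sim_config()].
#' @return list with elements `annotation` (tibble symbol/chromosome/
#'   start/end) and `layout` (tibble chromosome/centromere_start/
#'   centromere_end/length/acrocentric).
#' @export
generate_layout <- function(config) {
  chroms <- as.character(seq_len(config$n_chromosomes))
  al <- config$arm_length; cw <- config$centromere_width
  layout <- tibble::tibble(
    chromosome = chroms,
    centromere_start = al + 1,
    centromere_end = al + cw,
    length = 2 * al + cw
  ) |> validate_layout()

  step <- config$gene_length + config$gene_spacing
  one_arm <- function(chrom, arm, offset) {
    start <- offset + (seq_len(config$genes_per_arm) - 1) * step + 1
    tibble::tibble(
      symbol = sprintf("G%s%s%03d", chrom, toupper(arm),
                       seq_len(config$genes_per_arm)),
      chromosome = chrom,
      start = start,
      end = start + config$gene_length - 1)
  }
  annotation <- purrr::map_dfr(chroms, function(chrom) {
    acro <- chrom %in% acrocentric_labels()
    dplyr::bind_rows(
      if (!acro) one_arm(chrom, "p", 0),
      one_arm(chrom, "q", al + cw))
  })
  list(annotation = validate_annotation(annotation), layout = layout)
}

# arm tiling reused by generate_segments: abutting closed segments, split at
# focal-span boundaries so focal events hit exactly their genes
arm_tiles <- function(config, chrom, arm, annotation) {
  al <- config$arm_length; cw <- config$centromere_width
  lo <- if (arm == "p") 1 else al + cw + 1
  hi <- if (arm == "p") al else 2 * al + cw
  cuts <- round(seq(lo - 1, hi, length.out = config$segments_per_arm + 1))
  for (alt in config$alterations) {
    if (alt$kind == "focal" && alt$chromosome == chrom &&
        (alt$arm == arm || alt$arm == "whole")) {
      genes <- arm_genes(annotation, chrom, arm)
      span <- genes[alt$focal_span[1]:alt$focal_span[2], ]
      cuts <- c(cuts, min(span$start) - 1, max(span$end))
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, lo - 1), hi)))
  tibble::tibble(chromosome = chrom, arm = arm,
                 start = head(cuts, -1) + 1, end = cuts[-1])
}

arm_genes <- function(annotation, chrom, arm_label) {
  # genes of one synthetic arm, by construction wholly on one side
  genes <- annotation[annotation$chromosome == chrom, ]
  genes <- genes[order(genes$start), ]
  if (!nrow(genes)) return(genes)
  if (arm_label == "p") genes[grepl("P", genes$symbol), ]
  else genes[grepl("Q", genes$symbol), ]
}

#' Generate the synthetic segment table
#'
#' Tiles every arm of every sample with abutting segments whose means are
#' `baseline + N(0, noise_sd)`, then adds each alteration's magnitude to the
#' overlapping segments of its affected tumor samples. Byte-identical output
#' under a fixed seed.
#'
#' @param config a [sim_config()].
#' @param genome optional precomputed [generate_layout()] result.
#' @return list with `segments` (SEG-style tibble), `truth` (one row per
#'   alteration: chromosome, arm, kind, magnitude, span, affected genes and
#'   samples), `annotation`, `layout`.
#' @export
generate_segments <- function(config, genome = generate_layout(config)) {
  annotation <- genome$annotation
  chroms <- as.character(seq_len(config$n_chromosomes))
  tiles <- purrr::map_dfr(chroms, function(chrom) {
    dplyr::bind_rows(arm_tiles(config, chrom, "p", annotation),
                     arm_tiles(config, chrom, "q", annotation))
  })
  ids <- sim_sample_ids(config)
  tumor_ids <- ids[seq_len(config$n_tumor)]

  with_local_seed(config$seed, function() {
    seg <- tidyr::expand_grid(sample = ids, tiles)
    seg$segment_mean <- config$baseline +
      rnorm(nrow(seg), sd = config$noise_sd)

    truth_rows <- list()
    for (k in seq_along(config$alterations)) {
      alt <- config$alterations[[k]]
      arms <- if (alt$arm == "whole") c("p", "q") else alt$arm
      for (a in arms) {
        genes <- arm_genes(annotation, alt$chromosome, a)
        if (!nrow(genes)) next
        if (alt$kind == "focal") {
          genes <- genes[alt$focal_span[1]:alt$focal_span[2], ]
        }
        span <- c(min(genes$start), max(genes$end))
        n_aff <- ceiling(alt$affected_fraction * length(tumor_ids))
        affected <- sort(sample(tumor_ids, n_aff))
        hit <- seg$sample %in% affected &
          seg$chromosome == alt$chromosome & seg$arm == a &
          seg$start <= span[2] & seg$end >= span[1]
        seg$segment_mean[hit] <- seg$segment_mean[hit] + alt$magnitude
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          alteration = k, chromosome = alt$chromosome, arm = a,
          kind = alt$kind, magnitude = alt$magnitude,
          span_start = span[1], span_end = span[2],
          genes = paste(genes$symbol, collapse = ","),
          samples = paste(affected, collapse = ","))
      }
    }
    segments <- tibble::tibble(
      sample = seg$sample, chromosome = seg$chromosome,
      start = seg$start, end = seg$end,
      num_probes = pmax(1, round((seg$end - seg$start + 1) / 1e4)),
      segment_mean = round(seg$segment_mean, 4))
    list(segments = segments, truth = dplyr::bind_rows(truth_rows),
         annotation = annotation, layout = genome$layout)
  })
}

#' Generate CNV-correlated expression values
#'
#' `expression = max(0, baseline + slope * cnv + N(0, sd))`, elementwise on
#' the gene-level CNV matrix; `NA` CNV values stay `NA`. Deterministic under
#' the config seed.
#'
#' @param config a [sim_config()].
#' @param cnv a `gene_matrix` of CNV values.
#' @return a `gene_matrix` with `value_kind = "expression"`.
#' @export
generate_expression <- function(config, cnv) {
  vals <- gm_values(cnv)
  expr <- with_local_seed(config$seed + 1000L, function() {
    noise <- matrix(rnorm(length(vals), sd = config$expression_noise_sd),
                    nrow = nrow(vals))
    pmax(config$expression_baseline + config$expression_slope * vals + noise,
         0)
  })
  out <- tibble::as_tibble(as.data.frame(expr))
  names(out) <- matrix_samples(cnv)
  out <- dplyr::bind_cols(tibble::tibble(symbol = cnv$symbol), out)
  gene_matrix(out, "expression")
}

#' Generate and write a full synthetic cohort to disk
#'
#' Runs the whole generator and writes the file dialects the readers
#' consume: a SEG file, annotation and layout tables, the expression matrix,
#' the sample-group table and the alteration truth record.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths plus the in-memory
#'   objects (`segments`, `annotation`, `layout`, `cnv`, `expression`,
#'   `truth`, `groups`).
#' @export
simulate_cohort <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gen <- generate_segments(config)
  cnv <- map_segments_to_genes(gen$segments, gen$annotation)
  expr <- generate_expression(config, cnv)
  groups <- tibble::tibble(
    sample = sim_sample_ids(config),
    group = rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal)))

  paths <- list(
    segments = file.path(dir, "cohort.seg.txt"),
    annotation = file.path(dir, "annotation.tsv"),
    layout = file.path(dir, "layout.tsv"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_seg_file(gen$segments, paths$segments)
  readr::write_tsv(gen$annotation, paths$annotation)
  readr::write_tsv(gen$layout[c("chromosome", "centromere_start",
                                "centromere_end", "length")], paths$layout)
  write_gene_matrix(expr, paths$expression)
  readr::write_tsv(groups, paths$groups)
  readr::write_tsv(gen$truth, paths$truth)
  invisible(c(paths, list(segments_tbl = gen$segments,
                          annotation_tbl = gen$annotation,
                          layout_tbl = gen$layout, cnv = cnv,
                          expression_mat = expr, truth_tbl = gen$truth,
                          groups_tbl = groups)))
}
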