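#' Assign genes to chromosome arms
#'
#' The gap between a chromosome's two arms is its centromere: a gene wholly
#' left of `centromere_start` is on the p arm, wholly right of
#' `centromere_end` on the q arm. A gene overlapping the centromere goes to
#' the arm holding the larger share of its body (bases left of the
#' centromere vs bases right of it, 1-based closed arithmetic); ties go to
#' p. Genes on chromosomes absent from the layout raise an error.
#'
#' @param annotation gene annotation tibble (`symbol`, `chromosome`,
#'   `start`, `end`).
#' @param layout genome layout tibble from [read_genome_layout()].
#' @return a tibble `symbol`, `chromosome`, `arm` (`"p"`/`"q"`).
#' @export
assign_arms <- function(annotation, layout) {
  annotation <- validate_annotation(annotation)
  unknown <- setdiff(unique(annotation$chromosome), layout$chromosome)
  if (length(unknown)) {
    stop_mcv(paste0("chromosome not in layout: ", unknown[1]), "validation_error")
  }
  joined <- dplyr::left_join(
    annotation,
    layout[c("chromosome", "centromere_start", "centromere_end")],
    by = "chromosome"
  )
  # bases of the gene body on each side of the centromere (closed intervals)
  left_bases <- pmax(0, pmin(joined$end, joined$centromere_start - 1) -
                          joined$start + 1)
  right_bases <- pmax(0, joined$end -
                           pmax(joined$start, joined$centromere_end + 1) + 1)
  tibble::tibble(
    symbol = joined$symbol,
    chromosome = joined$chromosome,
    arm = ifelse(left_bases >= right_bases, "p", "q")
  )
}

#' Map copy-number segments onto genes
#'
#' For each gene and sample, the gene-level CNV is the unweighted arithmetic
#' mean of `segment_mean` over every segment of that sample on the gene's
#' chromosome that intersects the gene interval — partial overlap counts, any
#' nonzero number of shared bases (1-based closed intervals). Genes with no
#' intersecting segment in a sample get `NA`. Segments of one sample on one
#' chromosome may abut but not overlap.
#'
#' @param segments segment tibble from [read_seg_file()].
#' @param annotation gene annotation tibble.
#' @param weighted if `TRUE`, weight each segment's mean by the number of
#'   bases it shares with the gene instead of the default unweighted mean.
#' @return a `gene_matrix` (`value_kind = "cnv"`) with one column per sample
#'   present in `segments`, genes in annotation order.
#' @export
map_segments_to_genes <- function(segments, annotation, weighted = FALSE) {
  annotation <- validate_annotation(annotation)
  validate_segments(segments)
  segments <- dplyr::mutate(segments,
                            chromosome = normalize_chromosome(.data$chromosome))
  check_segment_overlaps(segments)

  genes <- dplyr::mutate(annotation, gene_start = .data$start,
                         gene_end = .data$end, start = NULL, end = NULL)
  hits <- dplyr::inner_join(
    genes, segments,
    by = dplyr::join_by("chromosome",
                        overlaps("gene_start", "gene_end", "start", "end",
                                 bounds = "[]"))
  )
  if (nrow(hits)) {
    hits <- dplyr::mutate(
      hits,
      w = if (weighted) {
        pmin(.data$gene_end, .data$end) - pmax(.data$gene_start, .data$start) + 1
      } else 1
    )
    cells <- dplyr::summarise(
      dplyr::group_by(hits, .data$symbol, .data$sample),
      value = sum(.data$segment_mean * .data$w) / sum(.data$w),
      .groups = "drop"
    )
    wide <- tidyr::pivot_wider(cells, names_from = "sample",
                               values_from = "value")
  } else {
    wide <- tibble::tibble(symbol = character())
  }
  # all annotated genes and all samples appear, even when fully uncovered
  all_samples <- unique(segments$sample)
  out <- dplyr::left_join(annotation["symbol"], wide, by = "symbol")
  for (s in setdiff(all_samples, names(out))) out[[s]] <- NA_real_
  out <- out[c("symbol", all_samples)]
  gene_matrix(out, "cnv")
}

check_segment_overlaps <- function(segments) {
  bad <- segments |>
    dplyr::group_by(.data$sample, .data$chromosome) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter(dplyr::lead(.data$start) <= .data$end) |>
    dplyr::ungroup()
  if (nrow(bad)) {
    stop_mcv(paste0("overlapping segments in sample ", bad$sample[1],
                    " on chromosome ", bad$chromosome[1],
                    " near position ", bad$end[1]),
             "validation_error")
  }
  invisible(segments)
}

#' Restrict a gene matrix to autosomal genes
#'
#' Analysis is restricted to autosomes: only genes annotated on chromosomes
#' 1–22 are kept. Genes missing from the annotation are dropped with a
#' warning.
#'
#' @param x a `gene_matrix`.
#' @param annotation gene annotation tibble covering the rows of `x`.
#' @return a `gene_matrix` with sex-chromosome and unannotated genes removed.
#' @export
restrict_autosomes <- function(x, annotation) {
  annotation <- validate_annotation(annotation)
  unannotated <- setdiff(x$symbol, annotation$symbol)
  if (length(unannotated)) {
    warn(paste0(length(unannotated),
                " gene(s) without annotation dropped: ",
                paste(head(unannotated, 3), collapse = ", ")))
  }
  keep_syms <- annotation$symbol[is_autosome(annotation$chromosome)]
  new_gene_matrix(x[x$symbol %in% keep_syms, , drop = FALSE], value_kind(x))
}
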