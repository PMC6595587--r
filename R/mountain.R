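#' Per-gene group summary of a gene matrix
#'
#' Summarizes a group of samples gene-by-gene with the median (default) or
#' mean over non-missing values. The median is the default because it is
#' robust to the extreme single-sample amplifications common in copy-number
#' data; the mean is available for comparison. Genes with no non-missing
#' value in the group are dropped with a warning.
#'
#' @param x a `gene_matrix`.
#' @param sample_ids samples forming the group (subset of `matrix_samples(x)`).
#' @param summary_kind `"median"` or `"mean"`.
#' @return a tibble `symbol`, `value`.
#' @export
summarize_group <- function(x, sample_ids = matrix_samples(x),
                            summary_kind = c("median", "mean")) {
  summary_kind <- match.arg(summary_kind)
  if (!length(sample_ids)) stop_mcv("empty sample set", "validation_error")
  missing_ids <- setdiff(sample_ids, matrix_samples(x))
  if (length(missing_ids)) {
    stop_mcv(paste0("sample not in matrix: ", missing_ids[1]), "validation_error")
  }
  vals <- gm_values(x, sample_ids)
  fn <- if (summary_kind == "median") {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  value <- apply(vals, 1, fn)
  out <- tibble::tibble(symbol = x$symbol, value = unname(value))
  dropped <- out$symbol[!is.finite(out$value)]
  if (length(dropped)) {
    warn(paste0(length(dropped), " gene(s) with no observed value dropped"))
    out <- out[is.finite(out$value), , drop = FALSE]
  }
  out
}

#' Build the Mountain curve of one chromosome arm
#'
#' A Mountain curve is the ordered per-gene summary track of one arm for one
#' sample group: genes sorted by genomic start position (ties broken by
#' symbol), each carrying the group median or mean of its gene-level value.
#' The p arms of the acrocentric chromosomes (13, 14, 15, 21, 22) carry no
#' profiled genes and yield an empty curve with a warning unless
#' `allow_acrocentric_p = TRUE`.
#'
#' @param summary_tbl tibble `symbol`, `value` from [summarize_group()].
#' @param annotation gene annotation tibble.
#' @param layout genome layout tibble.
#' @param chromosome,arm which arm to build (`arm` is `"p"` or `"q"`).
#' @param group_label free-text label of the sample group.
#' @param summary_kind tag recorded on the curve.
#' @param n_samples group size recorded on the curve.
#' @param allow_acrocentric_p include genes on acrocentric p arms when the
#'   annotation provides them.
#' @return a `mountain_curve` tibble: `chromosome`, `arm`, `symbol`,
#'   `start`, `value`, with attributes `summary_kind`, `group_label`,
#'   `n_samples`.
#' @export
build_arm_curve <- function(summary_tbl, annotation, layout, chromosome, arm,
                            group_label = "group",
                            summary_kind = "median", n_samples = NA_integer_,
                            allow_acrocentric_p = FALSE) {
  chromosome <- normalize_chromosome(chromosome)
  if (!arm %in% c("p", "q")) {
    stop_mcv(paste0("unknown arm label: ", arm), "validation_error")
  }
  if (!chromosome %in% layout$chromosome) {
    stop_mcv(paste0("unknown chromosome: ", chromosome), "validation_error")
  }
  acro <- layout$acrocentric[match(chromosome, layout$chromosome)]
  if (arm == "p" && acro && !allow_acrocentric_p) {
    warn(paste0("chromosome ", chromosome,
                " is acrocentric; its p arm carries no profiled genes"))
    return(new_mountain_curve(
      tibble::tibble(chromosome = character(), arm = character(),
                     symbol = character(), start = double(), value = double()),
      summary_kind, group_label, n_samples))
  }
  arms <- assign_arms(annotation, layout)
  genes <- annotation |>
    dplyr::inner_join(arms, by = c("symbol", "chromosome")) |>
    dplyr::filter(.data$chromosome == .env$chromosome, .data$arm == .env$arm) |>
    dplyr::inner_join(summary_tbl, by = "symbol") |>
    dplyr::arrange(.data$start, .data$symbol)
  new_mountain_curve(
    tibble::tibble(chromosome = genes$chromosome, arm = genes$arm,
                   symbol = genes$symbol, start = genes$start,
                   value = genes$value),
    summary_kind, group_label, n_samples)
}

new_mountain_curve <- function(tbl, summary_kind, group_label, n_samples) {
  structure(tibble::as_tibble(tbl),
            summary_kind = summary_kind,
            group_label = group_label,
            n_samples = n_samples,
            class = c("mountain_curve", class(tibble::tibble())))
}

#' Build Mountain curves for the whole autosomal genome
#'
#' Builds the 44 arm slots 1p, 1q, ..., 22p, 22q in chromosome-then-arm
#' order for one sample group. Acrocentric p slots (13p, 14p, 15p, 21p, 22p)
#' are empty by default, so a fully covered genome yields 39 non-empty
#' curves. Chromosomes absent from the annotation yield empty slots.
#'
#' @inheritParams build_arm_curve
#' @param x a `gene_matrix`.
#' @param sample_ids group sample ids.
#' @return a nested tibble with one row per arm slot: `chromosome`, `arm`,
#'   `n_genes`, `curve` (list column of `mountain_curve` tibbles).
#' @export
build_genome_curves <- function(x, annotation, layout,
                                sample_ids = matrix_samples(x),
                                group_label = "group",
                                summary_kind = c("median", "mean"),
                                allow_acrocentric_p = FALSE) {
  summary_kind <- match.arg(summary_kind)
  smry <- summarize_group(x, sample_ids, summary_kind)
  if (!nrow(smry)) warn("no genes with observed values; all curves empty")
  slots <- arm_slots()
  slots$curve <- purrr::map2(slots$chromosome, slots$arm, function(chrom, arm) {
    if (!chrom %in% layout$chromosome ||
        !any(annotation$chromosome == chrom)) {
      return(new_mountain_curve(
        tibble::tibble(chromosome = character(), arm = character(),
                       symbol = character(), start = double(),
                       value = double()),
        summary_kind, group_label, length(sample_ids)))
    }
    suppressWarnings(build_arm_curve(
      smry, annotation, layout, chrom, arm,
      group_label = group_label, summary_kind = summary_kind,
      n_samples = length(sample_ids),
      allow_acrocentric_p = allow_acrocentric_p))
  })
  slots$n_genes <- vapply(slots$curve, nrow, integer(1))
  slots[c("chromosome", "arm", "n_genes", "curve")]
}

#' Serialize Mountain curves
#'
#' Tab-separated `chromosome`, `arm`, `symbol`, `start`, `value` — the
#' layout consumed by the plotting and similarity tools.
#'
#' @param curves a `mountain_curve` or the nested tibble from
#'   [build_genome_curves()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  flat <- flatten_curves(curves)
  readr::write_tsv(flat, path, na = "NA")
  invisible(path)
}

flatten_curves <- function(curves) {
  if (inherits(curves, "mountain_curve")) return(tibble::as_tibble(curves))
  dplyr::bind_rows(purrr::map(curves$curve, tibble::as_tibble))
}
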