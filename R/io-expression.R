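#' Read per-sample normalized expression files into a gene matrix
#'
#' Each file is the two-column `*.rsem.genes.normalized_results` dialect:
#' one header line, then `gene_id<TAB>normalized_count`. Gene identifiers of
#' the form `"SYMBOL|entrez"` are truncated at the first `"|"`; rows whose
#' symbol is `"?"` are dropped. The matrix is the union of genes across
#' files; a gene absent from some sample gets `NA` there.
#'
#' @param paths character vector of file paths.
#' @param sample_ids parallel vector of sample ids (must be unique).
#' @return a `gene_matrix` with `value_kind = "expression"`.
#' @export
read_expression_files <- function(paths, sample_ids) {
  if (length(paths) != length(sample_ids)) {
    stop_mcv("paths and sample_ids must have the same length", "validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_mcv("duplicate sample id in sample_ids", "validation_error")
  }
  cols <- purrr::map2(paths, sample_ids, function(path, id) {
    tbl <- readr::read_tsv(path, col_names = c("gene_id", "value"), skip = 1,
                           col_types = readr::cols(
                             gene_id = readr::col_character(),
                             value = readr::col_double()
                           ), progress = FALSE)
    tbl$symbol <- sub("\\|.*$", "", tbl$gene_id)
    tbl <- tbl[tbl$symbol != "?", c("symbol", "value")]
    if (any(tbl$value < 0, na.rm = TRUE) || any(!is.finite(tbl$value))) {
      stop_mcv(paste0("negative or non-finite expression value in ", path),
               "validation_error")
    }
    if (anyDuplicated(tbl$symbol)) {
      stop_mcv(paste0("duplicate gene symbol after truncation in ", path),
               "validation_error")
    }
    names(tbl)[2] <- id
    tbl
  })
  merged <- purrr::reduce(cols, dplyr::full_join, by = "symbol")
  gene_matrix(merged, "expression")
}
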