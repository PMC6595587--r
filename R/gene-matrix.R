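#' Gene-by-sample value tables
#'
#' Throughout the package a gene-level matrix (copy number or expression) is
#' carried as a tibble whose first column is `symbol` (HUGO gene symbol, the
#' unique row key) and whose remaining columns are one numeric column per
#' sample. The tibble carries a `value_kind` attribute, `"cnv"` or
#' `"expression"`, so downstream statistics can pick ratio- vs
#' difference-based effect sizes. Missing values (`NA`) mean the gene was not
#' measured/covered in that sample and are excluded pairwise downstream.
#'
#' @param data a data frame with a `symbol` column and numeric sample columns.
#' @param value_kind `"cnv"` or `"expression"`.
#' @return a `gene_matrix` tibble.
#' @export
#' @examples
#' gene_matrix(data.frame(symbol = c("A", "B"), S1 = c(0.1, -0.2)), "cnv")
gene_matrix <- function(data, value_kind = c("cnv", "expression")) {
  value_kind <- match.arg(value_kind)
  data <- tibble::as_tibble(data)
  if (!"symbol" %in% names(data)) {
    stop_mcv("a gene matrix needs a `symbol` column", "format_error")
  }
  data <- dplyr::relocate(data, "symbol")
  if (anyDuplicated(data$symbol)) {
    dup <- unique(data$symbol[duplicated(data$symbol)])
    stop_mcv(paste0("duplicate gene symbols: ", paste(head(dup, 5), collapse = ", ")),
             "validation_error")
  }
  if (anyDuplicated(names(data))) {
    stop_mcv("duplicate sample ids in gene matrix", "validation_error")
  }
  vals <- as.matrix(data[-1])
  if (length(vals) && any(!is.finite(vals) & !is.na(vals))) {
    stop_mcv("gene matrix values must be finite or NA", "validation_error")
  }
  new_gene_matrix(data, value_kind)
}

new_gene_matrix <- function(data, value_kind) {
  structure(tibble::as_tibble(data),
            value_kind = value_kind,
            class = c("gene_matrix", class(tibble::tibble())))
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat("<gene_matrix> kind:", attr(x, "value_kind"),
      "|", nrow(x), "genes x", ncol(x) - 1L, "samples\n")
  NextMethod()
}

#' Sample ids of a gene matrix
#' @param x a `gene_matrix`.
#' @return character vector of sample ids (column names minus `symbol`).
#' @export
matrix_samples <- function(x) setdiff(names(x), "symbol")

#' Kind of values stored in a gene matrix
#' @param x a `gene_matrix`.
#' @return `"cnv"` or `"expression"`.
#' @export
value_kind <- function(x) attr(x, "value_kind") %||% "cnv"

# base-matrix view, rownames = symbols; used by summary/bootstrap internals
gm_values <- function(x, samples = matrix_samples(x)) {
  m <- as.matrix(x[samples])
  storage.mode(m) <- "double"
  rownames(m) <- x$symbol
  m
}

#' Write / read a gene matrix as tab-separated text
#'
#' Serialization is genes x samples with a one-line header and `NA` for
#' missing values, the layout the rest of the toolkit consumes.
#'
#' @param x a `gene_matrix`.
#' @param path output/input file path.
#' @param value_kind kind tag to attach on read.
#' @return `write_gene_matrix` returns `path` invisibly; `read_gene_matrix`
#'   returns a `gene_matrix`.
#' @export
write_gene_matrix <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path, na = "NA")
  invisible(path)
}

#' @rdname write_gene_matrix
#' @export
read_gene_matrix <- function(path, value_kind = c("cnv", "expression")) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    symbol = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  gene_matrix(tbl, match.arg(value_kind))
}
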