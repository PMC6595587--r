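#' Read a gene annotation table
#'
#' Four-column tab-separated table with header: `symbol`, `chromosome`,
#' `start`, `end` (1-based closed coordinates; convert BED half-open
#' intervals before calling). Gene symbols must be unique HUGO symbols.
#'
#' @param path path to the annotation file.
#' @return a tibble with columns `symbol`, `chromosome`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    symbol = readr::col_character(),
    chromosome = readr::col_character(),
    start = readr::col_double(),
    end = readr::col_double()
  ), progress = FALSE)
  validate_annotation(tbl)
}

#' Validate a gene annotation table
#'
#' @param tbl a data frame with columns `symbol`, `chromosome`, `start`, `end`.
#' @return the validated tibble (chromosome labels normalized), invisibly
#'   usable in a pipe.
#' @export
validate_annotation <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("symbol", "chromosome", "start", "end")
  if (!all(need %in% names(tbl))) {
    stop_mcv("annotation needs columns symbol/chromosome/start/end", "format_error")
  }
  tbl$chromosome <- normalize_chromosome(tbl$chromosome)
  if (any(!nzchar(tbl$symbol)) || anyNA(tbl$symbol)) {
    stop_mcv("empty gene symbol in annotation", "validation_error")
  }
  if (anyDuplicated(tbl$symbol)) {
    dup <- tbl$symbol[duplicated(tbl$symbol)][1]
    stop_mcv(paste0("duplicate gene symbol in annotation: ", dup),
             "validation_error")
  }
  bad <- which(!(tbl$start < tbl$end))
  if (length(bad)) {
    stop_mcv(paste0("annotation record with start >= end: ", tbl$symbol[bad[1]]),
             "validation_error")
  }
  tbl[need]
}

#' Read a genome layout (centromere) table
#'
#' Tab-separated with header: `chromosome`, `centromere_start`,
#' `centromere_end`, `length` (1-based closed). Chromosomes 13, 14, 15, 21
#' and 22 are flagged acrocentric: their p arms carry no profiled genes.
#'
#' @param path path to the layout file.
#' @return a tibble with columns `chromosome`, `centromere_start`,
#'   `centromere_end`, `length`, `acrocentric`.
#' @export
read_genome_layout <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    chromosome = readr::col_character(),
    centromere_start = readr::col_double(),
    centromere_end = readr::col_double(),
    length = readr::col_double()
  ), progress = FALSE)
  validate_layout(tbl)
}

#' Validate a genome layout table
#' @inheritParams validate_annotation
#' @return validated layout tibble with an `acrocentric` flag column.
#' @export
validate_layout <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("chromosome", "centromere_start", "centromere_end", "length")
  if (!all(need %in% names(tbl))) {
    stop_mcv("layout needs columns chromosome/centromere_start/centromere_end/length",
             "format_error")
  }
  tbl$chromosome <- normalize_chromosome(tbl$chromosome)
  if (anyDuplicated(tbl$chromosome)) {
    stop_mcv("duplicate chromosome in layout", "validation_error")
  }
  ok <- tbl$centromere_start > 0 &
    tbl$centromere_start < tbl$centromere_end &
    tbl$centromere_end < tbl$length
  if (any(!ok)) {
    stop_mcv(paste0("invalid centromere interval for chromosome ",
                    tbl$chromosome[which(!ok)[1]],
                    " (need 0 < centromere_start < centromere_end < length)"),
             "validation_error")
  }
  tbl$acrocentric <- tbl$chromosome %in% acrocentric_labels()
  tbl[c(need, "acrocentric")]
}
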