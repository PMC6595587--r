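#' Parse TCGA-style sample barcodes
#'
#' A barcode like `TCGA-06-0187-01` has at least four dash-separated fields;
#' the fourth starts with a two-digit sample-type code. Code `"01"` is a
#' primary tumor; codes `"10"`–`"14"` are nonmalignant controls
#' (solid-tissue / blood normals); codes `"02"`–`"09"` are other tumor
#' samples, excluded by the primary filter.
#'
#' @param barcode character vector of barcodes.
#' @return a tibble with columns `full_barcode`, `participant_id` (first
#'   three fields), `sample_type_code`, `is_primary_tumor`,
#'   `is_nonmalignant`.
#' @export
#' @examples
#' parse_barcode(c("TCGA-06-0187-01", "TCGA-AA-0001-11"))
parse_barcode <- function(barcode) {
  parts <- strsplit(barcode, "-", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 4)) {
    stop_mcv(paste0("not a TCGA-style barcode (need >= 4 dash-separated fields): ",
                    barcode[which(nfield < 4)[1]]), "parse_error")
  }
  code <- vapply(parts, function(p) substr(p[4], 1, 2), character(1))
  if (any(!grepl("^[0-9]{2}$", code))) {
    stop_mcv(paste0("sample-type field must start with a two-digit code: ",
                    barcode[which(!grepl("^[0-9]{2}$", code))[1]]), "parse_error")
  }
  tibble::tibble(
    full_barcode = barcode,
    participant_id = vapply(parts, function(p) paste(p[1:3], collapse = "-"),
                            character(1)),
    sample_type_code = code,
    is_primary_tumor = code == "01",
    is_nonmalignant = code %in% c("10", "11", "12", "13", "14")
  )
}

sample_class <- function(barcode) {
  info <- parse_barcode(barcode)
  dplyr::case_when(
    info$is_primary_tumor ~ "primary",
    info$is_nonmalignant ~ "nonmalignant",
    .default = "other"
  )
}

#' Keep only samples of one class
#'
#' Non-primary samples are removed before any analysis; this filter applies
#' that rule (or selects the nonmalignant controls) to a segment table or a
#' gene matrix. Sample classes come from TCGA barcodes unless an explicit
#' `class_map` is given. Order is preserved and the filter is idempotent.
#'
#' @param x a segment tibble (with a `sample` column) or a `gene_matrix`.
#' @param keep `"primary"`, `"nonmalignant"` or `"other"`.
#' @param class_map optional named character vector sample id -> class,
#'   bypassing barcode parsing.
#' @return same type as `x`, restricted to the requested samples; an empty
#'   result carries a warning rather than an error.
#' @export
filter_samples <- function(x, keep = c("primary", "nonmalignant", "other"),
                           class_map = NULL) {
  keep <- match.arg(keep)
  classify <- function(ids) {
    if (!is.null(class_map)) {
      cls <- unname(class_map[ids])
      if (anyNA(cls)) {
        stop_mcv("class_map is missing some sample ids", "validation_error")
      }
      cls
    } else {
      sample_class(ids)
    }
  }
  if (inherits(x, "gene_matrix")) {
    ids <- matrix_samples(x)
    hit <- ids[classify(ids) == keep]
    if (!length(hit)) {
      warn(paste0("no samples of class '", keep, "' remain"))
    }
    new_gene_matrix(x[c("symbol", hit)], value_kind(x))
  } else {
    out <- x[classify(x$sample) == keep, , drop = FALSE]
    if (!nrow(out)) warn(paste0("no samples of class '", keep, "' remain"))
    tibble::as_tibble(out)
  }
}
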