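# shared internal helpers

#' Normalize chromosome labels
#'
#' Strips a case-insensitive `"chr"` prefix so `"chr7"` and `"7"` map to the
#' same key. Labels are returned as character (`"1"`..`"22"`, `"X"`, `"Y"`).
#'
#' @param x character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
#' @examples
#' normalize_chromosome(c("chr7", "7", "CHRX"))
normalize_chromosome <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

autosome_labels <- function() as.character(1:22)

acrocentric_labels <- function() c("13", "14", "15", "21", "22")

is_autosome <- function(chrom) normalize_chromosome(chrom) %in% autosome_labels()

# chromosome-then-arm ordering used for genome-wide arm slots (1p, 1q, ..., 22q)
arm_slots <- function(chromosomes = autosome_labels()) {
  tidyr::expand_grid(chromosome = chromosomes, arm = c("p", "q"))
}

# order chromosomes numerically when possible, X/Y after
chromosome_rank <- function(chrom) {
  chrom <- normalize_chromosome(chrom)
  r <- suppressWarnings(as.numeric(chrom))
  r[chrom == "X"] <- 23
  r[chrom == "Y"] <- 24
  r[is.na(r)] <- 25
  r
}

stop_mcv <- function(msg, class) {
  rlang::abort(msg, class = paste0("mountaincnv_", class))
}
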