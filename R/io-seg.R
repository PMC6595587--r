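#' Read a segmented copy-number (SEG) file
#'
#' Reads tab-separated level-3 style segment files
#' (`*.hg19.seg.txt`: Sample / Chromosome / Start / End / Num_Probes /
#' Segment_Mean; `Num_Probes` optional; header match is case-insensitive).
#' Chromosome labels are normalized by stripping a leading `"chr"`; row order
#' is preserved. Coordinates are 1-based, fully closed intervals (the TCGA
#' seg convention), and every overlap computation downstream uses that
#' convention.
#'
#' @param path path to a tab-separated SEG file with a header line.
#' @return a tibble with columns `sample`, `chromosome`, `start`, `end`,
#'   `num_probes` (NA when the column is absent), `segment_mean`.
#' @export
#' @examples
#' seg <- tempfile(fileext = ".seg.txt")
#' writeLines(c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
#'              "S1\t1\t100\t200\t5\t0.42"), seg)
#' read_seg_file(seg)
read_seg_file <- function(path) {
  if (!file.exists(path)) {
    stop_mcv(paste0("file not found: ", path), "io_error")
  }
  lines <- readr::read_lines(path)
  # tolerate trailing blank lines / Windows line endings
  lines <- sub("\r$", "", lines)
  while (length(lines) && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (!length(lines)) stop_mcv("empty SEG file (no header)", "format_error")

  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  key <- tolower(trimws(header))
  required <- c(sample = "sample", chromosome = "chromosome",
                start = "start", end = "end", segment_mean = "segment_mean")
  idx <- match(required, key)
  if (anyNA(idx)) {
    missing_col <- names(required)[is.na(idx)][1]
    stop_mcv(paste0("SEG file is missing required column: ", missing_col),
             "format_error")
  }
  probe_idx <- match("num_probes", key)

  parse_num <- function(txt, column, line_no) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & !(txt %in% c("NA", "")))
    if (length(bad)) {
      stop_mcv(paste0("non-numeric ", column, " value '", txt[bad[1]],
                      "' on line ", line_no[bad[1]]),
               "parse_error")
    }
    out
  }

  body <- lines[-1]
  if (!length(body)) {
    return(tibble::tibble(sample = character(), chromosome = character(),
                          start = double(), end = double(),
                          num_probes = double(), segment_mean = double()))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < max(idx))) {
    stop_mcv(paste0("too few fields on line ", which(nfield < max(idx))[1] + 1L),
             "parse_error")
  }
  pick <- function(i) vapply(fields, function(f) trimws(f[i]), character(1))
  line_no <- seq_along(body) + 1L

  out <- tibble::tibble(
    sample = pick(idx[1]),
    chromosome = normalize_chromosome(pick(idx[2])),
    start = parse_num(pick(idx[3]), "Start", line_no),
    end = parse_num(pick(idx[4]), "End", line_no),
    num_probes = if (is.na(probe_idx)) NA_real_
                 else parse_num(pick(probe_idx), "Num_Probes", line_no),
    segment_mean = parse_num(pick(idx[5]), "Segment_Mean", line_no)
  )
  validate_segments(out)
  out
}

validate_segments <- function(seg) {
  bad <- which(!(seg$start < seg$end) | seg$start < 0)
  if (length(bad)) {
    stop_mcv(paste0("invalid segment interval (need 0 <= start < end) on data row ",
                    bad[1]), "validation_error")
  }
  if (any(!is.finite(seg$segment_mean))) {
    stop_mcv("segment_mean must be finite", "validation_error")
  }
  invisible(seg)
}

#' Write a segment table as a SEG file
#'
#' @param seg a segment tibble as returned by [read_seg_file()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_seg_file <- function(seg, path) {
  out <- tibble::tibble(
    Sample = seg$sample, Chromosome = seg$chromosome,
    Start = seg$start, End = seg$end,
    Num_Probes = seg$num_probes, Segment_Mean = seg$segment_mean
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}
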