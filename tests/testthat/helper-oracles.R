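# Independent brute-force oracles, kept free of the implementation paths
# they check.

# minimum accumulated cost over ALL monotone warping paths, by recursion
# from (n, m); feasible for short sequences only
dtw_enumerate <- function(x, y, cost = c("absolute", "squared")) {
  cost <- match.arg(cost)
  d <- function(i, j) {
    v <- abs(x[i] - y[j])
    if (cost == "squared") v^2 else v
  }
  rec <- function(i, j) {
    if (i == 1 && j == 1) return(d(1, 1))
    best <- Inf
    if (i > 1) best <- min(best, rec(i - 1, j))
    if (j > 1) best <- min(best, rec(i, j - 1))
    if (i > 1 && j > 1) best <- min(best, rec(i - 1, j - 1))
    d(i, j) + best
  }
  rec(length(x), length(y))
}

# Benjamini-Hochberg step-up by the literal definition:
# q_(i) = min_{j >= i} p_(j) * n / j on sorted p, capped at 1
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  q_sorted <- vapply(seq_len(n), function(i) {
    min(1, min(p_sorted[i:n] * n / (i:n)))
  }, double(1))
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# gene-level CNV by a direct O(genes x segments) scan (1-based closed)
map_brute <- function(segments, annotation) {
  samples <- unique(segments$sample)
  out <- matrix(NA_real_, nrow(annotation), length(samples),
                dimnames = list(annotation$symbol, samples))
  for (g in seq_len(nrow(annotation))) {
    for (s in samples) {
      hit <- segments$sample == s &
        segments$chromosome == annotation$chromosome[g] &
        segments$start <= annotation$end[g] &
        segments$end >= annotation$start[g]
      if (any(hit)) out[g, s] <- mean(segments$segment_mean[hit])
    }
  }
  out
}

# arm call by counting individual bases of the gene body on each side
arm_brute <- function(start, end, cen_start, cen_end) {
  bases <- start:end
  left <- sum(bases < cen_start)
  right <- sum(bases > cen_end)
  if (left >= right) "p" else "q"
}

# tiny deterministic annotation/layout pair used across tests
toy_genome <- function() {
  annotation <- tibble::tibble(
    symbol = c("A1", "A2", "B1", "B2", "X1"),
    chromosome = c("1", "1", "2", "2", "X"),
    start = c(100, 3000, 150, 2900, 500),
    end = c(500, 3600, 600, 3400, 900))
  layout <- tibble::tibble(
    chromosome = c("1", "2", "X"),
    centromere_start = 1000, centromere_end = 2000, length = 4000)
  list(annotation = mountaincnv::validate_annotation(annotation),
       layout = mountaincnv::validate_layout(layout))
}

toy_seg_lines <- function() {
  c("Sample\tChromosome\tStart\tEnd\tNum_Probes\tSegment_Mean",
    "TCGA-01-0001-01\t1\t1\t1500\t10\t0.5",
    "TCGA-01-0001-01\t1\t1501\t4000\t12\t0.3",
    "TCGA-01-0001-01\tchr2\t1\t4000\t20\t-0.2",
    "TCGA-01-0002-11\t1\t1\t4000\t22\t0.0",
    "TCGA-01-0002-11\t2\t1\t4000\t20\t0.1")
}

random_segments <- function(n_seg, chroms = c("1", "2"), samples = c("S-01", "S-02")) {
  rows <- lapply(seq_len(n_seg), function(i) {
    len <- sample(50:500, 1)
    start <- sample(1:2000, 1)
    tibble::tibble(sample = sample(samples, 1),
                   chromosome = sample(chroms, 1),
                   start = start, end = start + len,
                   num_probes = 5, segment_mean = round(rnorm(1), 3))
  })
  seg <- dplyr::bind_rows(rows)
  # drop within-sample overlaps so the non-overlap precondition holds
  seg <- seg[order(seg$sample, seg$chromosome, seg$start), ]
  keep <- rep(TRUE, nrow(seg))
  last_end <- list()
  for (i in seq_len(nrow(seg))) {
    key <- paste(seg$sample[i], seg$chromosome[i])
    if (!is.null(last_end[[key]]) && seg$start[i] <= last_end[[key]]) {
      keep[i] <- FALSE
    } else {
      last_end[[key]] <- seg$end[i]
    }
  }
  seg[keep, ]
}
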