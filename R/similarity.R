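#' Distance-based similarity scores of two aligned curves
#'
#' Three simple index-wise companions to the DTW score, for two equal-length
#' value vectors: the signed distance `sum(x - y)` (cancellation-prone but
#' direction-aware), the absolute distance `sum(|x - y|)`, and the squared
#' distance `sum((x - y)^2)`.
#'
#' @param x,y equal-length finite numeric vectors.
#' @return one-row tibble `signed_distance`, `absolute_distance`,
#'   `squared_distance`.
#' @export
#' @examples
#' distance_scores(c(1, 2), c(0, 1))
distance_scores <- function(x, y) {
  if (length(x) != length(y)) {
    stop_mcv("distance scores need equal-length sequences", "validation_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_mcv("distance scores need finite values", "validation_error")
  }
  d <- x - y
  tibble::tibble(signed_distance = sum(d),
                 absolute_distance = sum(abs(d)),
                 squared_distance = sum(d^2))
}

# intersect two curves to their common genes, in shared (position) order
common_curve_values <- function(curve_a, curve_b) {
  common <- dplyr::inner_join(
    tibble::as_tibble(curve_a), tibble::as_tibble(curve_b)[c("symbol", "value")],
    by = "symbol", suffix = c("_a", "_b"))
  common <- dplyr::arrange(common, .data$start, .data$symbol)
  common
}

#' Similarity of two Mountain curves on one chromosome arm
#'
#' Intersects the two curves to their common gene set (identical ordering by
#' genomic start), then computes the DTW alignment, the normalized
#' similarity score and the three distance-based scores on the aligned value
#' vectors. At least two common genes are required.
#'
#' @param curve_a,curve_b `mountain_curve` tibbles on the same chromosome arm.
#' @param cost,method passed to [dtw_align()] and [normalize_dtw()].
#' @return one-row tibble: `chromosome`, `arm`, `n_genes`, `dtw_raw`,
#'   `dtw_score`, `signed_distance`, `absolute_distance`, `squared_distance`.
#' @export
arm_similarity <- function(curve_a, curve_b,
                           cost = c("absolute", "squared"),
                           method = c("rational", "exponential")) {
  if (nrow(curve_a) && nrow(curve_b)) {
    same_arm <- identical(unique(curve_a$chromosome), unique(curve_b$chromosome)) &&
      identical(unique(curve_a$arm), unique(curve_b$arm))
    if (!same_arm) {
      stop_mcv("curves are not on the same chromosome arm", "validation_error")
    }
  }
  common <- common_curve_values(curve_a, curve_b)
  if (nrow(common) < 2) {
    stop_mcv("fewer than 2 common genes between the curves", "validation_error")
  }
  a <- dtw_align(common$value_a, common$value_b, cost)
  dplyr::bind_cols(
    tibble::tibble(chromosome = common$chromosome[1], arm = common$arm[1],
                   n_genes = nrow(common),
                   dtw_raw = a$raw_distance,
                   dtw_score = normalize_dtw(a$raw_distance, a$path_length,
                                             method)),
    distance_scores(common$value_a, common$value_b))
}

#' Genome-wide DTW score
#'
#' Aggregates arm-level normalized DTW scores over the genome as their sum
#' across non-empty arms, alongside the number of arms entering the sum. On
#' a fully profiled autosomal genome 39 arms contribute (44 slots minus the
#' 5 acrocentric p arms), so two identical cohorts score 39.
#'
#' @param arm_results tibble of arm similarity rows with a `dtw_score`
#'   column (see [arm_similarity()]).
#' @return one-row tibble `genome_score`, `n_arms`.
#' @export
genome_wide_score <- function(arm_results) {
  if (!nrow(arm_results)) {
    stop_mcv("no arm results to aggregate", "validation_error")
  }
  tibble::tibble(genome_score = sum(arm_results$dtw_score),
                 n_arms = nrow(arm_results))
}

# run fn with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

group_curve <- function(vals, summary_kind) {
  if (summary_kind == "median") {
    row_medians_cpp(vals)
  } else {
    suppressWarnings(rowMeans(vals, na.rm = TRUE))
  }
}

#' Bootstrap significance test for the difference of two Mountain curves
#'
#' Tests whether the dissimilarity between the Mountain curves of two sample
#' groups could arise from random sampling fluctuation. The null model pools
#' the two groups' sample columns and draws, with replacement, two
#' pseudo-groups of the original sizes; both curves and their normalized DTW
#' score are rebuilt for each draw. Since a LOW score means a LARGE
#' difference, the lower tail is extreme, and the add-one p-value is
#' `p = (1 + #\{null score <= observed\}) / (n_boot + 1)`, with floor
#' `1 / (n_boot + 1)`.
#'
#' @param values_a,values_b numeric matrices (genes on one arm x samples;
#'   same genes in the same order) or `gene_matrix` objects restricted to
#'   the arm (intersected to common genes automatically).
#' @param n_boot number of bootstrap draws (>= 1).
#' @param seed optional integer seed; the test is deterministic under a
#'   fixed seed and does not disturb the caller's RNG state.
#' @param summary_kind `"median"` or `"mean"` group summary.
#' @param observed optionally, the precomputed observed score; computed from
#'   the inputs when `NULL`.
#' @param cost,method DTW options, see [dtw_align()] / [normalize_dtw()].
#' @return one-row tibble `observed_score`, `boot_p`, `n_boot`, `n_genes`.
#' @export
bootstrap_curve_test <- function(values_a, values_b, n_boot = 999, seed = NULL,
                                 summary_kind = c("median", "mean"),
                                 observed = NULL,
                                 cost = c("absolute", "squared"),
                                 method = c("rational", "exponential")) {
  summary_kind <- match.arg(summary_kind)
  cost <- match.arg(cost); method <- match.arg(method)
  if (n_boot < 1) stop_mcv("n_boot must be >= 1", "validation_error")
  if (inherits(values_a, "gene_matrix") && inherits(values_b, "gene_matrix")) {
    common <- intersect(values_a$symbol, values_b$symbol)
    values_a <- gm_values(values_a)[common, , drop = FALSE]
    values_b <- gm_values(values_b)[common, , drop = FALSE]
  }
  values_a <- as.matrix(values_a); values_b <- as.matrix(values_b)
  if (nrow(values_a) != nrow(values_b)) {
    stop_mcv("the two groups must cover the same genes", "validation_error")
  }
  n1 <- ncol(values_a); n2 <- ncol(values_b)
  if (n1 < 2 || n2 < 2) {
    stop_mcv("each group needs at least 2 samples", "validation_error")
  }

  score_of <- function(m1, m2) {
    c1 <- group_curve(m1, summary_kind)
    c2 <- group_curve(m2, summary_kind)
    keep <- is.finite(c1) & is.finite(c2)
    dtw_score(c1[keep], c2[keep], cost, method)
  }
  if (is.null(observed)) observed <- score_of(values_a, values_b)

  pooled <- cbind(values_a, values_b)
  n_pool <- n1 + n2
  null_scores <- with_local_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      ga <- pooled[, sample.int(n_pool, n1, replace = TRUE), drop = FALSE]
      gb <- pooled[, sample.int(n_pool, n2, replace = TRUE), drop = FALSE]
      score_of(ga, gb)
    }, double(1))
  })
  tibble::tibble(
    observed_score = observed,
    boot_p = (1 + sum(null_scores <= observed)) / (n_boot + 1),
    n_boot = as.integer(n_boot),
    n_genes = nrow(values_a))
}

#' Arm-wise similarity report between two sample groups
#'
#' The workhorse behind a Table-1-style report: builds both groups' genome
#' curves, scores every arm with at least two common genes, optionally runs
#' the bootstrap test per arm, and appends a genome-wide summary row whose
#' `dtw_score` is the sum of the arm scores.
#'
#' @param x a `gene_matrix` of CNV values.
#' @param annotation,layout gene annotation and genome layout tibbles.
#' @param group_a,group_b sample id vectors of the two groups.
#' @param summary_kind `"median"` (default) or `"mean"`.
#' @param n_boot bootstrap draws per arm; `0` skips the test.
#' @param seed integer seed driving all bootstrap draws.
#' @param cost,method DTW options.
#' @return a tibble with one row per scored arm (`chromosome`, `arm`,
#'   `n_genes`, `dtw_raw`, `dtw_score`, `signed_distance`,
#'   `absolute_distance`, `squared_distance`, `boot_p`, `n_boot`) plus a
#'   final `genome-wide` row carrying the summed score.
#' @export
similarity_report <- function(x, annotation, layout, group_a, group_b,
                              summary_kind = c("median", "mean"),
                              n_boot = 0, seed = NULL,
                              cost = c("absolute", "squared"),
                              method = c("rational", "exponential")) {
  summary_kind <- match.arg(summary_kind)
  cost <- match.arg(cost); method <- match.arg(method)
  curves_a <- suppressWarnings(build_genome_curves(
    x, annotation, layout, group_a, "group_a", summary_kind))
  curves_b <- suppressWarnings(build_genome_curves(
    x, annotation, layout, group_b, "group_b", summary_kind))

  annotation <- validate_annotation(annotation)
  arms <- assign_arms(annotation, layout)

  rows <- purrr::pmap(
    list(curves_a$chromosome, curves_a$arm, curves_a$curve, curves_b$curve,
         seq_len(nrow(curves_a))),
    function(chrom, arm, ca, cb, slot) {
      common <- intersect(ca$symbol, cb$symbol)
      if (length(common) < 2) return(NULL)
      res <- arm_similarity(ca, cb, cost, method)
      if (n_boot >= 1) {
        syms <- arms$symbol[arms$chromosome == chrom & arms$arm == arm]
        sub <- x[x$symbol %in% intersect(syms, common), , drop = FALSE]
        ord <- annotation[match(sub$symbol, annotation$symbol), ]
        sub <- sub[order(ord$start, ord$symbol), , drop = FALSE]
        bt <- bootstrap_curve_test(
          gm_values(sub, group_a), gm_values(sub, group_b),
          n_boot = n_boot,
          seed = if (is.null(seed)) NULL else (seed + slot) %% .Machine$integer.max,
          summary_kind = summary_kind, observed = res$dtw_score,
          cost = cost, method = method)
        res$boot_p <- bt$boot_p
      } else {
        res$boot_p <- NA_real_
      }
      res$n_boot <- as.integer(n_boot)
      res
    })
  arm_tbl <- dplyr::bind_rows(rows)
  if (!nrow(arm_tbl)) {
    stop_mcv("no arm had >= 2 common genes between the groups", "validation_error")
  }
  genome <- genome_wide_score(arm_tbl)
  dplyr::bind_rows(
    arm_tbl,
    tibble::tibble(chromosome = "genome-wide", arm = NA_character_,
                   n_genes = sum(arm_tbl$n_genes),
                   dtw_raw = NA_real_, dtw_score = genome$genome_score,
                   signed_distance = NA_real_, absolute_distance = NA_real_,
                   squared_distance = NA_real_,
                   boot_p = NA_real_, n_boot = as.integer(n_boot)))
}
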