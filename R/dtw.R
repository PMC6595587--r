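#' Dynamic time warping alignment of two value sequences
#'
#' Aligns two ordered value sequences (e.g. per-gene Mountain-curve values)
#' by the standard dynamic-programming recursion on accumulated pairwise
#' distances,
#' `D(i,j) = d(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` with
#' `D(1,1) = d(1,1)`, where the local cost is `d(i,j) = |x_i - y_j|`
#' (absolute difference; squared difference behind `cost = "squared"`).
#' The optimal monotone warping path from `(1,1)` to `(n,m)` is recovered by
#' backtracking from the upper-right corner; ties prefer the diagonal
#' predecessor, then the vertical one, which fixes the path deterministically.
#'
#' @param x,y numeric sequences, non-empty and finite.
#' @param cost local cost: `"absolute"` (default) or `"squared"`.
#' @return a `dtw_alignment` object: `raw_distance` (accumulated distance at
#'   `(n,m)`), `path` (tibble of aligned index pairs), `path_length` (K),
#'   `n`, `m`, `cost`.
#' @seealso [normalize_dtw()] for the bounded similarity score.
#' @export
#' @examples
#' dtw_align(c(1, 2, 3), c(2, 3, 4))$raw_distance
dtw_align <- function(x, y, cost = c("absolute", "squared")) {
  cost <- match.arg(cost)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop_mcv("DTW needs two non-empty sequences", "validation_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_mcv("DTW sequences must be finite", "validation_error")
  }
  res <- dtw_align_cpp(x, y, cost == "squared")
  structure(
    list(raw_distance = res$distance,
         path = tibble::tibble(index_x = res$index_x, index_y = res$index_y),
         path_length = length(res$index_x),
         n = length(x), m = length(y), cost = cost),
    class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("<dtw_alignment> ", x$n, " x ", x$m,
      " | raw distance ", format(x$raw_distance),
      " | path length ", x$path_length, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.dtw_alignment <- function(x, ...) x$path

#' @export
glance.dtw_alignment <- function(x, ...) {
  tibble::tibble(raw_distance = x$raw_distance,
                 path_length = x$path_length,
                 n = x$n, m = x$m, cost = x$cost,
                 score = normalize_dtw(x$raw_distance, x$path_length))
}

#' Normalize a DTW distance to a bounded similarity score
#'
#' The accumulated DTW distance is unbounded and grows with sequence length,
#' so it is mapped to a bounded per-path-step similarity:
#' `score = 1 / (1 + D / K)` with `K` the warping-path length. Identical
#' curves score exactly 1; the score decreases strictly with distance and
#' tends to 0 as curves diverge, and path-length scaling keeps arms of
#' different gene counts comparable. `method = "exponential"` selects
#' `exp(-D / K)` instead, which shares the endpoints.
#'
#' @param raw_distance non-negative accumulated distance.
#' @param path_length warping-path length K (>= 1).
#' @param method `"rational"` (default, `1/(1 + D/K)`) or `"exponential"`.
#' @return similarity score in `[0, 1]`.
#' @export
#' @examples
#' normalize_dtw(0, 10)   # identical curves -> 1
#' normalize_dtw(2, 4)    # 1 / (1 + 0.5)
normalize_dtw <- function(raw_distance, path_length,
                          method = c("rational", "exponential")) {
  method <- match.arg(method)
  if (any(raw_distance < 0)) {
    stop_mcv("raw_distance must be non-negative", "validation_error")
  }
  if (any(path_length < 1)) {
    stop_mcv("path_length must be >= 1", "validation_error")
  }
  if (method == "rational") 1 / (1 + raw_distance / path_length)
  else exp(-raw_distance / path_length)
}

#' Normalized DTW similarity of two sequences
#'
#' Convenience wrapper: [dtw_align()] followed by [normalize_dtw()].
#'
#' @inheritParams dtw_align
#' @inheritParams normalize_dtw
#' @return similarity score in `[0, 1]`.
#' @export
dtw_score <- function(x, y, cost = c("absolute", "squared"),
                      method = c("rational", "exponential")) {
  a <- dtw_align(x, y, cost)
  normalize_dtw(a$raw_distance, a$path_length, method)
}
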