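#' Deterministic bee-swarm point layout
#'
#' Computes lateral offsets that turn a one-dimensional value vector into a
#' closely packed, non-overlapping swarm (a stripchart whose points never
#' overlap). Points are processed in sorted value order; each takes the
#' smallest-magnitude lateral slot at which its planar distance to every
#' already placed point within one diameter vertically is at least one
#' diameter. Candidate slots are 0 and the tangency points against placed
#' neighbours; magnitude ties go to the positive side first, so the swarm
#' grows symmetrically around offset 0. The layout is fully deterministic.
#'
#' Both the value axis and the offset axis are measured in the same units as
#' `point_diameter`, so callers should pass values rescaled to plot
#' coordinates when aspect ratios matter.
#'
#' @param values finite numeric vector.
#' @param point_diameter point diameter (> 0) in value-axis units.
#' @return numeric vector of lateral offsets, parallel to `values`.
#' @export
#' @examples
#' beeswarm_layout(c(0, 10, 20), 1)      # no collisions, all 0
#' beeswarm_layout(rep(1, 5), 1)         # packed symmetric swarm
beeswarm_layout <- function(values, point_diameter = 1) {
  if (!length(values)) return(numeric(0))
  if (any(!is.finite(values))) {
    stop_mcv("bee-swarm values must be finite", "validation_error")
  }
  if (point_diameter <= 0) {
    stop_mcv("point_diameter must be > 0", "validation_error")
  }
  d <- point_diameter
  eps <- d * 1e-9
  ord <- order(values)
  off <- numeric(length(values))
  placed_v <- numeric(0)
  placed_o <- numeric(0)
  for (i in ord) {
    v <- values[i]
    near <- which(abs(placed_v - v) < d)
    if (!length(near)) {
      o <- 0
    } else {
      dv <- placed_v[near] - v
      # minimum lateral gap to each neighbour for a planar distance of d
      need <- sqrt(pmax(0, d^2 - dv^2))
      cand <- c(0, placed_o[near] + need, placed_o[near] - need)
      ok <- vapply(cand, function(cc) {
        all(abs(cc - placed_o[near]) >= need - eps)
      }, logical(1))
      cand <- cand[ok]
      # smallest |offset| wins; exact magnitude ties go positive
      cand <- cand[order(abs(cand), -sign(cand))]
      o <- cand[1]
    }
    off[i] <- o
    placed_v <- c(placed_v, v)
    placed_o <- c(placed_o, o)
  }
  off
}
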