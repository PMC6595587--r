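# Rendering is deliberately thin: every number in a figure comes from the
# stat tables computed elsewhere, so correctness is tested on tables and
# figures are only smoke-tested.

#' Plot Mountain curves
#'
#' Per-gene group summary values against genomic position, one panel per
#' chromosome. The gap between the two arms of a chromosome is the
#' centromere; no genes lie there, which produces the characteristic break.
#'
#' @param curves a `mountain_curve` or the nested tibble from
#'   [build_genome_curves()].
#' @return a ggplot object.
#' @export
plot_mountain <- function(curves) {
  flat <- flatten_curves(curves)
  if (!nrow(flat)) stop_mcv("no curve points to plot", "validation_error")
  flat$chromosome <- factor(flat$chromosome,
                            levels = unique(flat$chromosome[
                              order(chromosome_rank(flat$chromosome))]))
  ggplot2::ggplot(flat, ggplot2::aes(x = .data$start, y = .data$value,
                                     colour = .data$arm)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = "group summary CNV",
                  colour = "arm") +
    ggplot2::theme_minimal()
}

#' Plot per-gene Manhattan statistics
#'
#' Vertical lines of height `-log10(q)`; in directional mode lines carry the
#' sign of the group-median difference, dropping below the zero baseline
#' when group 1's median is the smaller one.
#'
#' @param stats tibble from [manhattan_stats()].
#' @param annotation optional annotation to order genes genomically; row
#'   order of `stats` is used otherwise.
#' @return a ggplot object.
#' @export
plot_manhattan <- function(stats, annotation = NULL) {
  if (!nrow(stats)) stop_mcv("no genes to plot", "validation_error")
  stats <- order_by_position(stats, annotation)
  stats$amplitude <- stats$direction * stats$neg_log10_q
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$position_index,
                                      xend = .data$position_index,
                                      y = 0, yend = .data$amplitude)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "gene (genomic order)", y = "signed -log10(Q)") +
    ggplot2::theme_minimal()
}

#' Plot per-gene Deflection statistics
#'
#' One line per gene whose amplitude is the signed `-log10(Q)` of the more
#' strongly deflected cancer type, coloured by which type wins.
#'
#' @param records tibble from [deflection_stats()].
#' @param annotation optional annotation for genomic ordering.
#' @return a ggplot object.
#' @export
plot_deflection <- function(records, annotation = NULL) {
  if (!nrow(records)) stop_mcv("no genes to plot", "validation_error")
  records <- order_by_position(records, annotation)
  records$amplitude <- ifelse(abs(records$amplitude_a) >= abs(records$amplitude_b),
                              records$amplitude_a, records$amplitude_b)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$position_index,
                                        xend = .data$position_index,
                                        y = 0, yend = .data$amplitude,
                                        colour = .data$winner)) +
    ggplot2::geom_segment(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "gene (genomic order)", y = "signed -log10(Q)",
                  colour = "greater deflection") +
    ggplot2::theme_minimal()
}

order_by_position <- function(stats, annotation) {
  if (!is.null(annotation)) {
    annotation <- validate_annotation(annotation)
    pos <- annotation[match(stats$symbol, annotation$symbol), ]
    stats <- stats[order(chromosome_rank(pos$chromosome), pos$start), ]
  }
  stats$position_index <- seq_len(nrow(stats))
  stats
}

#' Plot volcano statistics
#'
#' Significance (`-log10` p) against fold change, with a dashed horizontal
#' line at the p-value cutoff; points above it have `p < cutoff`.
#'
#' @param records tibble from [volcano_stats()].
#' @param cutoff p-value cutoff drawn as the dashed line (default 0.05).
#' @return a ggplot object.
#' @export
plot_volcano <- function(records, cutoff = 0.05) {
  if (!nrow(records)) stop_mcv("no genes to plot", "validation_error")
  ggplot2::ggplot(records, ggplot2::aes(x = .data$log2_fold_change,
                                        y = .data$neg_log10_p,
                                        colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(cutoff), linetype = "dashed") +
    ggplot2::labs(x = "log2 fold change", y = "-log10(p)",
                  colour = paste0("p < ", cutoff)) +
    ggplot2::theme_minimal()
}

#' Plot a bee-swarm of per-sample values
#'
#' One-dimensional scatter with closely packed, non-overlapping points,
#' grouped on the x axis, optionally overlaid on a box plot.
#'
#' @param data data frame with columns `value` and `group`.
#' @param point_diameter swarm point diameter in value-axis units; defaults
#'   to 1/40 of the value range.
#' @param boxplot overlay a box plot per group?
#' @return a ggplot object.
#' @export
plot_beeswarm <- function(data, point_diameter = NULL, boxplot = FALSE) {
  if (!nrow(data)) stop_mcv("no values to plot", "validation_error")
  if (is.null(point_diameter)) {
    spread <- diff(range(data$value))
    point_diameter <- if (spread > 0) spread / 40 else 1
  }
  data <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(offset = beeswarm_layout(.data$value, point_diameter)) |>
    dplyr::ungroup()
  data$x <- as.numeric(factor(data$group)) + data$offset / (8 * point_diameter)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$x, y = .data$value))
  if (boxplot) {
    p <- p + ggplot2::geom_boxplot(
      ggplot2::aes(x = as.numeric(factor(.data$group)),
                   group = .data$group),
      width = 0.3, outliers = FALSE, colour = "grey60")
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(levels(factor(data$group))),
      labels = levels(factor(data$group))) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
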