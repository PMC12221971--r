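#' Histogram of per-site methylation
#'
#' The classic bimodal methylome histogram: per-site methylation
#' percentages in ten 10-point bins.
#'
#' @param calls Destranded call table (conventionally filtered >= 5x).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_methylation_histogram <- function(calls, title = NULL) {
  frac <- meth_fraction(calls)
  df <- meth_hist(frac)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo + 5, y = .data$n)) +
    ggplot2::geom_col(width = 9, fill = "grey30") +
    ggplot2::labs(x = "methylation (%)", y = "CpG sites",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Plot a methylome segmentation
#'
#' Segments drawn along each chromosome at their mean methylation,
#' coloured by class; PMD candidates (if flagged) are outlined.
#'
#' @param object A [segment_methylome()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meth_segmentation <- function(object, ...) {
  df <- as_tibble(object)
  if (!"is_pmd" %in% names(df)) df$is_pmd <- FALSE
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start / 1e6, xend = .data$end / 1e6,
      y = .data$mean_meth, yend = .data$mean_meth,
      colour = factor(.data$seg_class), linewidth = .data$is_pmd)) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.8,
                                               `TRUE` = 2.2),
                                    guide = "none") +
    ggplot2::facet_wrap(~chrom, ncol = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (Mb)", y = "mean methylation",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot a scaled meta-profile
#'
#' @param object A [meta_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$mean_meth)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$zone), size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "bin (5' flank - scaled body - 3' flank)",
                  y = "mean methylation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of DMR fates by parental origin
#'
#' @param report A [fate_report()] result.
#' @return A ggplot object.
#' @export
plot_fate_counts <- function(report) {
  ggplot2::ggplot(report$counts,
                  ggplot2::aes(x = .data$fate, y = .data$n,
                               fill = .data$origin)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "gamete DMRs", fill = "origin") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot chromosome-group methylation distributions
#'
#' @param dist A [chrom_distributions()] result.
#' @return A ggplot object.
#' @export
plot_chrom_distributions <- function(dist) {
  df <- tidyr::unnest(select(dist, "group", "hist"), "hist")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lo + 5, y = .data$n,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge", width = 9) +
    ggplot2::labs(x = "methylation (%)", y = "CpG sites", fill = NULL) +
    ggplot2::theme_minimal()
}
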