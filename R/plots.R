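#' Plot a bulked-segregant window profile
#'
#' Passing-variant counts per sliding window along the chromosome, with the
#' called enriched interval shaded when supplied.
#'
#' @param profile A `bsa_profile` from [bsa_scan()].
#' @param interval Optional `bsa_interval` from [call_enriched_interval()].
#'
#' @return A ggplot object.
#' @export
plot_bsa_profile <- function(profile, interval = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$count
  )) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Position (Mb)", y = "Filtered variants per window",
      title = "Bulked-segregant recessive-filter scan"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(interval) && nrow(interval) > 0) {
    p <- p + ggplot2::annotate("rect",
      xmin = interval$start / 1e6, xmax = interval$end / 1e6,
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "firebrick"
    )
  }
  p
}

#' @rdname plot_bsa_profile
#' @param object,... Passed through (`autoplot` interface).
#' @export
autoplot.bsa_profile <- function(object, ...) plot_bsa_profile(object, ...)

#' Plot the per-sample excess-homozygosity metric
#'
#' @param profile A [het_profile()] after [homozygosity_metric()].
#'
#' @return A ggplot object with one panel per sample.
#' @export
plot_het_metric <- function(profile) {
  if (!"metric" %in% names(profile)) profile <- homozygosity_metric(profile)
  ggplot2::ggplot(profile, ggplot2::aes(
    x = (.data$start + .data$end) / 2e6, y = .data$metric
  )) +
    ggplot2::geom_step(colour = "darkgreen") +
    ggplot2::facet_grid(sample ~ chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Position (Mb)",
      y = "-(het sites per window / median het sites)",
      title = "Windowed excess homozygosity"
    ) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a dominance-coded association scan
#'
#' @param scan A `gwas_scan` from [genome_scan()].
#'
#' @return A ggplot object; the dashed line marks the genome-wide
#'   significance threshold used by the scan.
#' @export
plot_manhattan <- function(scan) {
  p_star <- attr(scan, "p_star")
  if (is.null(p_star)) p_star <- 5e-8
  ggplot2::ggplot(
    filter(scan, !is.na(.data$p)),
    ggplot2::aes(x = .data$pos / 1e6, y = .data$neglog10p)
  ) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(p_star),
      linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(
      x = "Position (Mb)", y = expression(-log[10](italic(p))),
      title = "Dominance-coded exact-test scan"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_manhattan
#' @param object,... Passed through (`autoplot` interface).
#' @export
autoplot.gwas_scan <- function(object, ...) plot_manhattan(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
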