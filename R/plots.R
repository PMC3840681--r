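#' Plot DSB relative presence per transcription category
#'
#' Bar chart of observed/expected DSB counts per category with the
#' empirical p-value printed above each bar; the dashed line at 1 marks
#' the random-placement expectation.
#'
#' @param enrichment Tibble from [enrichment_test()] / [dsb_enrichment()].
#' @return A ggplot.
#' @export
plot_dsb_enrichment <- function(enrichment) {
  ggplot2::ggplot(enrichment,
                  ggplot2::aes(x = .data$category,
                               y = .data$relative_presence)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$p_empirical, 2)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = "transcription category",
                  y = "relative presence (observed / expected)") +
    ggplot2::theme_minimal()
}

#' Plot recombination rate against a window transcription metric
#'
#' @param metrics Output of [window_metrics()].
#' @param recomb_map Recombination map tibble.
#' @param metric Metric column to plot on x (default `"n_transcribed"`).
#' @return A ggplot.
#' @export
plot_landscape <- function(metrics, recomb_map, metric = "n_transcribed") {
  joined <- join_windows(metrics, recomb_map)
  ggplot2::ggplot(joined, ggplot2::aes(x = .data[[metric]],
                                       y = .data$rate)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick") +
    ggplot2::labs(x = metric, y = "recombination rate (cM/Mb)") +
    ggplot2::theme_minimal()
}

#' Plot the recombination landscape along chromosomes
#'
#' @param recomb_map Recombination map tibble (`chrom`, `start`, `end`,
#'   `rate`).
#' @return A ggplot faceted by chromosome.
#' @export
plot_recombination_map <- function(recomb_map) {
  ggplot2::ggplot(recomb_map,
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$rate)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "rate (cM/Mb)") +
    ggplot2::theme_minimal()
}

#' @method autoplot runs_test
#' @export
autoplot.runs_test <- function(object, ...) {
  ggplot2::ggplot(object$by_chrom,
                  ggplot2::aes(x = .data$chrom, y = .data$n_runs)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected_runs),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = NULL, y = "runs (bar = observed, point = expected)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
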