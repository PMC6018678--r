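#' Volcano plot of gene fitness versus significance
#'
#' @param results Hit-annotated gene results from [call_hits()].
#' @param fdr Dashed-line hit threshold to display (default 0.05).
#' @return A ggplot object: gene fitness on x, -log10 P on y, hits
#'   highlighted.
#' @export
plot_volcano <- function(results, fdr = 0.05) {
  results$neg_log10_p <- -log10(results$p)
  ggplot2::ggplot(results,
                  ggplot2::aes(.data$fitness, .data$neg_log10_p,
                               colour = .data$hit)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
      name = sprintf("q < %.2g", fdr)
    ) +
    ggplot2::labs(x = "Gene fitness (log2)",
                  y = expression(-log[10] ~ italic(P)))
}

#' Plot the sgRNA activity profile along the ORF
#'
#' @param profile Tibble from [position_activity_profile()].
#' @param alpha Significance level for bin highlighting (default 0.01).
#' @return A ggplot object of median |Z| per position bin.
#' @export
plot_position_activity <- function(profile, alpha = 0.01) {
  profile$flag <- !is.na(profile$p) & profile$p < alpha
  ggplot2::ggplot(profile,
                  ggplot2::aes((.data$lower + .data$upper) / 2,
                               .data$median_abs_z, fill = .data$flag)) +
    ggplot2::geom_col(width = 0.04) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = sprintf("P < %.2g", alpha)
    ) +
    ggplot2::labs(x = "Relative position in ORF", y = "Median |Z|")
}
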