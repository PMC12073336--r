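#' Box plot of score distributions by category and version
#'
#' Horizontal box plots of total scores per beverage category, one box per
#' algorithm version, with the beverage letter cut-offs of both versions
#' drawn as vertical reference lines (solid for 2015, dotted for 2023). The
#' long-format data behind the plot is available from
#' [build_summary()]`$long_scores`; this renderer is a convenience, not an
#' analysis surface.
#'
#' @param summary An `ns_summary` from [build_summary()].
#' @return A ggplot object.
#' @export
plot_score_boxplot <- function(summary) {
  stopifnot(inherits(summary, "ns_summary"))
  cuts <- summary$letter_cutoffs
  ggplot2::ggplot(summary$long_scores,
                  ggplot2::aes(x = .data$score, y = .data$category,
                               fill = .data$version)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(
      data = cuts[cuts$scale == "beverage_2015", ],
      ggplot2::aes(xintercept = .data$upper + 0.5),
      linetype = "solid", color = "grey55", linewidth = 0.3) +
    ggplot2::geom_vline(
      data = cuts[cuts$scale == "beverage_2023", ],
      ggplot2::aes(xintercept = .data$upper + 0.5),
      linetype = "dotted", color = "black", linewidth = 0.4) +
    ggplot2::scale_fill_manual(values = c(`2015` = "#8da0cb",
                                          `2023` = "#66c2a5")) +
    ggplot2::labs(x = "total score", y = NULL, fill = "algorithm") +
    ggplot2::theme_minimal(base_size = 10)
}
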