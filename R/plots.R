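# Optional figures: histogram plus boundary-corrected density of the
# non-covered ratios, overall and by day of the week. ggplot2 is suggested,
# not imported.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort_dietmap("plotting requires the ggplot2 package")
  }
}

#' Histogram and density of a non-covered ratio
#'
#' @param coverage Coverage tibble from [daily_coverage_ratios()].
#' @param metric `"freq_ratio"` or `"amount_ratio"`.
#' @param bins Histogram bin count (default 20).
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(coverage, metric = c("freq_ratio", "amount_ratio"),
                                    bins = 20) {
  need_ggplot()
  metric <- match.arg(metric)
  vals <- coverage[[metric]]
  vals <- vals[!is.na(vals)]
  dens <- ratio_density(vals)
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = data.frame(x = vals),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = bins, boundary = 0, fill = "grey80", colour = "grey40"
    ) +
    ggplot2::geom_line(
      data = dens, ggplot2::aes(x = .data$x, y = .data$density),
      linewidth = 0.8
    ) +
    ggplot2::labs(
      x = sprintf("non-covered %s", sub("_", " ", metric)),
      y = "density"
    ) +
    ggplot2::theme_minimal()
}

#' Density of a non-covered ratio by day of the week
#'
#' @param coverage Coverage tibble from [daily_coverage_ratios()].
#' @param metric `"freq_ratio"` or `"amount_ratio"`.
#' @return A ggplot object with one density per weekday.
#' @export
plot_ratio_by_weekday <- function(coverage, metric = c("freq_ratio", "amount_ratio")) {
  need_ggplot()
  metric <- match.arg(metric)
  keep <- !is.na(coverage[[metric]])
  dens <- lapply(weekday_levels(), function(d) {
    v <- coverage[[metric]][keep & coverage$weekday == d]
    if (length(v) < 2) {
      return(NULL)
    }
    out <- ratio_density(v)
    out$weekday <- factor(d, levels = weekday_levels())
    out
  })
  dens <- dplyr::bind_rows(dens)
  ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density, colour = .data$weekday)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("non-covered %s", sub("_", " ", metric)),
      y = "density", colour = "weekday"
    ) +
    ggplot2::theme_minimal()
}
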