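#' Plot per-year inbreeding trends
#'
#' Line plot of one or more per-year summaries from [summarize_f_by_year()],
#' on the percent scale.
#'
#' @param ... Named per-year summary tibbles (the names label the series),
#'   e.g. `plot_inbreeding_trend(F_PED = s1, F_ROH = s2)`.
#' @return A ggplot object.
#' @export
plot_inbreeding_trend <- function(...) {
  series <- list(...)
  if (is.null(names(series)) || any(names(series) == "")) {
    names(series) <- paste0("series_", seq_along(series))
  }
  df <- dplyr::bind_rows(series, .id = "estimator")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$birth_year, y = 100 * .data$f,
    colour = .data$estimator
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Birth year", y = "Inbreeding (%)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot mean per-chromosome ROH coverage
#'
#' @param coverage Tibble from [chromosome_coverage()].
#' @return A ggplot bar chart of mean percent covered per chromosome.
#' @export
plot_roh_coverage <- function(coverage) {
  ggplot2::ggplot(coverage, ggplot2::aes(
    x = factor(.data$chromosome), y = .data$mean_pct
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Chromosome", y = "Mean genome in ROH (%)") +
    ggplot2::theme_minimal()
}

#' Plot setting-wise correlations of F_ROH with F_PED
#'
#' @param object A `grid_comparison` from [grid_compare()].
#' @param ... Unused.
#' @return A ggplot dot plot of Pearson r per threshold setting, the best
#'   setting highlighted.
#' @export
autoplot.grid_comparison <- function(object, ...) {
  df <- object$correlations |>
    dplyr::mutate(best = .data$setting == object$best_setting)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$r, y = stats::reorder(.data$setting, .data$r),
    colour = .data$best
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#D55E00", `FALSE` = "grey30"),
      guide = "none"
    ) +
    ggplot2::labs(
      x = "Pearson r with F_PED",
      y = "Threshold setting"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
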