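#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_hline geom_col geom_line geom_tile scale_x_log10 labs theme_minimal
#'   facet_wrap scale_fill_gradient2
#' @export
ggplot2::autoplot

#' Forest plot of a signal screen
#'
#' Drugs on the vertical axis, ROR with its 95% Wald interval on a log
#' horizontal axis, the null at 1 as a dashed line; flagged drugs (ROR rule
#' set) are coloured.
#'
#' @param object A `signal_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signal_screen <- function(object, ...) {
  df <- object$results |>
    mutate(drug = factor(.data$drug, levels = rev(.data$drug)))
  ggplot(df, aes(x = .data$ror, y = .data$drug, colour = .data$flag_ror)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ror_ci_low, xmax = .data$ror_ci_high),
                   height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    scale_x_log10() +
    labs(x = "Reporting odds ratio (95% CI)", y = NULL,
         colour = "ROR CI lower > 1",
         title = sprintf("Disproportionality screen: %s", object$event)) +
    theme_minimal()
}

#' Yearly report-count trend
#'
#' @param counts Tibble from [yearly_counts()].
#' @return A ggplot object.
#' @export
plot_yearly_trend <- function(counts) {
  ggplot(counts, aes(x = .data$year, y = .data$count)) +
    geom_col(fill = "steelblue") +
    geom_line(colour = "grey30") +
    labs(x = "Year", y = "Reports") +
    theme_minimal()
}

#' Heatmap of a stratified metric matrix
#'
#' @param metrics Long tibble from [stratified_metrics()].
#' @param metric Metric column to display.
#' @return A ggplot object.
#' @export
plot_stratified_heatmap <- function(metrics, metric = "rrr") {
  if (!metric %in% names(metrics)) stopf("metric column %s not found", metric)
  fill_scale <- if (metric == "count") {
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick")
  } else {
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         midpoint = 0)
  }
  ggplot(metrics, aes(x = .data$stratum, y = .data$drug,
                      fill = .data[[metric]])) +
    geom_tile() +
    fill_scale +
    labs(x = NULL, y = NULL, fill = metric) +
    theme_minimal()
}

#' Outcome distribution by year
#'
#' @param dist Tibble from [outcome_distribution()] with `by_year = TRUE`.
#' @param percentage Plot the percentage view instead of absolute counts?
#' @return A ggplot object.
#' @export
plot_outcomes <- function(dist, percentage = FALSE) {
  y <- if (percentage) "percentage" else "count"
  ggplot(dist, aes(x = .data$year, y = .data[[y]], fill = .data$outcome)) +
    geom_col(position = if (percentage) "stack" else "stack") +
    labs(x = "Year", y = if (percentage) "% of reports" else "Reports") +
    theme_minimal()
}
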