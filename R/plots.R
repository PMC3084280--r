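#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trend series with its fitted trend line
#'
#' @param object A [trend_series()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trend_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(title = series_label(object), x = "time", y = "value") +
    ggplot2::theme_minimal()
}

#' Plot interval means over the original series
#'
#' @param object An [interval_means][divide_series()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interval_means <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$midpoint, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("%s: k = %d interval means (%s)",
                      attr(object, "label"), attr(object, "k"),
                      attr(object, "method")),
      x = "interval midpoint", y = "interval mean") +
    ggplot2::theme_minimal()
}

#' Plot the per-division statistics of a meaningfulness test
#'
#' r-squared for every division count in the sweep, with the r-squared
#' threshold and the per-k critical r-squared (above which p <= p_max)
#' overlaid; a division qualifies where its point clears both curves.
#'
#' @param object A [test_meaningfulness()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meaningfulness_test <- function(object, ...) {
  pd <- dplyr::filter(object$per_division, !.data$skipped)
  th <- object$thresholds
  crit <- tibble::tibble(k = pd$k,
                         critical = critical_r2(pd$k, th$p_max))
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$k, y = .data$r_squared)) +
    ggplot2::geom_line(data = crit,
                       ggplot2::aes(y = .data$critical),
                       linetype = "dotted", colour = "grey40") +
    ggplot2::geom_hline(yintercept = th$r2_min, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$qualifies), size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "forestgreen",
                                            `FALSE` = "grey30")) +
    ggplot2::labs(
      title = sprintf("%s: %s", object$label,
                      gsub("_", " ", object$verdict)),
      subtitle = sprintf("thresholds r2 >= %g, p <= %g; dotted: critical r2 for p = %g",
                         th$r2_min, th$p_max, th$p_max),
      x = "number of interval divisions (k)", y = "r squared",
      colour = "qualifies") +
    ggplot2::theme_minimal()
}

#' Plot a division-frequency profile
#'
#' Bar chart of how often each division count indicated a meaningful trend
#' across Monte Carlo runs (see [division_frequency_experiment()]).
#'
#' @param freq A [division_frequency_experiment()] tibble.
#' @return A ggplot.
#' @export
plot_division_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$k, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of interval divisions (k)",
                  y = "fraction of runs qualifying") +
    ggplot2::theme_minimal()
}
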