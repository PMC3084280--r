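#' Test a time series for a statistically meaningful trend
#'
#' A linear trend is *statistically meaningful* when at least one regression
#' of time against the series itself, or against interval mean values from a
#' division of the series into `k` consecutive intervals
#' (`k = k_min .. k_max`), attains `r_squared >= r2_min` together with
#' `p_value <= p_max` (both comparisons inclusive). The defaults
#' `r2_min = 0.65` (the classical predictive-power threshold) and
#' `p_max = 0.05` encode the standard definition; the sweep default is
#' `k = 3 .. 30`.
#'
#' The full-series regression participates in the verdict on equal footing
#' with the interval-mean regressions. Division counts whose sub-ranges
#' contain no observation (possible only for irregular series) are skipped
#' with a recorded reason, not treated as failures. No multiple-testing
#' correction is applied across the k sweep — the test is defined as a
#' disjunction over divisions, which users should keep in mind when
#' interpreting a single qualifying division; per-division slope signs are
#' reported but sign consistency across divisions is not required.
#'
#' @param data A data frame (or [trend_series()]) with the time and value
#'   columns.
#' @param time,value Columns holding time coordinate and measurement
#'   (tidy-eval; defaults `time`, `value`). Ignored when `data` is already
#'   a `trend_series`.
#' @param method Interval-division method: `"auto"` (default; regular
#'   spacing selects equal time steps, otherwise different time steps),
#'   `"equal"` or `"different"`.
#' @param r2_min,p_max Meaningfulness thresholds (defaults 0.65 and 0.05).
#' @param k_min,k_max Division-count sweep bounds (defaults 3 and 30);
#'   capped by [max_divisions()]. Values of `k_max` above 30 are allowed
#'   but mainly cost computation on long series — interval counts beyond
#'   ~19 rarely add qualifying divisions (see [redundancy_scan()]).
#' @param integer_blocks Passed to [divide_series()] for irregular series.
#' @param label Optional series label.
#' @return An object of class `meaningfulness_test`: use `print()`,
#'   [tidy()][generics::tidy] (per-division statistics),
#'   [glance()][generics::glance] (one-row summary) and
#'   [autoplot()][ggplot2::autoplot] on it. Fields include `full_series`
#'   (one-row tibble from [trend_regression()]), `per_division` (tibble of
#'   `k`, `r_squared`, `p_value`, `slope_sign`, `qualifies`, `skipped`,
#'   `reason`), `qualifying_divisions`, `full_series_qualifies` and
#'   `verdict` (`"meaningful"` or `"not_meaningful"`).
#' @examples
#' ts <- generate_trend_noise(n = 60, slope = 0.05, noise_sd = 1, seed = 1)
#' fit <- test_meaningfulness(ts)
#' fit
#' tidy(fit)
#' @export
test_meaningfulness <- function(data, time = time, value = value,
                                method = c("auto", "equal", "different"),
                                r2_min = 0.65, p_max = 0.05,
                                k_min = 3L, k_max = 30L,
                                integer_blocks = FALSE, label = NULL) {
  method <- match.arg(method)
  check_thresholds(r2_min, p_max, k_min, k_max)
  ts <- if (inherits(data, "trend_series")) data
        else trend_series(data, time = {{ time }}, value = {{ value }},
                          label = label %||% rlang::as_label(rlang::enquo(data)),
                          quiet = TRUE)
  if (!is.null(label)) attr(ts, "label") <- label
  n <- nrow(ts)
  if (n < 3L) {
    rlang::abort("meaningfulness test needs at least 3 observations.",
                 class = "smtrend_insufficient_data_error")
  }
  if (method == "auto") {
    method <- if (classify_spacing(ts)$kind == "regular") "equal" else "different"
  }

  full <- trend_regression(ts$time, ts$value)
  kmax_use <- tryCatch(
    max_divisions(ts, method = method, cap = k_max,
                  integer_blocks = integer_blocks),
    smtrend_series_too_short_error = function(e) NA_integer_)
  ks <- if (is.na(kmax_use) || kmax_use < k_min) integer(0)
        else seq.int(k_min, kmax_use)

  per_division <- purrr::map_dfr(ks, function(k) {
    im <- divide_series(ts, k, method = method,
                        integer_blocks = integer_blocks)
    if (attr(im, "empty_intervals") > 0L) {
      return(tibble::tibble(k = k, r_squared = NA_real_, p_value = NA_real_,
                            slope_sign = NA_character_, qualifies = FALSE,
                            skipped = TRUE,
                            reason = sprintf("%d empty interval(s)",
                                             attr(im, "empty_intervals"))))
    }
    reg <- trend_regression(im$midpoint, im$mean)
    tibble::tibble(k = k, r_squared = reg$r_squared, p_value = reg$p_value,
                   slope_sign = reg$slope_sign,
                   qualifies = reg$r_squared >= r2_min & reg$p_value <= p_max,
                   skipped = FALSE, reason = NA_character_)
  })
  if (nrow(per_division) == 0L) {
    per_division <- tibble::tibble(k = integer(), r_squared = double(),
                                   p_value = double(), slope_sign = character(),
                                   qualifies = logical(), skipped = logical(),
                                   reason = character())
  }

  full_q <- full$r_squared >= r2_min && full$p_value <= p_max
  qualifying <- per_division$k[per_division$qualifies]
  structure(list(
    label = series_label(ts),
    n = n,
    method = paste0(method, "_time_steps"),
    thresholds = list(r2_min = r2_min, p_max = p_max,
                      k_min = k_min, k_max = k_max),
    k_max_used = if (length(ks)) max(ks) else NA_integer_,
    full_series = full,
    per_division = per_division,
    qualifying_divisions = qualifying,
    full_series_qualifies = full_q,
    verdict = if (full_q || length(qualifying) > 0) "meaningful"
              else "not_meaningful"),
    class = "meaningfulness_test")
}

check_thresholds <- function(r2_min, p_max, k_min, k_max) {
  ok <- r2_min > 0 && r2_min < 1 && p_max > 0 && p_max < 1 &&
    k_min >= 3 && k_min <= k_max
  if (!ok) {
    rlang::abort("thresholds must satisfy 0 < r2_min < 1, 0 < p_max < 1, 3 <= k_min <= k_max.",
                 class = "smtrend_domain_error")
  }
  invisible(TRUE)
}

#' @export
print.meaningfulness_test <- function(x, ...) {
  th <- x$thresholds
  cat(sprintf("Statistical meaningfulness test: %s\n", x$label))
  cat(sprintf("  n = %d, method = %s, sweep k = %d..%s\n",
              x$n, x$method, th$k_min,
              ifelse(is.na(x$k_max_used), "(none)", x$k_max_used)))
  cat(sprintf("  thresholds: r2 >= %g, p <= %g\n", th$r2_min, th$p_max))
  fs <- x$full_series
  cat(sprintf("  full series: slope %s, r2 = %.4g, p = %.4g%s\n",
              fs$slope_sign, fs$r_squared, fs$p_value,
              if (x$full_series_qualifies) "  [qualifies]" else ""))
  nq <- length(x$qualifying_divisions)
  cat(sprintf("  qualifying divisions: %s\n",
              if (nq == 0) "none"
              else paste0(nq, " (k = ",
                          paste(x$qualifying_divisions, collapse = ", "), ")")))
  cat(sprintf("  verdict: %s\n",
              ifelse(x$verdict == "meaningful",
                     "statistically MEANINGFUL trend",
                     "trend NOT statistically meaningful")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-division statistics of a meaningfulness test
#'
#' @param x A [test_meaningfulness()] result.
#' @param ... Unused.
#' @return A tibble with one row per division count `k` (plus one row with
#'   `k = NA` for the full-series regression): `r_squared`, `p_value`,
#'   `slope_sign`, `qualifies`, `skipped`, `reason`.
#' @export
tidy.meaningfulness_test <- function(x, ...) {
  fs <- x$full_series
  dplyr::bind_rows(
    tibble::tibble(k = NA_integer_, r_squared = fs$r_squared,
                   p_value = fs$p_value, slope_sign = fs$slope_sign,
                   qualifies = x$full_series_qualifies, skipped = FALSE,
                   reason = "full series"),
    x$per_division)
}

#' One-row summary of a meaningfulness test
#'
#' Columns mirror a per-series report row: label, n, method, full-series
#' slope sign / r-squared / p, the number of qualifying divisions, and the
#' verdict.
#'
#' @inheritParams tidy.meaningfulness_test
#' @return A one-row tibble.
#' @export
glance.meaningfulness_test <- function(x, ...) {
  fs <- x$full_series
  tibble::tibble(
    label = x$label, n = x$n, method = x$method,
    slope_sign = fs$slope_sign, r_squared = fs$r_squared,
    p_value = fs$p_value,
    n_qualifying = length(x$qualifying_divisions),
    full_series_qualifies = x$full_series_qualifies,
    k_max_used = x$k_max_used,
    meaningful = x$verdict == "meaningful",
    verdict = x$verdict)
}

#' Sensitivity of verdicts to the r-squared and p limits
#'
#' Re-evaluates the meaningfulness verdict of every series in a corpus over
#' a grid of `(p_max, r2_min)` limit pairs, showing how the set of
#' meaningful series grows as either limit is relaxed. The sets are nested:
#' lowering `r2_min` or raising `p_max` can only add series.
#'
#' Per-division statistics are computed once per series and the thresholds
#' applied per grid cell, so large grids cost no extra regression work.
#'
#' @param data A data frame in long format with one row per observation and
#'   a series-identifier column.
#' @param time,value,series Tidy-eval columns: time coordinate, measurement
#'   and series identifier (defaults `time`, `value`, `series`).
#' @param r2_grid,p_grid Numeric vectors of limits in `(0, 1)` (defaults:
#'   the conventional grid `r2 = 0.85 .. 0.55`, `p = 0.01, 0.05, 0.1`).
#' @param ... Passed to [test_meaningfulness()] (`method`, `k_min`,
#'   `k_max`, `integer_blocks`).
#' @return A tibble with one row per `(p_max, r2_min)` pair: `p_max`,
#'   `r2_min`, `meaningful` (list-column of series labels),
#'   `n_meaningful`.
#' @export
sensitivity_analysis <- function(data, time = time, value = value,
                                 series = series,
                                 r2_grid = c(0.85, 0.8, 0.75, 0.7, 0.65,
                                             0.6, 0.55),
                                 p_grid = c(0.01, 0.05, 0.1), ...) {
  if (any(r2_grid <= 0 | r2_grid >= 1) || any(p_grid <= 0 | p_grid >= 1) ||
      !length(r2_grid) || !length(p_grid)) {
    rlang::abort("r2_grid and p_grid must be non-empty with values in (0, 1).",
                 class = "smtrend_domain_error")
  }
  groups <- dplyr::group_split(
    dplyr::group_by(
      tibble::tibble(time = rlang::eval_tidy(rlang::enquo(time), data),
                     value = rlang::eval_tidy(rlang::enquo(value), data),
                     series = as.character(
                       rlang::eval_tidy(rlang::enquo(series), data))),
      series))
  # widest thresholds: every candidate regression's stats get computed once
  fits <- purrr::map(groups, function(g) {
    test_meaningfulness(g[c("time", "value")], label = g$series[1],
                        r2_min = min(r2_grid), p_max = max(p_grid), ...)
  })
  stats <- purrr::map(fits, tidy)
  labels <- purrr::map_chr(fits, "label")
  grid <- tidyr::expand_grid(p_max = p_grid, r2_min = r2_grid)
  grid$meaningful <- purrr::map2(grid$p_max, grid$r2_min, function(p, r) {
    labels[purrr::map_lgl(stats, function(s) {
      any(!s$skipped & s$r_squared >= r & s$p_value <= p, na.rm = TRUE)
    })]
  })
  grid$n_meaningful <- lengths(grid$meaningful)
  grid
}

#' Does restricting the sweep to small division counts change the verdict?
#'
#' Audits the finding that sweeping interval divisions beyond `k = 19` is
#' redundant: returns `TRUE` when dropping all qualifying divisions above
#' `k_limit` leaves the verdict unchanged.
#'
#' @param result A [test_meaningfulness()] result computed with
#'   `k_max >= k_limit`.
#' @param k_limit Division-count cutoff (default 19).
#' @return `TRUE` if the verdict is unchanged under the restricted sweep.
#' @export
redundancy_scan <- function(result, k_limit = 19L) {
  stopifnot(inherits(result, "meaningfulness_test"))
  if (k_limit < result$thresholds$k_min) {
    rlang::abort("k_limit must be >= the sweep's k_min.",
                 class = "smtrend_domain_error")
  }
  restricted <- result$full_series_qualifies ||
    any(result$qualifying_divisions <= k_limit)
  restricted == (result$verdict == "meaningful")
}
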