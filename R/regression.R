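#' Bivariate trend regression statistics
#'
#' Ordinary least-squares regression of `y` on `x` summarised by the three
#' quantities the meaningfulness test uses: the coefficient of determination
#' (the squared Pearson correlation computed from deviations about the two
#' means), the t statistic derived from `n` and r-squared,
#' `t = sqrt(r2 * (n - 2) / (1 - r2))`, and the two-tailed Student-t tail
#' probability at `n - 2` degrees of freedom.
#'
#' A response with zero variance carries no trend by convention: it is
#' reported as `r_squared = 0`, `p_value = 1` and flagged `degenerate`, so a
#' flat series can never pass the test.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; `x` (the time
#'   coordinate) must have nonzero variance.
#' @return A one-row tibble: `n`, `slope`, `intercept`, `r_squared`,
#'   `t_value` (reported non-negative; `slope_sign` carries direction),
#'   `df = n - 2`, `p_value`, `slope_sign` (`"positive"`, `"negative"` or
#'   `"zero"`), `degenerate`.
#' @examples
#' trend_regression(1:10, 2 * (1:10) + 1)
#' @export
trend_regression <- function(x, y) {
  if (length(x) != length(y)) {
    rlang::abort("x and y must have equal length.",
                 class = "smtrend_insufficient_data_error")
  }
  n <- length(x)
  if (n < 3L) {
    rlang::abort("regression needs at least 3 data pairs (df = n - 2 >= 1).",
                 class = "smtrend_insufficient_data_error")
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2)
  syy <- sum(dy^2)
  if (sxx <= 0) {
    rlang::abort("predictor (time) has zero variance.",
                 class = "smtrend_invalid_predictor_error")
  }
  degenerate <- syy <= 0
  sxy <- sum(dx * dy)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r2 <- if (degenerate) 0 else min((sxy * sxy) / (sxx * syy), 1)
  df <- n - 2L
  tv <- if (r2 >= 1) Inf else t_from_r2(r2, n)
  p <- if (degenerate) 1 else p_from_t(tv, df)
  tibble::tibble(
    n = n, slope = slope, intercept = intercept, r_squared = r2,
    t_value = tv, df = df, p_value = p,
    slope_sign = if (degenerate || slope == 0) "zero"
                 else if (slope > 0) "positive" else "negative",
    degenerate = degenerate)
}

#' t statistic from r-squared and the number of data pairs
#'
#' `t = sqrt(r2 * (n - 2) / (1 - r2))`: the magnitude of the regression t
#' statistic as a function of the coefficient of determination alone.
#'
#' @param r_squared Coefficient of determination in `[0, 1)`.
#' @param n Number of data pairs, `n >= 3`.
#' @return Non-negative t value (vectorised); `Inf` for `r_squared = 1`.
#' @examples
#' t_from_r2(0.65, 7)   # ~3.047
#' @export
t_from_r2 <- function(r_squared, n) {
  if (any(!is.finite(r_squared) | r_squared < 0 | r_squared > 1)) {
    rlang::abort("r_squared must lie in [0, 1].", class = "smtrend_domain_error")
  }
  if (any(n < 3)) {
    rlang::abort("n must be >= 3.", class = "smtrend_domain_error")
  }
  # r_squared = 1 yields Inf naturally via division by zero
  sqrt(r_squared * (n - 2) / (1 - r_squared))
}

#' Two-tailed p-value of the Student-t statistic
#'
#' @param t_value Non-negative finite t statistic (vectorised).
#' @param df Degrees of freedom, `>= 1` (the number of data pairs minus 2).
#' @return Two-tailed tail probability in `(0, 1]`.
#' @examples
#' p_from_t(3.0473, 5)   # ~0.0286
#' @export
p_from_t <- function(t_value, df) {
  if (any(df < 1)) {
    rlang::abort("df must be >= 1.", class = "smtrend_domain_error")
  }
  if (any(t_value < 0)) {
    rlang::abort("t_value must be non-negative (magnitude convention).",
                 class = "smtrend_domain_error")
  }
  2 * stats::pt(t_value, df, lower.tail = FALSE)
}

#' Critical r-squared for a given significance limit
#'
#' The coefficient of determination at which the two-tailed p exactly equals
#' `p_limit` for `n` data pairs: `r2_crit = tc^2 / (tc^2 + n - 2)`, with
#' `tc` the critical t at `df = n - 2`. Any regression on `n` points with
#' r-squared above this value is significant at `p_limit`. The function is
#' strictly decreasing in `n`; at `p_limit = 0.05` it crosses 0.65 between
#' `n = 7` (0.569) and `n = 6` (0.658), which is why interval counts of 3-6
#' can show r-squared above 0.65 without significance while counts of 7 or
#' more can be significant below 0.65.
#'
#' @param n Number of data pairs, `>= 3` (vectorised).
#' @param p_limit Two-tailed significance limit in `(0, 1)`.
#' @return Critical r-squared in `(0, 1)`.
#' @examples
#' critical_r2(6:7, 0.05)
#' @export
critical_r2 <- function(n, p_limit = 0.05) {
  if (any(n < 3)) {
    rlang::abort("n must be >= 3.", class = "smtrend_domain_error")
  }
  if (any(p_limit <= 0 | p_limit >= 1)) {
    rlang::abort("p_limit must lie in (0, 1).", class = "smtrend_domain_error")
  }
  tc <- stats::qt(1 - p_limit / 2, df = n - 2)
  tc^2 / (tc^2 + n - 2)
}
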