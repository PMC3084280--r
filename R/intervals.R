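#' Divide a trend series into k intervals and compute interval means
#'
#' The meaningfulness test summarises a series by mean values over `k`
#' consecutive intervals before regressing time against those means. Two
#' division methods exist, chosen by the spacing of the series:
#'
#' * **equal time steps** (`method = "equal"`), for regularly spaced series
#'   with one observation per time unit. Observation `i` is modelled as a
#'   unit cell `[i-1, i)` on an axis of length `n`; the axis is cut into `k`
#'   cells of length `n/k`, and each observation contributes to an interval
#'   with weight equal to the overlap of its unit cell with that interval.
#'   The interval mean is the weighted sum divided by the constant total
#'   weight `n/k`. For `n = 7`, `k = 3` this yields the fractional weights
#'   1/3 and 2/3 on the boundary-straddling observations and the denominator
#'   `2 + 1/3`: means `(y1+y2+y3/3)/(7/3)`, `(2*y3/3+y4+2*y5/3)/(7/3)`,
#'   `(y5/3+y6+y7)/(7/3)`. Every observation's weights sum to exactly 1, so
#'   observation mass is conserved.
#'
#' * **different time steps** (`method = "different"`), for irregularly
#'   spaced series (uneven steps and/or several samples per time unit). The
#'   time range is cut into `k` equal-length sub-ranges, half-open on the
#'   right except the last (closed); each observation belongs wholly to the
#'   sub-range containing its time, and the interval mean is the unweighted
#'   mean of its values. Times `(1,3,4,5,6,8,9)` at `k = 3` give the groups
#'   `{1,3}`, `{4,5,6}`, `{8,9}`. A sub-range containing no observation
#'   makes the division unusable (its mean is `NA` and `empty_intervals`
#'   is positive); downstream code skips such divisions rather than failing.
#'
#' The representative time for each interval is its midpoint on the time
#' axis. Both methods produce equally spaced midpoints, so regression
#' r-squared and p are invariant to any affine re-labelling of this choice
#' (midpoint versus interval index); it is cosmetic.
#'
#' @param ts A [trend_series()] or data frame with `time` and `value`.
#' @param k Number of intervals, `3 <= k <= n`.
#' @param method `"auto"` (default; resolve via [classify_spacing()]),
#'   `"equal"` or `"different"`.
#' @param integer_blocks For the different-steps method on all-integer
#'   times: treat each integer time unit as an inclusive block by extending
#'   the divided range to `[t_min, t_max + 1)`, so e.g. times 1..9 at
#'   `k = 3` split as the unit blocks 1-3, 4-6, 7-9. Default `FALSE`
#'   (divide the observed range `[t_min, t_max]`; both readings reproduce
#'   the canonical grouping above).
#' @return A tibble of class `interval_means` with one row per interval:
#'   `interval`, `midpoint`, `mean`, `support` (total weight `n/k` for the
#'   equal method, observation count for the different method), and
#'   attributes `k`, `method`, `empty_intervals`, `label`.
#' @examples
#' ts <- trend_series(data.frame(time = 1:7, value = c(1, 2, 3, 4, 5, 6, 7)))
#' divide_series(ts, k = 3)   # means 12/7, 4, 44/7
#' @seealso [max_divisions()], [test_meaningfulness()]
#' @export
divide_series <- function(ts, k, method = c("auto", "equal", "different"),
                          integer_blocks = FALSE) {
  ts <- as_trend_series(ts)
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (classify_spacing(ts)$kind == "regular") "equal" else "different"
  }
  switch(method,
         equal = divide_equal_time_steps(ts, k),
         different = divide_different_time_steps(ts, k,
                                                 integer_blocks = integer_blocks))
}

check_k <- function(k, n) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k < 3 || k > n) {
    rlang::abort(sprintf("k must be an integer with 3 <= k <= n (= %d); got %s.",
                         n, format(k)),
                 class = "smtrend_invalid_k_error")
  }
  as.integer(k)
}

#' @rdname divide_series
#' @export
divide_equal_time_steps <- function(ts, k) {
  ts <- as_trend_series(ts)
  n <- nrow(ts)
  k <- check_k(k, n)
  sp <- classify_spacing(ts)
  if (sp$kind != "regular") {
    rlang::abort("equal time steps division requires a regularly spaced series; use divide_different_time_steps().",
                 class = "smtrend_method_mismatch_error")
  }
  y <- ts$value
  # Overlap weights via the cumulative step function: the weighted sum over
  # interval [a, b) on the unit-cell axis is Y(b) - Y(a), with Y linearly
  # interpolating the cumulative sums at integer positions.
  Y <- c(0, cumsum(y))
  pos <- (0:k) * (n / k)
  fl <- pmin(floor(pos), n)
  fr <- pos - fl
  Yv <- Y[fl + 1L] + fr * y[pmin(fl + 1L, n)]
  means <- diff(Yv) / (n / k)
  # interval centres on the cell axis, mapped back to the time axis
  centre <- ((seq_len(k) - 0.5) * n / k)
  midpoints <- ts$time[1] + (centre - 0.5) * sp$step
  new_interval_means(
    tibble::tibble(interval = seq_len(k), midpoint = midpoints,
                   mean = means, support = rep(n / k, k)),
    k = k, method = "equal_time_steps", empty_intervals = 0L,
    label = series_label(ts))
}

#' @rdname divide_series
#' @export
divide_different_time_steps <- function(ts, k, integer_blocks = FALSE) {
  ts <- as_trend_series(ts)
  n <- nrow(ts)
  k <- check_k(k, n)
  t0 <- ts$time[1]
  t1 <- max(ts$time)
  if (integer_blocks && all(ts$time == round(ts$time))) t1 <- t1 + 1
  if (t1 <= t0) {
    rlang::abort("time range has zero width; cannot divide.",
                 class = "smtrend_invalid_k_error")
  }
  breaks <- t0 + (0:k) * (t1 - t0) / k
  # half-open on the right, last interval closed
  idx <- pmin(findInterval(ts$time, breaks, rightmost.closed = TRUE), k)
  counts <- tabulate(idx, nbins = k)
  sums <- vapply(seq_len(k), function(j) sum(ts$value[idx == j]), numeric(1))
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), NA_real_)
  new_interval_means(
    tibble::tibble(interval = seq_len(k),
                   midpoint = (breaks[-(k + 1)] + breaks[-1]) / 2,
                   mean = means, support = as.double(counts)),
    k = k, method = "different_time_steps",
    empty_intervals = sum(counts == 0L), label = series_label(ts))
}

new_interval_means <- function(tbl, k, method, empty_intervals, label) {
  structure(tbl, k = k, method = method,
            empty_intervals = as.integer(empty_intervals), label = label,
            class = c("interval_means", class(tibble::as_tibble(tbl))))
}

#' @export
print.interval_means <- function(x, ...) {
  cat(sprintf("# Interval means: %s, k = %d (%s)%s\n",
              attr(x, "label"), attr(x, "k"), attr(x, "method"),
              if (attr(x, "empty_intervals") > 0)
                sprintf(" [UNUSABLE: %d empty interval(s)]",
                        attr(x, "empty_intervals")) else ""))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Largest usable number of interval divisions
#'
#' The division sweep runs from 3 up to a cap (default 30) but can never
#' exceed the number of observations; for irregular series it is further
#' limited to the largest `k` at which no sub-range is empty (scanning
#' downward from the cap).
#'
#' @inheritParams divide_series
#' @param cap Upper limit of the sweep (default 30).
#' @return The largest usable `k` (integer).
#' @export
max_divisions <- function(ts, method = c("auto", "equal", "different"),
                          cap = 30L, integer_blocks = FALSE) {
  ts <- as_trend_series(ts)
  method <- match.arg(method)
  if (method == "auto") {
    method <- if (classify_spacing(ts)$kind == "regular") "equal" else "different"
  }
  n <- nrow(ts)
  top <- min(cap, n)
  if (top < 3L) {
    rlang::abort("series too short: fewer than 3 intervals possible.",
                 class = "smtrend_series_too_short_error")
  }
  if (method == "equal") return(as.integer(top))
  for (k in seq(top, 3L)) {
    im <- divide_different_time_steps(ts, k, integer_blocks = integer_blocks)
    if (attr(im, "empty_intervals") == 0L) return(as.integer(k))
  }
  rlang::abort("series too short: every k in 3..cap leaves an empty interval.",
               class = "smtrend_series_too_short_error")
}
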