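#' Build a trend series from a data frame
#'
#' A trend series is the package's basic container: a tibble with numeric
#' columns `time` and `value`, sorted by time, containing only finite
#' observations. Times are continuous reals in whatever unit the caller uses
#' (years, nights, ...); calendar parsing is deliberately out of scope, so
#' dates must be pre-converted to, e.g., decimal years. Duplicate time
#' coordinates are permitted (monitoring data often carry many samples per
#' time unit) and make the series irregular for the purposes of
#' [classify_spacing()].
#'
#' Rows with non-finite time or value (`NA`, `NaN`, `Inf`) are dropped, never
#' imputed; the number dropped is recorded in the `n_dropped` attribute and
#' reported via a message.
#'
#' @param data A data frame containing the time and value columns.
#' @param time,value Columns holding the time coordinate and the measurement
#'   (tidy-eval; defaults `time` and `value`).
#' @param label Free-text identifier for the series. Defaults to the name of
#'   the `data` argument.
#' @param quiet Suppress the dropped-row message.
#' @return A tibble of class `trend_series` with columns `time` and `value`,
#'   attributes `label` and `n_dropped`.
#' @examples
#' trend_series(data.frame(time = c(3, 1, 2), value = c(9, 4, 6)))
#' @export
trend_series <- function(data, time = time, value = value, label = NULL,
                         quiet = FALSE) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame.", class = "smtrend_type_error")
  }
  if (is.null(label)) label <- rlang::as_label(rlang::enquo(data))
  t <- rlang::eval_tidy(rlang::enquo(time), data)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  if (!is.numeric(t) || !is.numeric(v)) {
    rlang::abort("time and value columns must be numeric.",
                 class = "smtrend_parse_error")
  }
  keep <- is.finite(t) & is.finite(v)
  n_dropped <- sum(!keep)
  t <- as.double(t[keep]); v <- as.double(v[keep])
  if (length(t) < 1L) {
    rlang::abort("no finite (time, value) observations in input.",
                 class = "smtrend_empty_input_error")
  }
  ord <- order(t)
  out <- tibble::tibble(time = t[ord], value = v[ord])
  if (n_dropped > 0 && !quiet) {
    rlang::inform(sprintf("Dropped %d row(s) with non-finite entries.",
                          n_dropped))
  }
  new_trend_series(out, label = label, n_dropped = n_dropped)
}

new_trend_series <- function(tbl, label = "series", n_dropped = 0L) {
  structure(tbl,
            label = label,
            n_dropped = as.integer(n_dropped),
            class = c("trend_series", class(tibble::as_tibble(tbl))))
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("# A trend series: %s (n = %d%s)\n",
              series_label(x), nrow(x),
              if (attr(x, "n_dropped") > 0)
                sprintf(", %d dropped", attr(x, "n_dropped")) else ""))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

series_label <- function(ts) {
  lab <- attr(ts, "label")
  if (is.null(lab)) "series" else lab
}

# Coerce loosely-typed input (any df with time/value) for internal use.
as_trend_series <- function(data, label = NULL) {
  if (inherits(data, "trend_series")) return(data)
  trend_series(data, label = label %||% "series", quiet = TRUE)
}

#' Read a trend series from a delimited text file
#'
#' Reads a CSV/TSV (or other single-character delimited) file with a header
#' row, selects a time and a value column by name or 1-based position, drops
#' non-finite rows and returns a sorted [trend_series()].
#'
#' @param path Path to the file.
#' @param time,value Column name (character) or 1-based column position
#'   (integer) of the time coordinate and the measurement. Defaults: first
#'   and second column.
#' @param delim Field delimiter; `NULL` (default) guesses `","` for `.csv`
#'   and `"\t"` for `.tsv`/`.txt`.
#' @param label Series identifier; defaults to the file name.
#' @param quiet Suppress the dropped-row message.
#' @return A [trend_series()].
#' @export
read_trend_series <- function(path, time = 1L, value = 2L, delim = NULL,
                              label = NULL, quiet = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path),
                 class = "smtrend_io_error")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) {
    rlang::abort("no parseable data rows in file.",
                 class = "smtrend_empty_input_error")
  }
  pick <- function(col, what) {
    if (is.character(col)) {
      if (!col %in% names(raw)) {
        rlang::abort(sprintf("%s column '%s' not found (columns: %s).",
                             what, col, paste(names(raw), collapse = ", ")),
                     class = "smtrend_io_error")
      }
      raw[[col]]
    } else {
      col <- as.integer(col)
      if (col < 1L || col > ncol(raw)) {
        rlang::abort(sprintf("%s column index %d out of range.", what, col),
                     class = "smtrend_io_error")
      }
      raw[[col]]
    }
  }
  t <- pick(time, "time"); v <- pick(value, "value")
  coerce_num <- function(x, what) {
    if (is.numeric(x)) return(x)
    y <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(y))
    if (length(bad)) {
      rlang::abort(sprintf("non-numeric %s entry at data row %d: '%s'",
                           what, bad[1], x[bad[1]]),
                   class = "smtrend_parse_error")
    }
    y
  }
  trend_series(tibble::tibble(time = coerce_num(t, "time"),
                              value = coerce_num(v, "value")),
               label = label %||% basename(path), quiet = quiet)
}

#' Write a trend series to a delimited text file
#'
#' Round-trips bit-identically with [read_trend_series()] for finite inputs
#' (full double precision is written).
#'
#' @param ts A [trend_series()] or any data frame with `time` and `value`.
#' @param path Output path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_trend_series <- function(ts, path, delim = ",") {
  ts <- as_trend_series(ts)
  out <- tibble::tibble(time = sprintf("%.17g", ts$time),
                        value = sprintf("%.17g", ts$value))
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Classify the spacing of a trend series
#'
#' A series is *regular* when it has exactly one observation per time point
#' and all consecutive time differences are equal (relative tolerance 1e-9);
#' otherwise it is *irregular*. Regular series are divided by the equal time
#' steps method, irregular ones by the different time steps method (see
#' [divide_series()]). The classification is invariant under affine
#' rescaling of the time axis.
#'
#' @param ts A [trend_series()] or data frame with `time` and `value`.
#' @return A one-row tibble with columns `kind` (`"regular"` or
#'   `"irregular"`) and `step` (the constant step when regular, else `NA`).
#' @examples
#' classify_spacing(data.frame(time = 1:7, value = rnorm(7)))
#' @export
classify_spacing <- function(ts) {
  ts <- as_trend_series(ts)
  n <- nrow(ts)
  if (n < 2L) {
    rlang::abort("spacing classification needs at least 2 observations.",
                 class = "smtrend_insufficient_data_error")
  }
  d <- diff(ts$time)
  span <- max(abs(ts$time))
  regular <- all(d > span * 1e-9) &&           # strictly increasing: unique
    (diff(range(d)) <= 1e-9 * max(abs(d)))     # constant step, rel tol 1e-9
  tibble::tibble(kind = if (regular) "regular" else "irregular",
                 step = if (regular) mean(d) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
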