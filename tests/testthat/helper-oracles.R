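# Independent brute-force oracles, kept deliberately distinct from the
# implementation's code paths (which use cor-style sums and stats::pt).

# coefficient of determination: direct transcription of the defining ratio
# of summed cross-products about the two means, written loop-style
oracle_r2 <- function(x, y) {
  n <- length(x)
  xm <- sum(x) / n
  ym <- sum(y) / n
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - xm) * (y[i] - ym)
    dx2 <- dx2 + (x[i] - xm)^2
    dy2 <- dy2 + (y[i] - ym)^2
  }
  num^2 / (dx2 * dy2)
}

# two-tailed Student-t tail probability by numeric integration of the
# hand-written density (no stats::pt / stats::dt)
oracle_p_two_tailed <- function(t_value, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_value, Inf, rel.tol = 1e-10)$value
}

# critical r2 by bisection on the p oracle (no stats::qt)
oracle_critical_r2 <- function(n, p_limit) {
  f <- function(r2) {
    t <- sqrt(r2 * (n - 2) / (1 - r2))
    oracle_p_two_tailed(t, n - 2) - p_limit
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# a small mixed corpus in long format for sensitivity / monotonicity checks
make_corpus <- function(n_series = 50, n = 40, seed = 1) {
  set.seed(seed)
  purrr::map_dfr(seq_len(n_series), function(i) {
    slope <- stats::runif(1, 0, 0.25)
    sd <- stats::runif(1, 0.5, 3)
    tibble::tibble(series = sprintf("s%02d", i), time = as.double(1:n),
                   value = slope * (1:n) + stats::rnorm(n, sd = sd))
  })
}
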