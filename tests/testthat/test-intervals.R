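ts7 <- function(y = 1:7) trend_series(data.frame(time = 1:7, value = y),
                                      quiet = TRUE)

test_that("equal-steps division reproduces the canonical n=7, k=3 weights", {
  # extract each observation's weights by probing with unit vectors
  W <- sapply(1:7, function(i) {
    y <- rep(0, 7); y[i] <- 1
    divide_equal_time_steps(ts7(y), 3)$mean * (7 / 3)
  })
  expected <- rbind(c(1, 1, 1 / 3, 0, 0, 0, 0),
                    c(0, 0, 2 / 3, 1, 2 / 3, 0, 0),
                    c(0, 0, 0, 0, 1 / 3, 1, 1))
  expect_equal(unname(W), expected, tolerance = 1e-12)

  im <- divide_equal_time_steps(ts7(), 3)
  expect_equal(im$mean, c(12 / 7, 4, 44 / 7), tolerance = 1e-12)
  expect_equal(im$support, rep(7 / 3, 3))
  expect_equal(attr(im, "empty_intervals"), 0L)
  # linear input gives exactly collinear, equally spaced means
  expect_equal(diff(im$mean), rep(16 / 7, 2), tolerance = 1e-12)
})

test_that("equal-steps division conserves weight and the grand mean", {
  set.seed(3)
  for (n in c(7, 12, 30, 101)) {
    y <- rnorm(n)
    ts <- trend_series(data.frame(time = seq_len(n), value = y), quiet = TRUE)
    for (k in c(3, 5, min(n, 13), n)) {
      im <- divide_equal_time_steps(ts, k)
      # support-weighted mean of means equals the grand mean
      expect_equal(sum(im$mean * im$support) / sum(im$support), mean(y),
                   tolerance = 1e-12)
      expect_equal(sum(im$support), n, tolerance = 1e-12)
      # per-observation weights sum to 1
      W <- sapply(seq_len(n), function(i) {
        e <- rep(0, n); e[i] <- 1
        ets <- trend_series(data.frame(time = seq_len(n), value = e),
                            quiet = TRUE)
        sum(divide_equal_time_steps(ets, k)$mean * (n / k))
      })
      expect_equal(W, rep(1, n), tolerance = 1e-12)
    }
  }
})

test_that("k = n equal-steps division is the identity", {
  set.seed(4)
  y <- rnorm(9)
  im <- divide_equal_time_steps(
    trend_series(data.frame(time = 1:9, value = y), quiet = TRUE), 9)
  expect_equal(im$mean, y)
  expect_equal(im$midpoint, as.double(1:9))
})

test_that("equal-steps division rejects irregular series and bad k", {
  irr <- generate_irregular_series(c(1, 3, 4, 5, 6, 8, 9), values = 1:7)
  expect_error(divide_equal_time_steps(irr, 3),
               class = "smtrend_method_mismatch_error")
  expect_error(divide_equal_time_steps(ts7(), 2),
               class = "smtrend_invalid_k_error")
  expect_error(divide_equal_time_steps(ts7(), 8),
               class = "smtrend_invalid_k_error")
})

test_that("different-steps division reproduces the canonical gapped example", {
  tm <- c(1, 3, 4, 5, 6, 8, 9)
  y <- c(2, 4, 3, 5, 7, 6, 8)
  irr <- generate_irregular_series(tm, values = y)
  im <- divide_different_time_steps(irr, 3)
  expect_equal(im$mean, c((2 + 4) / 2, (3 + 5 + 7) / 3, (6 + 8) / 2))
  expect_equal(im$support, c(2, 3, 2))
  # the inclusive integer-block reading groups identically here
  im2 <- divide_different_time_steps(irr, 3, integer_blocks = TRUE)
  expect_equal(im2$mean, im$mean)
  # support-weighted mean of means equals the grand mean
  expect_equal(sum(im$mean * im$support) / sum(im$support), mean(y),
               tolerance = 1e-12)
})

test_that("empty sub-ranges flag the division unusable rather than failing", {
  irr <- generate_irregular_series(c(1, 2, 9, 10), values = c(1, 2, 3, 4))
  im <- divide_different_time_steps(irr, 3)
  expect_equal(attr(im, "empty_intervals"), 1L)
  expect_true(is.na(im$mean[2]))
  expect_equal(im$support, c(2, 0, 2))
})

test_that("max_divisions caps by length, cap and empty-interval feasibility", {
  reg15 <- generate_trend_noise(15, 0.1, 1, seed = 5)
  expect_equal(max_divisions(reg15, cap = 30), 15L)
  reg1000 <- generate_trend_noise(1000, 0.1, 1, seed = 5)
  expect_equal(max_divisions(reg1000, cap = 30), 30L)
  # gapped series: k = 3 already leaves an empty sub-range
  gap <- generate_irregular_series(c(1, 2, 9, 10), values = 1:4)
  expect_error(max_divisions(gap, cap = 30),
               class = "smtrend_series_too_short_error")
  # mild gaps: the scan settles on the largest feasible k
  mild <- generate_irregular_series(c(1, 3, 4, 5, 6, 8, 9), values = 1:7)
  kmax <- max_divisions(mild, cap = 30)
  expect_gte(kmax, 3L)
  expect_equal(
    attr(divide_different_time_steps(mild, kmax), "empty_intervals"), 0L)
  if (kmax < 7) {
    expect_gt(
      attr(divide_different_time_steps(mild, kmax + 1L), "empty_intervals"), 0L)
  }
})

test_that("divide_series auto-selects the method from the spacing", {
  expect_equal(attr(divide_series(ts7(), 3), "method"), "equal_time_steps")
  irr <- generate_irregular_series(c(1, 3, 4, 5, 6, 8, 9), values = 1:7)
  expect_equal(attr(divide_series(irr, 3), "method"), "different_time_steps")
})
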