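test_that("a perfect linear trend is meaningful at every division count", {
  ts <- generate_trend_noise(30, slope = 2, noise_sd = 0, intercept = 1)
  fit <- test_meaningfulness(ts)
  expect_equal(fit$verdict, "meaningful")
  expect_true(fit$full_series_qualifies)
  expect_equal(fit$full_series$r_squared, 1)
  evaluated <- fit$per_division$k[!fit$per_division$skipped]
  expect_equal(fit$qualifying_divisions, evaluated)   # all k qualify
  expect_equal(fit$k_max_used, 30L)
})

test_that("a flat series is never meaningful", {
  ts <- trend_series(data.frame(time = 1:30, value = rep(5, 30)),
                     quiet = TRUE)
  fit <- test_meaningfulness(ts)
  expect_equal(fit$verdict, "not_meaningful")
  expect_length(fit$qualifying_divisions, 0)
  expect_false(fit$full_series_qualifies)
})

test_that("interval means can reveal a trend the full series hides", {
  # trend + strong high-frequency noise: weak full-series r2, but coarse
  # interval means align
  ts <- generate_trend_noise(200, slope = 0.05, noise_sd = 2.2, seed = 14)
  fit <- test_meaningfulness(ts)
  expect_lt(fit$full_series$r_squared, 0.65)
  small_k <- intersect(fit$qualifying_divisions, 3:7)
  expect_gt(length(small_k), 0)
  expect_equal(fit$verdict, "meaningful")
  # oracle at one qualifying k: manual division + lm regression
  k <- small_k[1]
  im <- divide_series(ts, k)
  man <- summary(lm(im$mean ~ im$midpoint))
  expect_gte(man$r.squared, 0.65)
  expect_lte(unname(coef(man)[2, 4]), 0.05)
  row <- fit$per_division[fit$per_division$k == k, ]
  expect_equal(row$r_squared, man$r.squared, tolerance = 1e-9)
})

test_that("k = n division reproduces the full-series statistics exactly", {
  ts <- generate_trend_noise(20, slope = 0.2, noise_sd = 1.5, seed = 8)
  fit <- test_meaningfulness(ts, k_max = 20)
  row <- fit$per_division[fit$per_division$k == 20, ]
  expect_equal(row$r_squared, fit$full_series$r_squared, tolerance = 1e-12)
  expect_equal(row$p_value, fit$full_series$p_value, tolerance = 1e-12)
})

test_that("the verdict is invariant under affine transforms of both axes", {
  set.seed(21)
  for (i in 1:8) {
    ts <- generate_trend_noise(40, slope = runif(1, -0.3, 0.3),
                               noise_sd = runif(1, 0.2, 3))
    base <- test_meaningfulness(ts)
    a <- runif(1, 0.1, 20); b <- runif(1, -100, 100)
    ta <- runif(1, 0.1, 5); tb <- runif(1, -50, 50)
    scaled <- data.frame(time = ta * ts$time + tb, value = a * ts$value + b)
    fit <- test_meaningfulness(scaled)
    expect_equal(fit$verdict, base$verdict)
    expect_equal(fit$qualifying_divisions, base$qualifying_divisions)
    expect_equal(fit$per_division$r_squared, base$per_division$r_squared,
                 tolerance = 1e-9)
  }
})

test_that("relaxing either threshold never revokes meaningfulness", {
  corpus <- make_corpus(n_series = 20, n = 35, seed = 31)
  for (lab in unique(corpus$series)) {
    g <- corpus[corpus$series == lab, ]
    strict <- test_meaningfulness(g, r2_min = 0.75, p_max = 0.02)
    mid <- test_meaningfulness(g)
    loose <- test_meaningfulness(g, r2_min = 0.55, p_max = 0.1)
    if (strict$verdict == "meaningful") {
      expect_equal(mid$verdict, "meaningful")
    }
    if (mid$verdict == "meaningful") {
      expect_equal(loose$verdict, "meaningful")
    }
    expect_true(all(strict$qualifying_divisions %in% mid$qualifying_divisions))
    expect_true(all(mid$qualifying_divisions %in% loose$qualifying_divisions))
  }
})

test_that("skipped divisions are recorded and do not decide the verdict", {
  # clustered sampling leaves some fine divisions with empty sub-ranges
  tm <- c(1, 1.1, 1.2, 4, 4.1, 4.2, 7, 7.1, 7.2, 10, 10.1, 10.2)
  irr <- generate_irregular_series(tm, values = tm * 2, label = "clustered")
  fit <- test_meaningfulness(irr, method = "different")
  expect_equal(fit$verdict, "meaningful")   # exact trend in the values
  expect_gt(sum(fit$per_division$skipped), 0)
  expect_true(all(!fit$per_division$qualifies[fit$per_division$skipped]))
})

test_that("the pure-noise false-positive rate reflects the uncorrected sweep", {
  # The verdict is a disjunction over ~28 correlated divisions with no
  # multiplicity correction, so the family-wise rate on pure noise sits
  # well above the nominal 5% — but far below the naive per-k sum.
  rec <- run_simulation(1000, n = 100, generator = "pure_noise",
                        constant = 1, sweep = 3:30, seed = 99)
  per_run <- dplyr::summarise(rec, q = any(qualifies), .by = "run")
  rate <- mean(per_run$q)
  expect_gt(rate, 0.05)
  expect_lt(rate, 0.25)
})

test_that("tidy and glance summarise the fit consistently", {
  ts <- generate_trend_noise(50, slope = 0.3, noise_sd = 1, seed = 2)
  fit <- test_meaningfulness(ts)
  td <- tidy(fit)
  expect_equal(nrow(td), 1 + nrow(fit$per_division))
  expect_true(is.na(td$k[1]))
  gl <- glance(fit)
  expect_equal(gl$n_qualifying, length(fit$qualifying_divisions))
  expect_equal(gl$meaningful, fit$verdict == "meaningful")
  expect_output(print(fit), "verdict")
})

test_that("sensitivity analysis yields nested meaningful sets", {
  corpus <- make_corpus(n_series = 15, n = 30, seed = 41)
  grid <- sensitivity_analysis(corpus,
                               r2_grid = c(0.85, 0.65, 0.55),
                               p_grid = c(0.01, 0.05, 0.1))
  expect_equal(nrow(grid), 9)
  # fixed p: meaningful set grows as r2_min drops
  for (p in c(0.01, 0.05, 0.1)) {
    s85 <- grid$meaningful[grid$p_max == p & grid$r2_min == 0.85][[1]]
    s65 <- grid$meaningful[grid$p_max == p & grid$r2_min == 0.65][[1]]
    s55 <- grid$meaningful[grid$p_max == p & grid$r2_min == 0.55][[1]]
    expect_true(all(s85 %in% s65))
    expect_true(all(s65 %in% s55))
  }
  # fixed r2: meaningful set grows as p_max rises
  for (r2 in c(0.85, 0.65, 0.55)) {
    s01 <- grid$meaningful[grid$r2_min == r2 & grid$p_max == 0.01][[1]]
    s05 <- grid$meaningful[grid$r2_min == r2 & grid$p_max == 0.05][[1]]
    s10 <- grid$meaningful[grid$r2_min == r2 & grid$p_max == 0.1][[1]]
    expect_true(all(s01 %in% s05))
    expect_true(all(s05 %in% s10))
  }
  # grid verdicts agree with direct per-limit test calls
  one <- corpus[corpus$series == "s01", ]
  direct <- test_meaningfulness(one, r2_min = 0.65, p_max = 0.05)
  in_set <- "s01" %in% grid$meaningful[grid$p_max == 0.05 &
                                         grid$r2_min == 0.65][[1]]
  expect_equal(in_set, direct$verdict == "meaningful")
})

test_that("a perfect line passes the sensitivity grid everywhere", {
  line <- tibble::tibble(series = "line", time = as.double(1:30),
                         value = 2 * (1:30) + 1)
  grid <- sensitivity_analysis(line, r2_grid = c(0.55, 0.65, 0.85),
                               p_grid = 0.05)
  expect_true(all(grid$n_meaningful == 1))
})

test_that("redundancy scan reports whether small divisions suffice", {
  ts <- generate_trend_noise(200, slope = 0.05, noise_sd = 2.2, seed = 14)
  fit <- test_meaningfulness(ts)
  expect_true(redundancy_scan(fit, 19))          # qualifiers are small-k
  flat <- test_meaningfulness(
    trend_series(data.frame(time = 1:30, value = rep(1, 30)), quiet = TRUE))
  expect_true(redundancy_scan(flat, 19))         # vacuously unchanged
  expect_error(redundancy_scan(fit, 2), class = "smtrend_domain_error")
})
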