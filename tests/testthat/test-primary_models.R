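test_that("Gompertz curve evaluates its anchors correctly", {
  # upper asymptote
  expect_equal(gompertz_eval(1e6, 6.5, 3.5, 0.8, 2), 10.0,
               tolerance = 1e-6)
  # lag boundary: logN0 + logNm * exp(-e), parameterization-independent
  expect_equal(gompertz_eval(2, 6.5, 3.5, 0.8, 2), 6.7310,
               tolerance = 1e-4)
  set.seed(5)
  for (i in 1:20) {
    p <- c(logN0 = runif(1, 3, 8), logNm = runif(1, 1, 5),
           mu_m = runif(1, 0.1, 3), lambda = runif(1, 0, 10))
    expect_equal(
      gompertz_eval(p["lambda"], p["logN0"], p["logNm"], p["mu_m"],
                    p["lambda"]),
      unname(p["logN0"] + p["logNm"] * exp(-exp(1))), tolerance = 1e-9,
      ignore_attr = TRUE)
  }
  # flat curve
  expect_equal(gompertz_eval(c(0, 5, 50), 6.5, 0, 0.8, 2), rep(6.5, 3))
})

test_that("Gompertz curve is non-decreasing and bounded", {
  set.seed(6)
  for (i in 1:20) {
    logN0 <- runif(1, 3, 8); logNm <- runif(1, 1, 5)
    mu <- runif(1, 0.1, 3); lam <- runif(1, 0, 10)
    t <- seq(0, 60, length.out = 200)
    y <- gompertz_eval(t, logN0, logNm, mu, lam)
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= logN0 - 1e-12 & y <= logN0 + logNm + 1e-12))
  }
})

test_that("Gompertz fit recovers noise-free parameters across the realistic range", {
  s <- exact_growth_series(6.5, 3.5, 0.8, 2)
  f <- fit_gompertz(s)
  expect_equal(coef(f),
               c(logN0 = 6.5, logNm = 3.5, mu_m = 0.8, lambda = 2),
               tolerance = 1e-4)
  expect_true(f$quality$accepted)
  expect_identical(f$quality$reason, "ok")

  # corners of the realistic parameter box; the sampling grid must cover
  # the exponential rise densely for the curve to be identifiable
  grid <- expand.grid(logNm = c(1, 5), mu_m = c(0.3, 3), lambda = c(0, 10))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    t_end <- p$lambda + 3 * p$logNm / p$mu_m
    times <- sort(unique(c(
      seq(0, t_end, length.out = 10),
      seq(max(p$lambda - 0.2 * p$logNm / p$mu_m, 0),
          p$lambda + 1.5 * p$logNm / p$mu_m, length.out = 10))))
    s <- exact_growth_series(6, p$logNm, p$mu_m, p$lambda, times = times)
    f <- fit_gompertz(s)
    expect_equal(coef(f),
                 c(logN0 = 6, logNm = p$logNm, mu_m = p$mu_m,
                   lambda = p$lambda),
                 tolerance = 1e-4)
  }
})

test_that("stagnant series are classified as no growth trend", {
  set.seed(303)
  for (i in 1:10) {
    y <- 6.0 + rnorm(8, 0, 0.2)
    f <- fit_gompertz(growth_series(seq(0, 21, 3), y, 4))
    expect_identical(f$quality$reason, "no_growth_trend")
    expect_false(f$quality$accepted)
  }
})

test_that("Gompertz fit rejects too-short series", {
  expect_error(fit_gompertz(growth_series(c(0, 5, 10), c(6, 7, 8), 4)),
               "at least 4")
})

test_that("growth-rate recovery under measurement noise is accurate", {
  set.seed(404)
  tt <- seq(0, 24, length.out = 7)
  mu_truth <- 0.4
  rel_err <- replicate(200, {
    y <- gompertz_eval(tt, 6.5, 3.5, mu_truth, 2) + rnorm(7, 0, 0.2)
    f <- fit_gompertz(growth_series(tt, y, 4))
    abs(f$mu_m - mu_truth) / mu_truth
  })
  expect_lt(median(rel_err), 0.20)
})

test_that("zero-order model evaluates and inverts hand values", {
  expect_equal(zero_order_eval(0, 8, 0.12), 8)
  expect_equal(zero_order_eval(10, 8, 0.12), 6.8)
  expect_equal(zero_order_eval(100, 8, 0), 8)
  expect_equal(zero_order_eval(10, 5, 0.1, "increasing"), 6)
})

test_that("zero-order fit equals closed-form OLS and recovers exact lines", {
  s <- sensory_series(c(0, 10, 20), c(8, 6.8, 5.6), 4)
  f <- fit_zero_order(s)
  expect_equal(f$S0, 8, tolerance = 1e-9)
  expect_equal(f$k_s, 0.12, tolerance = 1e-9)
  expect_identical(f$direction, "decreasing")

  # constant series: zero rate
  f0 <- fit_zero_order(sensory_series(c(0, 5, 10, 15), rep(7, 4), 4))
  expect_equal(f0$k_s, 0)

  # textbook OLS cross-check on arbitrary data
  set.seed(505)
  t <- sort(runif(8, 0, 30)); y <- pmin(pmax(8 - 0.1 * t +
    rnorm(8, 0, 0.3), 1), 9)
  f <- fit_zero_order(sensory_series(t, y, 4))
  beta <- cov(t, y) / var(t)
  alpha <- mean(y) - beta * mean(t)
  expect_equal(f$k_s, abs(beta), tolerance = 1e-12)
  expect_equal(f$S0, alpha, tolerance = 1e-12)

  expect_error(fit_zero_order(sensory_series(c(0, 5), c(8, 7), 4)),
               "at least 3")
})

test_that("zero-order intercept is unbiased under panel noise", {
  set.seed(606)
  tt <- seq(0, 25, length.out = 6)
  est <- replicate(200, {
    y <- pmin(pmax(8 - 0.12 * tt + rnorm(6, 0, 0.3), 1), 9)
    f <- fit_zero_order(sensory_series(tt, y, 4))
    c(f$S0, f$k_s)
  })
  expect_lt(abs(mean(est[1, ]) - 8), 3 * sd(est[1, ]) / sqrt(200))
  expect_lt(abs(mean(est[2, ]) - 0.12), 3 * sd(est[2, ]) / sqrt(200))
})
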