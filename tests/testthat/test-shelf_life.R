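test_that("sensory shelf life inverts the zero-order model", {
  expect_equal(shelf_life_sensory(8, 0.12, 4), 25.0)
  # already at the rejection score
  sl0 <- shelf_life_sensory(5, 0.12, 4)
  expect_equal(as.numeric(sl0), 0)
  expect_identical(attr(sl0, "flag"), "already_rejected")
  # homogeneity: doubling the rate halves the shelf life
  set.seed(11)
  for (i in 1:10) {
    S0 <- runif(1, 5.5, 9); ks <- runif(1, 0.05, 1)
    expect_equal(shelf_life_sensory(S0, 2 * ks, 4),
                 shelf_life_sensory(S0, ks, 4) / 2, tolerance = 1e-12)
  }
})

test_that("microbial shelf life applies the linear-growth-plus-lag formula", {
  expect_equal(shelf_life_microbial(6.5, 0.5, 1.0, 4), 3.0)
  expect_equal(shelf_life_microbial(6.5, 1, 0, 4), 1.0)
  # no growth: the distinguished stable value
  slm <- shelf_life_microbial(6.5, 0, NULL, 4)
  expect_identical(as.numeric(slm), Inf)
  expect_identical(attr(slm, "flag"), "stable")
  # already over the limit
  sl0 <- shelf_life_microbial(8, 0.5, 0, 4)
  expect_equal(as.numeric(sl0), 0)
  expect_identical(attr(sl0, "flag"), "already_rejected")
})

test_that("combined shelf life is the minimum with a microbial tie-break", {
  r <- combined_shelf_life(25, 3, 4)
  expect_equal(r$sl_combined, 3)
  expect_identical(r$limiting_mode, "microbial")

  # microbially stable product: sensory-limited
  r2 <- combined_shelf_life(20, Inf, 4)
  expect_equal(r2$sl_combined, 20)
  expect_identical(r2$limiting_mode, "sensory")

  # ties resolve conservatively to the microbial endpoint
  r3 <- combined_shelf_life(10, 10, 4)
  expect_identical(r3$limiting_mode, "microbial")

  expect_true(r$sl_combined <= r$sl_sensory)
  expect_true(r$sl_combined <= r$sl_microbial)
})

test_that("shelf life decreases strictly with temperature when Ea > 0", {
  mu <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.4, 80000))
  ks <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.12, 60000))
  temps <- seq(2, 24, by = 2)
  sls <- vapply(temps, function(Tc) shelf_life_sensory(8, ks, Tc), 0)
  slm <- vapply(temps, function(Tc)
    as.numeric(shelf_life_microbial(6.5, mu, NULL, Tc)), 0)
  expect_true(all(diff(sls) < 0))
  expect_true(all(diff(slm) < 0))
})

test_that("profile rule reduces to the constant-temperature shelf life", {
  ks <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.12, 60000))
  mu <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.4, 80000))
  const <- temperature_profile(1000, 8)
  r <- shelf_life_under_profile(const, S0 = 8, ks_model = ks,
                                logN0 = 6.5, mu_model = mu)
  expect_equal(r$sl_sensory, shelf_life_sensory(8, ks, 8), tolerance = 1e-9)
  expect_equal(r$sl_microbial,
               as.numeric(shelf_life_microbial(6.5, mu, NULL, 8)),
               tolerance = 1e-9)
})

test_that("fraction-consumed rule reproduces the two-segment hand value", {
  # constant rates chosen so SL(T1) = 10 d and SL(T2) = 5 d
  ks <- fit_arrhenius(c(4, 12), c((8 - 5) / 10, (8 - 5) / 5))
  prof <- temperature_profile(c(5, 100), c(4, 12))
  r <- shelf_life_under_profile(prof, S0 = 8, ks_model = ks,
                                logN0 = 6.5, mu_model = NULL)
  # half consumed in segment 1, remaining half takes 2.5 d at SL = 5
  expect_equal(r$sl_sensory, 7.5, tolerance = 1e-9)
  expect_identical(r$limiting_mode, "sensory")
})

test_that("splitting a constant segment does not change the profile result", {
  ks <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.12, 60000))
  p1 <- temperature_profile(c(6, 4, 30), c(4, 15, 8))
  p2 <- temperature_profile(c(6, 2, 2, 15, 15), c(4, 15, 15, 8, 8))
  r1 <- shelf_life_under_profile(p1, 8, ks, 6.5, NULL)
  r2 <- shelf_life_under_profile(p2, 8, ks, 6.5, NULL)
  expect_equal(r1$sl_sensory, r2$sl_sensory, tolerance = 1e-9)
})

test_that("reordering segments preserves whether the profile is survived", {
  ks <- fit_arrhenius(c(4, 12, 20), arrhenius_eval(c(4, 12, 20), 0.12, 60000))
  p <- temperature_profile(c(10, 8, 6), c(4, 20, 10))
  perm <- temperature_profile(c(6, 10, 8), c(10, 4, 20))
  r <- shelf_life_under_profile(p, 8, ks, 6.5, NULL)
  rp <- shelf_life_under_profile(perm, 8, ks, 6.5, NULL)
  expect_identical(is.finite(r$sl_sensory), is.finite(rp$sl_sensory))
})

test_that("profile validation rejects empty or non-positive segments", {
  expect_error(temperature_profile(numeric(0), numeric(0)), "duration")
  expect_error(temperature_profile(c(5, 0), c(4, 8)), "> 0")
})

test_that("full Gompertz inversion reaches the limit and brackets the linear rule", {
  # inversion accuracy: the curve value at the root equals the limit
  set.seed(21)
  for (i in 1:20) {
    logN0 <- 6.5; logNm <- runif(1, 2, 5)
    mu <- runif(1, 0.2, 2); lam <- runif(1, 0, 5)
    lim <- logN0 + runif(1, 0.3, 0.9) * logNm
    t_star <- invert_gompertz_time_to_limit(logN0, logNm, mu, lam, lim)
    expect_lt(abs(gompertz_eval(t_star, logN0, logNm, mu, lam) - lim), 1e-5)
  }

  # asymptote below the limit: never crossed
  expect_identical(invert_gompertz_time_to_limit(6.5, 0.5, 0.8, 2, 7.5), Inf)
  expect_identical(invert_gompertz_time_to_limit(8, 2, 0.8, 2, 7.5), 0)

  # linear approximation vs full inversion on the default parameter grid
  truth <- truth_config()
  for (Tc in truth$temps_c) {
    mu <- mu_true(truth, Tc); lam <- lambda_true(truth, Tc)
    sl_lin <- shelf_life_microbial(truth$logN0, mu, lam, Tc)
    t_star <- invert_gompertz_time_to_limit(truth$logN0, truth$logNm, mu,
                                            lam, 7.5)
    expect_lt(abs(sl_lin - t_star) / t_star, 0.25)
  }
})
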