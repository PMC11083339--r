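test_that("simulation is deterministic in (truth, seed)", {
  tr <- truth_config()
  expect_identical(simulate_od_series(tr, 3), simulate_od_series(tr, 3))
  expect_identical(simulate_growth_curves(tr, 3),
                   simulate_growth_curves(tr, 3))
  expect_identical(simulate_sensory_series(tr, 3),
                   simulate_sensory_series(tr, 3))
  # different seeds: different data, same shape
  a <- simulate_od_series(tr, 3); b <- simulate_od_series(tr, 4)
  expect_false(identical(a$wl, b$wl))
  expect_identical(dim(a), dim(b))
})

test_that("noise-free simulation closes the loop for every fit stage", {
  tr <- truth_config(sd_wl = 0, sd_sg = 0, sd_logN = 0, sd_score = 0)

  s <- simulate_od_series(tr, 1)
  expect_equal(fit_penetration(s, "wl")$k, tr$k_wl, tolerance = 1e-9)
  expect_equal(fit_penetration(s, "sg")$k, tr$k_sg, tolerance = 1e-9)

  growth <- simulate_growth_curves(tr, 1)
  fits <- lapply(growth, fit_gompertz)
  mu_hat <- vapply(fits, `[[`, 0, "mu_m")
  af <- fit_arrhenius(tr$temps_c, mu_hat, tr$T_ref_celsius)
  expect_equal(af$k_ref, tr$mu_ref, tolerance = 1e-3)
  expect_equal(af$Ea, tr$Ea_mu, tolerance = 1e-3 * tr$Ea_mu)

  sens <- simulate_sensory_series(tr, 1)
  zf <- lapply(sens, fit_zero_order)
  expect_equal(vapply(zf, `[[`, 0, "S0"), rep(tr$S0, 3), tolerance = 1e-9)
  ks_hat <- vapply(zf, `[[`, 0, "k_s")
  expect_equal(ks_hat, ks_true(tr, tr$temps_c), tolerance = 1e-9)
})

test_that("simulated values respect physical ranges", {
  tr <- truth_config(sd_score = 2, sd_logN = 0.5)  # exaggerated noise
  sens <- simulate_sensory_series(tr, 9)
  for (s in sens) expect_true(all(s$score >= 1 & s$score <= 9))
  growth <- simulate_growth_curves(tr, 9)
  for (g in growth) expect_true(all(g$logN >= 0))
  od <- simulate_od_series(tr, 9)
  expect_equal(od$wl[1], 0)
  expect_equal(od$sg[1], 0)
})

test_that("strong decay clamps panel scores at the floor and flags the series", {
  tr <- truth_config(ks_ref = 2, sd_score = 0.3,
                     sensory_days = seq(0, 6, by = 1))
  sens <- simulate_sensory_series(tr, 2)
  clamped <- vapply(sens, function(s) isTRUE(attr(s, "range_limited")),
                    TRUE)
  expect_true(any(clamped))
  expect_true(all(vapply(sens, function(s) min(s$score) >= 1, TRUE)))
})

test_that("stagnant truth yields series all classified no growth trend", {
  tr <- truth_config(logNm = 0)
  growth <- simulate_growth_curves(tr, 5)
  for (g in growth) {
    f <- fit_gompertz(g)
    expect_identical(f$quality$reason, "no_growth_trend")
  }
})

test_that("penetration-constant sampling variability matches the OLS formula", {
  tr <- truth_config(k_wl = 0.5 / sqrt(60), sd_wl = 0.1)
  k_hat <- vapply(1:500, function(i)
    fit_penetration(simulate_od_series(tr, i), "wl")$k, 0)
  analytic_sd <- tr$sd_wl / sqrt(sum(60 * tr$od_minutes[-1]))
  expect_lt(abs(sd(k_hat) - analytic_sd) / analytic_sd, 0.15)
})

test_that("a full simulated study round-trips through the readers", {
  outdir <- withr::local_tempdir()
  truths <- list(truth_config(label = "od_60"),
                 truth_config(logNm = 0, label = "pef_od"))
  paths <- simulate_study(truths, outdir = outdir, seed = 11)
  expect_true(all(file.exists(paths)))

  od <- read_od_masses(paths[["od_masses"]])
  expect_setequal(unique(od$treatment), c("od_60", "pef_od"))
  # masses invert back to the simulated water loss / solid gain
  d <- od[od$treatment == "od_60", ]
  ser <- simulate_od_series(truths[[1]], 11)
  wl_back <- suppressWarnings(
    compute_water_loss(d$m0_g, d$m_wet_g, d$m_dry_g, d$dw_wb))
  expect_equal(wl_back, ser$wl, tolerance = 1e-9)

  tvc <- read_storage_tvc(paths[["storage_tvc"]])
  expect_setequal(unique(tvc$temp_c), truths[[1]]$temps_c)
  sens <- read_storage_sensory(paths[["storage_sensory"]])
  expect_true(all(sens$score >= 1 & sens$score <= 9))
  col <- read_color(paths[["color"]])
  expect_true(all(c("L", "a", "b") %in% names(col)))

  # same seed reproduces the files byte-for-byte
  outdir2 <- withr::local_tempdir()
  paths2 <- simulate_study(truths, outdir = outdir2, seed = 11)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
  }
})
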