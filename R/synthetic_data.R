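#' Ground-truth configuration for a synthetic shelf-life study
#'
#' Bundles the true generating parameters for one treatment: penetration
#' constants for the osmotic-dehydration stage, Gompertz growth truth with
#' an Arrhenius temperature law for `mu_m` (and optionally for `1/lambda`),
#' zero-order sensory truth with its own Arrhenius law, Gaussian noise
#' levels, and the sampling design.
#'
#' Defaults emulate a chilled leafy-green study: initial load 6.5 log10
#' CFU/g growing by ~3.5 log to the stationary phase, growth rate 0.4 /day
#' at the 4 degC reference with an 80 kJ/mol activation energy, initial
#' hedonic score 8 decaying at 0.12 /day at 4 degC (60 kJ/mol), storage at
#' 4/12/20 degC, osmotic sampling at 0-120 min, and measurement noise of
#' 0.2 log10 CFU/g (plate counts) and 0.3 score units (panel).
#'
#' @param k_wl,k_sg True penetration constants, g/(g DW s^0.5).
#' @param sd_wl,sd_sg Gaussian noise on water loss / solid gain, g/g DW.
#' @param od_minutes Osmotic-dehydration sampling grid, minutes.
#' @param m0_g,dw_wb Initial wet mass (g) and dry-weight fraction used when
#'   materializing gravimetric data.
#' @param logN0,logNm True initial load and maximum increase, log10 CFU/g.
#'   `logNm = 0` gives a stagnant (no-growth) treatment.
#' @param mu_ref,Ea_mu Growth rate at `T_ref_celsius` (log10 CFU/g/day) and
#'   its activation energy (J/mol).
#' @param lambda_ref,Ea_lag Lag at `T_ref_celsius` (days) and the activation
#'   energy of `1/lambda`; `lambda_ref = 0` disables the lag.
#' @param sd_logN Gaussian noise on counts, log10 CFU/g.
#' @param S0 True initial sensory score (1-9).
#' @param ks_ref,Ea_ks Sensory decay rate at `T_ref_celsius` (score/day) and
#'   its activation energy (J/mol).
#' @param sd_score Gaussian noise on scores, score units.
#' @param temps_c Storage temperatures, deg C (distinct).
#' @param n_days Number of sampling days per storage series.
#' @param growth_days,sensory_days Optional explicit sampling grids (days)
#'   used at every temperature; `NULL` (default) spans each curve
#'   adaptively: lag + rise + early stationary phase for growth, decay to
#'   deep rejection for sensory.
#' @param T_ref_celsius Reference temperature for the Arrhenius truths.
#' @param label Treatment label string.
#' @return A `truth_config` list.
#' @export
truth_config <- function(k_wl = 0.0461, k_sg = 0.012,
                         sd_wl = 0.10, sd_sg = 0.05,
                         od_minutes = c(0, 20, 40, 60, 90, 120),
                         m0_g = 5, dw_wb = 0.10,
                         logN0 = 6.5, logNm = 3.5,
                         mu_ref = 0.4, Ea_mu = 80000,
                         lambda_ref = 2, Ea_lag = 60000,
                         sd_logN = 0.2,
                         S0 = 8, ks_ref = 0.12, Ea_ks = 60000,
                         sd_score = 0.3,
                         temps_c = c(4, 12, 20), n_days = 7,
                         growth_days = NULL, sensory_days = NULL,
                         T_ref_celsius = 4,
                         label = "od_60") {
  stopifnot(sd_wl >= 0, sd_sg >= 0, sd_logN >= 0, sd_score >= 0,
            logNm >= 0, mu_ref > 0, ks_ref > 0, lambda_ref >= 0,
            S0 >= 1, S0 <= 9, n_days >= 4)
  if (anyDuplicated(temps_c)) stop("temperatures must be distinct",
                                   call. = FALSE)
  structure(
    list(k_wl = k_wl, k_sg = k_sg, sd_wl = sd_wl, sd_sg = sd_sg,
         od_minutes = od_minutes, m0_g = m0_g, dw_wb = dw_wb,
         logN0 = logN0, logNm = logNm, mu_ref = mu_ref, Ea_mu = Ea_mu,
         lambda_ref = lambda_ref, Ea_lag = Ea_lag, sd_logN = sd_logN,
         S0 = S0, ks_ref = ks_ref, Ea_ks = Ea_ks, sd_score = sd_score,
         temps_c = temps_c, n_days = n_days,
         growth_days = growth_days, sensory_days = sensory_days,
         T_ref_celsius = T_ref_celsius, label = label),
    class = "truth_config"
  )
}

#' True growth rate / lag / sensory rate implied by a truth config
#'
#' @param truth A [truth_config()].
#' @param T_celsius Temperature(s), deg C.
#' @return `mu_true`, `lambda_true`, `ks_true` give the generating values at
#'   a temperature.
#' @name truth-values
NULL

#' @rdname truth-values
#' @export
mu_true <- function(truth, T_celsius) {
  arrhenius_eval(T_celsius, truth$mu_ref, truth$Ea_mu, truth$T_ref_celsius)
}

#' @rdname truth-values
#' @export
lambda_true <- function(truth, T_celsius) {
  if (truth$lambda_ref <= 0) return(rep(0, length(T_celsius)))
  1 / arrhenius_eval(T_celsius, 1 / truth$lambda_ref, truth$Ea_lag,
                     truth$T_ref_celsius)
}

#' @rdname truth-values
#' @export
ks_true <- function(truth, T_celsius) {
  arrhenius_eval(T_celsius, truth$ks_ref, truth$Ea_ks, truth$T_ref_celsius)
}

#' Simulate an osmotic-dehydration kinetics series
#'
#' Forward model: `WL = k_wl * sqrt(t_seconds) + N(0, sd_wl)` and the
#' analogue for solid gain, on the configured minute grid. The t = 0 point
#' is exactly (0, 0): the untouched sample has lost and gained nothing.
#'
#' @param truth A [truth_config()].
#' @param seed Integer seed; identical (truth, seed) give identical output.
#' @return An [od_series()].
#' @export
simulate_od_series <- function(truth, seed = 1) {
  set.seed(seed)
  t_min <- truth$od_minutes
  sqrt_t <- sqrt(60 * t_min)
  wl <- truth$k_wl * sqrt_t + stats::rnorm(length(t_min), 0, truth$sd_wl)
  sg <- truth$k_sg * sqrt_t + stats::rnorm(length(t_min), 0, truth$sd_sg)
  wl[t_min == 0] <- 0
  sg[t_min == 0] <- 0
  od_series(t_min, wl, sg,
            treatment = treatment_label(0.6, 0, 0))
}

growth_sampling_days <- function(truth, T_celsius) {
  if (!is.null(truth$growth_days)) return(truth$growth_days)
  if (truth$logNm <= 0 || truth$mu_ref <= 0) {
    return(seq(0, 24, length.out = truth$n_days))
  }
  # span lag + rise + early stationary phase at this temperature
  t_end <- lambda_true(truth, T_celsius) +
    2.5 * truth$logNm / mu_true(truth, T_celsius)
  seq(0, t_end, length.out = truth$n_days)
}

#' Simulate per-temperature microbial growth curves
#'
#' For each storage temperature, `mu_m` (and the lag, if configured) is set
#' from the Arrhenius truth and counts are drawn as
#' `gompertz_eval(t) + N(0, sd_logN)`, on a sampling grid spanning lag,
#' exponential rise and early stationary phase. With `logNm = 0` every
#' series is stagnant at `logN0` plus noise (the heavily hurdled regime).
#'
#' @param truth A [truth_config()].
#' @param seed Integer seed.
#' @return A list of [growth_series()], one per temperature.
#' @export
simulate_growth_curves <- function(truth, seed = 1) {
  set.seed(seed)
  lapply(truth$temps_c, function(Tc) {
    days <- growth_sampling_days(truth, Tc)
    mu <- if (truth$logNm > 0) mu_true(truth, Tc) else 0
    lam <- lambda_true(truth, Tc)
    y <- if (truth$logNm > 0) {
      gompertz_eval(days, truth$logN0, truth$logNm, mu, lam)
    } else rep(truth$logN0, length(days))
    y <- pmax(y + stats::rnorm(length(days), 0, truth$sd_logN), 0)
    growth_series(days, y, temperature = Tc)
  })
}

sensory_sampling_days <- function(truth, T_celsius) {
  if (!is.null(truth$sensory_days)) return(truth$sensory_days)
  # span the decay down to deep rejection (score ~ 4) at this temperature
  t_end <- (truth$S0 - 4) / ks_true(truth, T_celsius)
  seq(0, t_end, length.out = truth$n_days)
}

#' Simulate per-temperature sensory series
#'
#' Scores are drawn as `S0 - ks(T) * t + N(0, sd_score)` and clamped to the
#' 1-9 hedonic scale (the panel cannot score outside it; clamping exists
#' only here, never in the fitted model). If any value was clamped the
#' series carries attribute `range_limited = TRUE`.
#'
#' @param truth A [truth_config()].
#' @param seed Integer seed.
#' @return A list of [sensory_series()], one per temperature.
#' @export
simulate_sensory_series <- function(truth, seed = 1) {
  set.seed(seed)
  lapply(truth$temps_c, function(Tc) {
    days <- sensory_sampling_days(truth, Tc)
    raw <- zero_order_eval(days, truth$S0, ks_true(truth, Tc)) +
      stats::rnorm(length(days), 0, truth$sd_score)
    sc <- pmin(pmax(raw, 1), 9)
    s <- sensory_series(days, sc, temperature = Tc)
    attr(s, "range_limited") <- any(sc != raw)
    s
  })
}

#' Simulate a complete study and write its input files
#'
#' Materializes everything a real study would hand the pipeline: gravimetric
#' osmotic-dehydration data (`od_masses.csv`, masses back-computed from the
#' simulated water loss / solid gain so the mass identities hold exactly),
#' storage trials (`storage_tvc.csv`, `storage_sensory.csv`), replicate
#' CIELab readings (`color.csv`), and the generating truth (`truth.json`).
#' One treatment per truth config; pass several configs to emulate
#' untreated / OD / PEF-OD arms.
#'
#' @param truths A [truth_config()] or a list of them.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Invisibly, the named vector of file paths written.
#' @export
simulate_study <- function(truths = truth_config(), outdir, seed = 1) {
  if (inherits(truths, "truth_config")) truths <- list(truths)
  stopifnot(length(truths) >= 1)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  od_rows <- list(); tvc_rows <- list(); sens_rows <- list()
  col_rows <- list()
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    sd_off <- (i - 1L) * 1000L
    ser <- simulate_od_series(tr, seed + sd_off)
    # invert WL/SG to wet/dry masses (exact inverse of the mass equations)
    m_dry <- tr$dw_wb * tr$m0_g * (1 + ser$sg)
    m_wet <- m_dry + tr$m0_g * (1 - tr$dw_wb) - ser$wl * tr$m0_g * tr$dw_wb
    od_rows[[i]] <- data.frame(
      treatment = tr$label, time_min = ser$time_min,
      m0_g = tr$m0_g, m_wet_g = m_wet, m_dry_g = m_dry,
      dw_wb = tr$dw_wb)

    growth <- simulate_growth_curves(tr, seed + sd_off + 1L)
    tvc_rows[[i]] <- do.call(rbind, lapply(growth, function(g) {
      data.frame(treatment = tr$label, temp_c = attr(g, "temperature"),
                 time_d = g$time_d, log_cfu_g = g$logN)
    }))

    sens <- simulate_sensory_series(tr, seed + sd_off + 2L)
    sens_rows[[i]] <- do.call(rbind, lapply(sens, function(s) {
      data.frame(treatment = tr$label, temp_c = attr(s, "temperature"),
                 time_d = s$time_d, attribute = attr(s, "attribute"),
                 score = s$score)
    }))

    set.seed(seed + sd_off + 3L)
    col_rows[[i]] <- do.call(rbind, lapply(tr$temps_c, function(Tc) {
      days <- sensory_sampling_days(tr, Tc)
      do.call(rbind, lapply(days, function(d) {
        # slow darkening/yellowing drift with replicate reading noise
        data.frame(treatment = tr$label, temp_c = Tc, time_d = d,
                   replicate = 1:3,
                   L = pmin(pmax(45 - 0.15 * d + stats::rnorm(3, 0, 1),
                                 0), 100),
                   a = -14 + 0.10 * d + stats::rnorm(3, 0, 0.5),
                   b = 20 + 0.12 * d + stats::rnorm(3, 0, 0.5))
      }))
    }))
  }

  paths <- c(od_masses = file.path(outdir, "od_masses.csv"),
             storage_tvc = file.path(outdir, "storage_tvc.csv"),
             storage_sensory = file.path(outdir, "storage_sensory.csv"),
             color = file.path(outdir, "color.csv"),
             truth = file.path(outdir, "truth.json"))
  utils::write.csv(do.call(rbind, od_rows), paths[["od_masses"]],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, tvc_rows), paths[["storage_tvc"]],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, sens_rows), paths[["storage_sensory"]],
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, col_rows), paths[["color"]],
                   row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(lapply(truths, unclass),
                    vapply(truths, `[[`, "", "label")),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
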