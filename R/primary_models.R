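#' Evaluate the modified Gompertz growth curve
#'
#' The Zwietering reparameterization of the Gompertz sigmoid for microbial
#' growth on the log10 scale,
#' \deqn{\log N(t) = \log N_0 + \log N_m \exp\!\left(-\exp\!\left(
#'   \frac{\mu_m e}{\log N_m}(\lambda - t) + 1\right)\right),}
#' where `logN0` is the initial load (log10 CFU/g), `logNm` the maximum
#' increase over the initial load, `mu_m` the exponential growth rate
#' (log10 CFU/g per day) and `lambda` the lag phase (days). For
#' `logNm = 0` the curve is flat at `logN0`.
#'
#' @param t Time, days.
#' @param logN0 Initial load, log10 CFU/g.
#' @param logNm Maximum increase over initial load, log10 CFU/g (>= 0).
#' @param mu_m Exponential growth rate, log10 CFU/g per day (>= 0).
#' @param lambda Lag phase, days (>= 0).
#' @return log10 CFU/g at each `t`.
#' @export
#' @examples
#' gompertz_eval(c(0, 2, 10, 1e6), logN0 = 6.5, logNm = 3.5,
#'               mu_m = 0.8, lambda = 2)
gompertz_eval <- function(t, logN0, logNm, mu_m, lambda) {
  stopifnot(logNm >= 0, mu_m >= 0, lambda >= 0)
  if (logNm == 0) return(rep(logN0, length(t)))
  logN0 + logNm * exp(-exp((mu_m * exp(1) / logNm) * (lambda - t) + 1))
}

#' Construct a per-temperature growth series
#'
#' @param time_d Sampling times, days, strictly increasing.
#' @param logN Total viable counts, log10 CFU/g.
#' @param temperature Storage temperature, deg C.
#' @return A `growth_series` data.frame with the temperature attached.
#' @export
growth_series <- function(time_d, logN, temperature) {
  stopifnot(length(time_d) == length(logN))
  if (is.unsorted(time_d, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(time_d < 0)) stop("times must be >= 0", call. = FALSE)
  structure(data.frame(time_d = time_d, logN = logN),
            temperature = temperature,
            class = c("growth_series", "data.frame"))
}

#' Fit the modified Gompertz model to a total-viable-count series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, `minpack.lm`) of
#' [gompertz_eval()] with `logNm, mu_m, lambda >= 0`. Starting values:
#' `logN0` from the first observation, `logNm` from the observed amplitude,
#' `mu_m` from the steepest pairwise finite-difference slope, and `lambda`
#' from the time-intercept of the tangent at the steepest segment (floored
#' at 0).
#'
#' The fit is classified (`quality$reason`):
#' * `no_growth_trend` - the fitted rate is not distinguishable from zero
#'   (`mu_m <= 2 se`) or the observed amplitude is below 0.5 log10 CFU/g.
#'   This is the regime seen in heavily hurdled samples whose counts stay
#'   stagnant throughout storage.
#' * `poor_fit` - r2 below `r2_min` (default 0.7).
#' * `ok` - otherwise.
#'
#' `lambda` is additionally flagged unreliable when its standard error
#' exceeds its value, a common outcome for chilled leafy produce where the
#' lag is poorly identified.
#'
#' @param series A [growth_series()] with at least 4 points.
#' @param r2_min Acceptance threshold on r2.
#' @return A `gompertz_fit`: parameter estimates, standard errors, `r2`,
#'   `quality` (list with `accepted` and `reason`), `lambda_reliable`, and
#'   the temperature of the series.
#' @export
fit_gompertz <- function(series, r2_min = 0.7) {
  if (nrow(series) < 4) {
    stop("insufficient data: need at least 4 points", call. = FALSE)
  }
  t <- series$time_d
  y <- series$logN
  amplitude <- max(y) - min(y)

  # initialization
  logN0_0 <- y[1]
  logNm_0 <- max(max(y) - y[1], 0.1)
  slopes <- diff(y) / diff(t)
  i <- which.max(slopes)
  mu_0 <- max(slopes[i], 0.01)
  # tangent through the midpoint of the steepest segment, floored at 0
  tm <- (t[i] + t[i + 1]) / 2
  ym <- (y[i] + y[i + 1]) / 2
  lambda_0 <- max(tm - (ym - logN0_0) / mu_0, 0)

  # multi-start bounded Levenberg-Marquardt: the surface is flat near
  # logNm = 0 and near parameter collinearity at zero residual, so try a
  # ladder of starts and keep the best converged solution
  resid_fun <- function(p) y - gompertz_eval(t, p[1], p[2], p[3], p[4])
  starts <- list(
    c(logN0 = logN0_0, logNm = logNm_0, mu_m = mu_0, lambda = lambda_0),
    c(logN0 = logN0_0, logNm = max(amplitude, 0.5),
      mu_m = max(amplitude, 0.5) / max(diff(range(t)), 1), lambda = 0),
    c(logN0 = mean(y), logNm = 1, mu_m = 0.5,
      lambda = diff(range(t)) / 4)
  )
  best <- NULL
  for (st in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fun,
        lower = c(-Inf, 0, 0, 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(out) && out$info %in% 1:4 &&
        (is.null(best) || out$deviance < best$deviance)) {
      best <- out
    }
  }

  if (is.null(best)) {
    # unidentifiable on trendless data: declare no growth trend when the
    # amplitude is small or there is no significant linear trend either
    lfit <- suppressWarnings(summary(stats::lm(y ~ t)))$coefficients
    no_lin_trend <- lfit["t", "Estimate"] <= 2 * lfit["t", "Std. Error"]
    if (amplitude < 0.5 || no_lin_trend) {
      return(new_gompertz_fit(
        est = c(logN0 = mean(y), logNm = 0, mu_m = 0, lambda = 0),
        se = c(logN0 = stats::sd(y) / sqrt(length(y)), logNm = NA,
               mu_m = NA, lambda = NA),
        r2 = NA_real_, quality = "no_growth_trend",
        temperature = attr(series, "temperature")))
    }
    stop("Gompertz fit failed to converge from any start", call. = FALSE)
  }

  est <- best$par
  names(est) <- c("logN0", "logNm", "mu_m", "lambda")
  se <- tryCatch(
    suppressWarnings(summary(best)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, 4))
  names(se) <- names(est)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - best$deviance / ss_tot else NA_real_

  # growth is demonstrated only by a rate significantly above zero on a
  # non-flat fitted curve; an inestimable se cannot demonstrate it
  flat_fit <- est[["logNm"]] < 1e-8 || est[["mu_m"]] < 1e-8
  growth_significant <- is.finite(se[["mu_m"]]) &&
    est[["mu_m"]] > 2 * se[["mu_m"]]
  reason <- "ok"
  if (amplitude < 0.5 || flat_fit || !growth_significant) {
    reason <- "no_growth_trend"
  } else if (!is.na(r2) && r2 < r2_min) {
    reason <- "poor_fit"
  }
  new_gompertz_fit(est, se, r2, reason,
                   temperature = attr(series, "temperature"))
}

new_gompertz_fit <- function(est, se, r2, quality, temperature = NA_real_) {
  lam_rel <- is.finite(se[["lambda"]]) && se[["lambda"]] <= est[["lambda"]]
  structure(
    list(logN0 = est[["logN0"]], logNm = est[["logNm"]],
         mu_m = est[["mu_m"]], lambda = est[["lambda"]],
         se = se, r2 = r2,
         quality = list(accepted = identical(quality, "ok"),
                        reason = quality),
         lambda_reliable = lam_rel,
         temperature = temperature),
    class = "gompertz_fit"
  )
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf(
    "Gompertz fit (%g degC): logN0 = %.3f, logNm = %.3f, mu_m = %.4f /d, lambda = %.3f d%s\n",
    x$temperature, x$logN0, x$logNm, x$mu_m, x$lambda,
    if (!x$lambda_reliable) " (lambda unreliable)" else ""))
  cat(sprintf("  r2 = %s, quality = %s\n",
              ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2)),
              x$quality$reason))
  invisible(x)
}

#' @export
coef.gompertz_fit <- function(object, ...) {
  c(logN0 = object$logN0, logNm = object$logNm,
    mu_m = object$mu_m, lambda = object$lambda)
}

#' Evaluate the zero-order sensory-decay model
#'
#' \eqn{S(t) = S_0 \pm k_s t}: a quality score changing linearly with time at
#' rate `k_s` (score units per day). The value is not clamped to the 1-9
#' hedonic range; the line is the model.
#'
#' @param t Time, days.
#' @param S0 Intercept score.
#' @param k_s Deterioration rate, score units/day (>= 0).
#' @param direction `"decreasing"` (default; quality loss) or `"increasing"`.
#' @return Predicted score.
#' @export
zero_order_eval <- function(t, S0, k_s,
                            direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(k_s >= 0)
  if (direction == "decreasing") S0 - k_s * t else S0 + k_s * t
}

#' Construct a per-temperature sensory series
#'
#' @param time_d Sampling times, days.
#' @param score Hedonic scores, 1-9.
#' @param temperature Storage temperature, deg C.
#' @param attribute Attribute label (default overall acceptance).
#' @return A `sensory_series` data.frame.
#' @export
sensory_series <- function(time_d, score, temperature,
                           attribute = "overall_acceptance") {
  stopifnot(length(time_d) == length(score))
  if (any(score < 1 | score > 9)) {
    stop("scores must lie within the 1-9 hedonic range", call. = FALSE)
  }
  structure(data.frame(time_d = time_d, score = score),
            temperature = temperature, attribute = attribute,
            class = c("sensory_series", "data.frame"))
}

#' Fit zero-order kinetics to a sensory series
#'
#' Ordinary least squares of score on time; `k_s` is the absolute slope and
#' `direction` its sign.
#'
#' @param series A [sensory_series()] with at least 3 points.
#' @return A `zero_order_fit` with `S0`, `k_s`, `direction`, standard
#'   errors, `r2` and the temperature.
#' @export
fit_zero_order <- function(series) {
  if (nrow(series) < 3) {
    stop("insufficient data: need at least 3 points", call. = FALSE)
  }
  fit <- stats::lm(score ~ time_d, data = series)
  sm <- suppressWarnings(summary(fit))  # noise-free data: "perfect fit"
  slope <- unname(stats::coef(fit)[["time_d"]])
  structure(
    list(S0 = unname(stats::coef(fit)[["(Intercept)"]]),
         k_s = abs(slope),
         direction = if (slope <= 0) "decreasing" else "increasing",
         se_S0 = sm$coefficients["(Intercept)", "Std. Error"],
         se_ks = sm$coefficients["time_d", "Std. Error"],
         r2 = sm$r.squared,
         temperature = attr(series, "temperature"),
         attribute = attr(series, "attribute")),
    class = "zero_order_fit"
  )
}

#' @export
print.zero_order_fit <- function(x, ...) {
  cat(sprintf(
    "Zero-order sensory fit (%g degC): S0 = %.3f, k_s = %.4f /d (%s), r2 = %.4f\n",
    x$temperature, x$S0, x$k_s, x$direction, x$r2))
  invisible(x)
}
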