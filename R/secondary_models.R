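#' Evaluate the Arrhenius secondary model
#'
#' Temperature dependence of a primary-model rate constant,
#' \deqn{k(T) = k_{ref} \exp\!\left(-\frac{E_a}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\right)\right)}
#' with T in kelvin and R = 8.314 J/(mol K). User-facing temperatures are
#' always deg C; kelvin appears only inside the math.
#'
#' @param T_celsius Temperature(s), deg C (> -273.15).
#' @param k_ref Rate at the reference temperature (units of the underlying
#'   rate).
#' @param Ea Activation energy, J/mol.
#' @param T_ref_celsius Reference temperature, deg C (default 4, the typical
#'   base chill temperature).
#' @return Rate constant(s) at `T_celsius`.
#' @export
#' @examples
#' arrhenius_eval(12, k_ref = 0.5, Ea = 80000, T_ref_celsius = 4)
arrhenius_eval <- function(T_celsius, k_ref, Ea, T_ref_celsius = 4) {
  stopifnot(all(T_celsius > -273.15), k_ref > 0)
  T_K <- T_celsius + 273.15
  T_ref <- T_ref_celsius + 273.15
  k_ref * exp(-(Ea / .R_GAS) * (1 / T_K - 1 / T_ref))
}

.R_GAS <- 8.314  # J/(mol K)

#' Fit the Arrhenius model to rate-vs-temperature observations
#'
#' Linearized fit: ordinary least squares of `ln(rate)` on
#' `(1/T_K - 1/T_ref)`; the slope is `-Ea/R` and the intercept `ln(k_ref)`.
#' With two distinct temperatures the fit interpolates exactly (r2 = 1).
#'
#' @param temperature Temperatures, deg C (>= 2 distinct values).
#' @param rate Positive rate constants (e.g. `mu_m` or `k_s`) at those
#'   temperatures.
#' @param T_ref_celsius Reference temperature, deg C.
#' @return An `arrhenius_fit` with `k_ref`, `Ea` (J/mol), `T_ref_celsius`,
#'   `se_Ea`, `r2`, `n`.
#' @export
fit_arrhenius <- function(temperature, rate, T_ref_celsius = 4) {
  stopifnot(length(temperature) == length(rate))
  if (any(rate <= 0)) {
    stop("rates must be strictly positive for log-linear fitting",
         call. = FALSE)
  }
  if (length(unique(temperature)) < 2) {
    stop("insufficient data: need >= 2 distinct temperatures", call. = FALSE)
  }
  x <- 1 / (temperature + 273.15) - 1 / (T_ref_celsius + 273.15)
  fit <- stats::lm(log(rate) ~ x)
  sm <- suppressWarnings(summary(fit))  # exact 2-point fits are saturated
  slope <- unname(stats::coef(fit)[["x"]])
  se_slope <- sm$coefficients["x", "Std. Error"]
  structure(
    list(k_ref = exp(unname(stats::coef(fit)[["(Intercept)"]])),
         Ea = -slope * .R_GAS,
         T_ref_celsius = T_ref_celsius,
         se_Ea = se_slope * .R_GAS,
         r2 = sm$r.squared,
         n = length(rate)),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "Arrhenius fit: k(%g degC) = %.4g, Ea = %.3f kJ/mol (se %.3f), r2 = %.4f, n = %d\n",
    x$T_ref_celsius, x$k_ref, x$Ea / 1000,
    ifelse(is.na(x$se_Ea), NA, x$se_Ea / 1000), x$r2, x$n))
  invisible(x)
}

#' Predict a rate from a fitted Arrhenius model
#'
#' @param object An `arrhenius_fit`.
#' @param T_celsius Temperature(s), deg C.
#' @param ... Unused.
#' @return Predicted rate(s).
#' @export
predict.arrhenius_fit <- function(object, T_celsius, ...) {
  arrhenius_eval(T_celsius, object$k_ref, object$Ea, object$T_ref_celsius)
}

#' Secondary model for the lag phase
#'
#' The lag `lambda` is a time, not a rate, so its temperature dependence is
#' modelled by applying the Arrhenius law to `1/lambda`:
#' \eqn{\lambda(T) = 1 / k_{1/\lambda}(T)}. When no reliable positive lags
#' are available (common when the lag is unidentifiable from chill-storage
#' data), the model degenerates to a constant `lambda = 0` and is flagged.
#'
#' @param temperature Temperatures, deg C.
#' @param lambda Lag phases, days, at those temperatures. Non-positive or
#'   `NA` entries are treated as unreliable.
#' @param reliable Optional logical vector marking which lags to use
#'   (default: all positive finite ones).
#' @param T_ref_celsius Reference temperature, deg C.
#' @return A `lag_model`: either an Arrhenius model on `1/lambda`
#'   (`degenerate = FALSE`) or the constant-zero fallback
#'   (`degenerate = TRUE`).
#' @export
fit_lag_model <- function(temperature, lambda, reliable = NULL,
                          T_ref_celsius = 4) {
  if (is.null(reliable)) reliable <- is.finite(lambda) & lambda > 0
  use <- reliable & is.finite(lambda) & lambda > 0
  if (sum(use) < 2 || length(unique(temperature[use])) < 2) {
    return(structure(list(degenerate = TRUE, fit = NULL),
                     class = "lag_model"))
  }
  fit <- fit_arrhenius(temperature[use], 1 / lambda[use], T_ref_celsius)
  structure(list(degenerate = FALSE, fit = fit), class = "lag_model")
}

#' Evaluate a lag-phase secondary model
#'
#' @param model A `lag_model` from [fit_lag_model()].
#' @param T_celsius Temperature(s), deg C.
#' @return Predicted lag(s), days (0 for the degenerate model).
#' @export
lag_eval <- function(model, T_celsius) {
  stopifnot(inherits(model, "lag_model"))
  if (model$degenerate) return(rep(0, length(T_celsius)))
  1 / predict(model$fit, T_celsius)
}

#' @export
print.lag_model <- function(x, ...) {
  if (x$degenerate) {
    cat("Lag model: degenerate (constant lambda = 0; lags unreliable)\n")
  } else {
    cat("Lag model via Arrhenius on 1/lambda:\n  ")
    print(x$fit)
  }
  invisible(x)
}
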