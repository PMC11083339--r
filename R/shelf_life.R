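#' Shelf-life rejection limits
#'
#' The customary endpoints for chilled leafy produce: sensory rejection at a
#' hedonic score of 5 and a maximum allowed microbial load of 7.5 log10
#' CFU/g.
#'
#' @param sensory_limit Rejection score on the 1-9 hedonic scale (default 5).
#' @param microbial_limit Maximum allowed total viable count, log10 CFU/g
#'   (default 7.5).
#' @return A `shelf_life_limits` list.
#' @export
shelf_life_limits <- function(sensory_limit = 5, microbial_limit = 7.5) {
  stopifnot(sensory_limit >= 1, sensory_limit <= 9, microbial_limit > 0)
  structure(list(sensory_limit = sensory_limit,
                 microbial_limit = microbial_limit),
            class = "shelf_life_limits")
}

#' Sensory shelf life at a constant temperature
#'
#' Inverts the zero-order sensory model under the Arrhenius rate law:
#' \deqn{SL_s(T) = \frac{S_0 - S_L}{k_s(T)}}
#' where `S_L` is the rejection score.
#'
#' @param S0 Initial score.
#' @param ks_model An `arrhenius_fit` for the sensory deterioration rate, or
#'   a plain positive number used as a temperature-independent rate.
#' @param T_celsius Storage temperature, deg C.
#' @param limits A [shelf_life_limits()].
#' @return Days to sensory rejection. If `S0` is already at or below the
#'   limit, 0 is returned with attribute `flag = "already_rejected"`.
#' @export
shelf_life_sensory <- function(S0, ks_model, T_celsius,
                               limits = shelf_life_limits()) {
  ks <- rate_at(ks_model, T_celsius)
  stopifnot(ks > 0)
  if (S0 <= limits$sensory_limit) {
    return(structure(0, flag = "already_rejected"))
  }
  (S0 - limits$sensory_limit) / ks
}

#' Microbial shelf life at a constant temperature
#'
#' The linear-growth approximation with lag:
#' \deqn{SL_{TVC}(T) = \frac{\log N_l - \log N_0}{\mu_m(T)} + \lambda(T).}
#' A zero growth rate yields the distinguished value `Inf` with attribute
#' `flag = "stable"` - microbially stable product, never an error.
#'
#' @param logN0 Initial load, log10 CFU/g.
#' @param mu_model An `arrhenius_fit` for `mu_m`, a plain number, or `NULL` /
#'   `0` for a no-growth (stable) product.
#' @param lag_model A `lag_model` from [fit_lag_model()], a plain number
#'   (constant lag, days), or `NULL` for zero lag.
#' @param T_celsius Storage temperature, deg C.
#' @param limits A [shelf_life_limits()].
#' @return Days to the microbial limit; `Inf` (flagged `"stable"`) when the
#'   rate is zero; 0 (flagged `"already_rejected"`) when `logN0` is at or
#'   above the limit.
#' @export
shelf_life_microbial <- function(logN0, mu_model, lag_model = NULL,
                                 T_celsius, limits = shelf_life_limits()) {
  if (logN0 >= limits$microbial_limit) {
    return(structure(0, flag = "already_rejected"))
  }
  mu <- if (is.null(mu_model)) 0 else rate_at(mu_model, T_celsius)
  if (mu == 0) return(structure(Inf, flag = "stable"))
  lag <- lag_at(lag_model, T_celsius)
  (limits$microbial_limit - logN0) / mu + lag
}

rate_at <- function(model, T_celsius) {
  if (inherits(model, "arrhenius_fit")) predict(model, T_celsius)
  else as.numeric(model)
}

lag_at <- function(model, T_celsius) {
  if (is.null(model)) 0
  else if (inherits(model, "lag_model")) lag_eval(model, T_celsius)
  else as.numeric(model)
}

#' Combine sensory and microbial shelf lives
#'
#' The product's shelf life is the minimum of the two endpoint predictions;
#' `limiting_mode` names the minimizer, with ties resolved to `microbial`
#' (the conservative convention for a safety-relevant endpoint).
#'
#' @param sl_sensory,sl_microbial Endpoint shelf lives, days (either may be
#'   `Inf` for a stable endpoint).
#' @param temperature Temperature (or profile label) the values refer to.
#' @return A `shelf_life_result` with `sl_sensory`, `sl_microbial`,
#'   `sl_combined` and `limiting_mode`.
#' @export
combined_shelf_life <- function(sl_sensory, sl_microbial,
                                temperature = NA_real_) {
  stopifnot(sl_sensory >= 0, sl_microbial >= 0)
  sl <- min(sl_sensory, sl_microbial)
  mode <- if (sl_microbial <= sl_sensory) "microbial" else "sensory"
  structure(
    list(temperature = temperature,
         sl_sensory = as.numeric(sl_sensory),
         sl_microbial = as.numeric(sl_microbial),
         sl_combined = as.numeric(sl),
         limiting_mode = mode),
    class = "shelf_life_result"
  )
}

#' @export
print.shelf_life_result <- function(x, ...) {
  fmt <- function(v) if (is.infinite(v)) "stable" else sprintf("%.2f d", v)
  cat(sprintf(
    "Shelf life (%s): sensory %s, microbial %s -> combined %s (%s-limited)\n",
    if (is.numeric(x$temperature)) sprintf("%g degC", x$temperature)
    else as.character(x$temperature),
    fmt(x$sl_sensory), fmt(x$sl_microbial), fmt(x$sl_combined),
    x$limiting_mode))
  invisible(x)
}

#' Shelf life at constant temperature from both endpoint models
#'
#' Convenience wrapper evaluating [shelf_life_sensory()] and
#' [shelf_life_microbial()] at one temperature and combining them.
#'
#' @inheritParams shelf_life_sensory
#' @inheritParams shelf_life_microbial
#' @return A `shelf_life_result`.
#' @export
shelf_life_at <- function(T_celsius, S0, ks_model, logN0, mu_model,
                          lag_model = NULL, limits = shelf_life_limits()) {
  sls <- shelf_life_sensory(S0, ks_model, T_celsius, limits)
  slm <- shelf_life_microbial(logN0, mu_model, lag_model, T_celsius, limits)
  combined_shelf_life(sls, slm, temperature = T_celsius)
}

#' Piecewise-constant temperature profile
#'
#' Represents temperature abuse during storage and transport as ordered
#' segments of constant temperature.
#'
#' @param duration_d Segment durations, days (> 0).
#' @param temp_c Segment temperatures, deg C.
#' @return A `temperature_profile` data.frame.
#' @export
temperature_profile <- function(duration_d, temp_c) {
  stopifnot(length(duration_d) == length(temp_c))
  if (length(duration_d) == 0 || sum(duration_d) <= 0) {
    stop("profile must have positive total duration", call. = FALSE)
  }
  if (any(duration_d <= 0)) {
    stop("segment durations must be > 0", call. = FALSE)
  }
  structure(data.frame(duration_d = duration_d, temp_c = temp_c),
            class = c("temperature_profile", "data.frame"))
}

#' Shelf life under a variable temperature profile
#'
#' Cumulative-fraction rule: at temperature T a day of storage consumes
#' `1/SL(T)` of the product's shelf life; the product expires at the first
#' time t where the consumed fraction \eqn{r(t) = \int_0^t ds / SL(T(s))}
#' reaches 1. Over piecewise-constant segments the integral is a sum, and at
#' constant temperature the rule reduces exactly to the closed-form shelf
#' life. Applied per endpoint, then combined by the minimum rule.
#'
#' @param profile A [temperature_profile()].
#' @param S0 Initial sensory score.
#' @param ks_model Arrhenius model (or constant) for the sensory rate.
#' @param logN0 Initial load, log10 CFU/g.
#' @param mu_model Arrhenius model (or constant) for `mu_m`; `NULL`/0 means
#'   microbially stable.
#' @param lag_model Lag secondary model or constant, days.
#' @param limits A [shelf_life_limits()].
#' @return A `shelf_life_result`; an endpoint that survives the whole
#'   profile is reported as `Inf` ("survives profile").
#' @export
shelf_life_under_profile <- function(profile, S0, ks_model, logN0, mu_model,
                                     lag_model = NULL,
                                     limits = shelf_life_limits()) {
  stopifnot(inherits(profile, "temperature_profile"))
  sl_fun_sensory <- function(T_c) {
    as.numeric(shelf_life_sensory(S0, ks_model, T_c, limits))
  }
  sl_fun_microbial <- function(T_c) {
    as.numeric(shelf_life_microbial(logN0, mu_model, lag_model, T_c, limits))
  }
  sls <- profile_hitting_time(profile, sl_fun_sensory)
  slm <- profile_hitting_time(profile, sl_fun_microbial)
  combined_shelf_life(sls, slm, temperature = "profile")
}

profile_hitting_time <- function(profile, sl_fun) {
  r <- 0       # consumed fraction
  elapsed <- 0
  for (s in seq_len(nrow(profile))) {
    sl <- sl_fun(profile$temp_c[s])
    if (sl <= 0) return(elapsed)          # already expired entering segment
    dur <- profile$duration_d[s]
    dr <- if (is.infinite(sl)) 0 else dur / sl
    if (r + dr >= 1) {
      return(elapsed + (1 - r) * sl)
    }
    r <- r + dr
    elapsed <- elapsed + dur
  }
  Inf  # survives profile
}

#' Time for the Gompertz curve to reach a microbial limit (full inversion)
#'
#' Root-finds `gompertz_eval(t) = logN_limit` by bisection-type search to
#' 1e-6 days; the crossing is unique because the curve is non-decreasing.
#' Serves as the exact cross-check for the linear-approximation shelf life
#' of [shelf_life_microbial()].
#'
#' @param logN0,logNm,mu_m,lambda Gompertz parameters
#'   (see [gompertz_eval()]).
#' @param logN_limit Microbial limit, log10 CFU/g.
#' @param t_max Upper bracket for the search, days.
#' @return Crossing time in days; `Inf` when the asymptote
#'   `logN0 + logNm` never reaches the limit; 0 when already above it.
#' @export
invert_gompertz_time_to_limit <- function(logN0, logNm, mu_m, lambda,
                                          logN_limit, t_max = 1e4) {
  if (logN0 >= logN_limit) return(0)
  if (logN0 + logNm <= logN_limit || mu_m == 0) return(Inf)
  f <- function(t) gompertz_eval(t, logN0, logNm, mu_m, lambda) - logN_limit
  if (f(t_max) < 0) return(Inf)
  stats::uniroot(f, lower = 0, upper = t_max, tol = 1e-6)$root
}
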