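#' Water loss of an osmotically dehydrated sample
#'
#' Computes water loss (WL) from gravimetric data: the mass of initial water
#' lost during osmotic dehydration, per gram of initial dry matter,
#' \deqn{WL = \frac{m_0 - m_0 DW_{wb} - (m_{wet} - m_{dry})}{m_0 DW_{wb}}.}
#'
#' A negative value means net water uptake; it is returned as-is with a
#' warning, never clamped, because uptake is physically meaningful.
#'
#' @param m0 Initial wet mass of the sample, g.
#' @param m_wet Wet mass after treatment, g.
#' @param m_dry Dry mass after treatment, g.
#' @param dw_wb Dry-weight fraction of the untreated material, g dry / g wet
#'   (a per-batch constant, strictly between 0 and 1).
#' @return Water loss in g water / g dry weight.
#' @seealso [compute_solid_gain()], [fit_penetration()]
#' @export
#' @examples
#' compute_water_loss(m0 = 5, m_wet = 3.8, m_dry = 0.65, dw_wb = 0.10)
compute_water_loss <- function(m0, m_wet, m_dry, dw_wb) {
  check_mass_obs(m0, m_wet, m_dry, dw_wb)
  wl <- (m0 - m0 * dw_wb - (m_wet - m_dry)) / (m0 * dw_wb)
  if (any(wl < 0)) {
    warning("negative water loss (net water uptake); value retained",
            call. = FALSE)
  }
  wl
}

#' Solid gain of an osmotically dehydrated sample
#'
#' Computes solid gain (SG): the mass of osmotic solids taken up by the
#' sample, per gram of initial dry matter,
#' \deqn{SG = \frac{m_{dry} - DW_{wb} m_0}{DW_{wb} m_0}.}
#'
#' @inheritParams compute_water_loss
#' @return Solid gain in g solids / g dry weight.
#' @export
#' @examples
#' compute_solid_gain(m0 = 5, m_dry = 0.65, dw_wb = 0.10)
compute_solid_gain <- function(m0, m_dry, dw_wb, m_wet = NULL) {
  check_mass_obs(m0, m_wet %||% m_dry, m_dry, dw_wb)
  (m_dry - dw_wb * m0) / (dw_wb * m0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_mass_obs <- function(m0, m_wet, m_dry, dw_wb) {
  stopifnot(is.numeric(m0), is.numeric(m_wet), is.numeric(m_dry),
            is.numeric(dw_wb))
  if (any(!is.finite(m0)) || any(m0 <= 0) || any(m_wet <= 0) ||
      any(m_dry <= 0)) {
    stop("all masses must be finite and positive", call. = FALSE)
  }
  if (any(dw_wb <= 0) || any(dw_wb >= 1)) {
    stop("dw_wb must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(m0 * dw_wb == 0)) {
    stop("invalid denominator: m0 * dw_wb is zero", call. = FALSE)
  }
  if (any(m_dry > m_wet)) {
    stop("m_dry must not exceed m_wet", call. = FALSE)
  }
  invisible(TRUE)
}

#' Treatment label for an osmotic-dehydration run
#'
#' Records the osmotic-medium composition and the pulsed-electric-field (PEF)
#' pre-treatment conditions for one treatment. `pulses = 0` means no PEF.
#'
#' @param glycerol_fraction Mass fraction of glycerol in the osmotic medium
#'   (e.g. 0.50, 0.60).
#' @param field_kv_cm PEF field strength, kV/cm (0 when untreated).
#' @param pulses Number of pulses applied (0 when untreated).
#' @param pulse_width_us,frequency_hz Fixed pulse metadata (optional).
#' @return A `treatment_label` object.
#' @export
treatment_label <- function(glycerol_fraction, field_kv_cm = 0, pulses = 0,
                            pulse_width_us = NA_real_, frequency_hz = NA_real_) {
  stopifnot(glycerol_fraction >= 0, glycerol_fraction <= 1,
            field_kv_cm >= 0, pulses >= 0)
  if ((pulses == 0) != (field_kv_cm == 0)) {
    stop("pulses = 0 must coincide with field_kv_cm = 0 (untreated by PEF)",
         call. = FALSE)
  }
  structure(
    list(glycerol_fraction = glycerol_fraction, field_kv_cm = field_kv_cm,
         pulses = pulses, pulse_width_us = pulse_width_us,
         frequency_hz = frequency_hz),
    class = "treatment_label"
  )
}

#' @export
format.treatment_label <- function(x, ...) {
  pef <- if (x$pulses == 0) "no PEF"
         else sprintf("%g kV/cm x %d pulses", x$field_kv_cm, x$pulses)
  sprintf("glycerol %.0f%%, %s", 100 * x$glycerol_fraction, pef)
}

#' @export
print.treatment_label <- function(x, ...) {
  cat("<treatment>", format(x), "\n")
  invisible(x)
}

#' Build an osmotic-dehydration kinetics series from gravimetric observations
#'
#' Converts raw mass observations taken along an immersion-time grid into a
#' water-loss / solid-gain series for one treatment. Times must be strictly
#' increasing; the customary grid is 0, 20, 40, 60, 90, 120 min with the t=0
#' point at WL = SG = 0.
#'
#' @param observations A data.frame with columns `time_min`, `m0_g`,
#'   `m_wet_g`, `m_dry_g` (one row per sampling time).
#' @param dw_wb Dry-weight fraction of the untreated material.
#' @param treatment A [treatment_label()].
#' @return An `od_series` object: a data.frame with columns `time_min`, `wl`,
#'   `sg` plus the treatment attached as an attribute.
#' @export
build_od_series <- function(observations, dw_wb,
                            treatment = treatment_label(0.6)) {
  req <- c("time_min", "m0_g", "m_wet_g", "m_dry_g")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(observations) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  t <- observations$time_min
  if (anyDuplicated(t)) stop("duplicate immersion times", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("immersion times must be strictly increasing", call. = FALSE)
  }
  wl <- compute_water_loss(observations$m0_g, observations$m_wet_g,
                           observations$m_dry_g, dw_wb)
  sg <- compute_solid_gain(observations$m0_g, observations$m_dry_g, dw_wb,
                           m_wet = observations$m_wet_g)
  new_od_series(data.frame(time_min = t, wl = wl, sg = sg), treatment)
}

#' Assemble an od_series from precomputed water-loss / solid-gain values
#'
#' @param time_min Immersion times, minutes, strictly increasing.
#' @param wl,sg Water loss and solid gain, g / g dry weight.
#' @param treatment A [treatment_label()].
#' @return An `od_series` object.
#' @export
od_series <- function(time_min, wl, sg = rep(NA_real_, length(time_min)),
                      treatment = treatment_label(0.6)) {
  stopifnot(length(time_min) == length(wl), length(wl) == length(sg))
  if (is.unsorted(time_min, strictly = TRUE)) {
    stop("immersion times must be strictly increasing", call. = FALSE)
  }
  new_od_series(data.frame(time_min = time_min, wl = wl, sg = sg), treatment)
}

new_od_series <- function(df, treatment) {
  structure(df, treatment = treatment,
            class = c("od_series", "data.frame"))
}

#' @export
print.od_series <- function(x, ...) {
  cat("Osmotic-dehydration series (", format(attr(x, "treatment")), ")\n",
      sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Fit the square-root-of-time penetration model
#'
#' Fits the empirical mass-transfer law \eqn{WL = k_X \sqrt{t}} (or SG
#' analogously) by least squares constrained through the origin. Times are
#' stored in minutes but `k` is reported per square-root *second* (the
#' customary unit for the constant), with the minute-to-second conversion
#' applied inside the fit.
#'
#' @param series An [od_series()] object.
#' @param response `"wl"` or `"sg"`.
#' @param with_intercept Diagnostic only: also fit an unconstrained line on
#'   \eqn{\sqrt t} and report its intercept.
#' @return A `penetration_fit` with elements `response`, `k` (g/(g DW
#'   s^0.5)), `se_k`, `r2`, `n` and, if requested, `diag_intercept`.
#' @export
#' @examples
#' s <- od_series(c(0, 20, 40, 60, 90, 120),
#'                wl = 0.046 * sqrt(60 * c(0, 20, 40, 60, 90, 120)))
#' fit_penetration(s, "wl")
fit_penetration <- function(series, response = c("wl", "sg"),
                            with_intercept = FALSE) {
  response <- match.arg(response)
  y <- series[[response]]
  t_min <- series$time_min
  ok <- is.finite(y) & is.finite(t_min)
  y <- y[ok]; t_min <- t_min[ok]
  nz <- t_min > 0
  if (sum(nz) < 1 || all(y == 0) && all(t_min == 0)) {
    stop("degenerate fit: no nonzero-time points with data", call. = FALSE)
  }
  sqrt_t_s <- sqrt(60 * t_min)  # minutes -> seconds under the root
  fit <- stats::lm(y ~ 0 + sqrt_t_s)
  sm <- suppressWarnings(summary(fit))  # noise-free data: "perfect fit"
  out <- list(
    response = response,
    k = unname(stats::coef(fit)[["sqrt_t_s"]]),
    se_k = unname(sm$coefficients["sqrt_t_s", "Std. Error"]),
    r2 = sm$r.squared,  # uncentered convention for through-origin fits
    n = length(y),
    treatment = attr(series, "treatment")
  )
  if (with_intercept) {
    dfit <- stats::lm(y ~ sqrt_t_s)
    out$diag_intercept <- unname(stats::coef(dfit)[["(Intercept)"]])
  }
  structure(out, class = "penetration_fit")
}

#' @export
print.penetration_fit <- function(x, ...) {
  cat(sprintf("Penetration fit [%s]: k = %.4g g/(g DW s^0.5) (se %.3g), r2 = %.4f, n = %d\n",
              toupper(x$response), x$k, x$se_k, x$r2, x$n))
  invisible(x)
}
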