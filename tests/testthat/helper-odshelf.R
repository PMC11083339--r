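# shared fixtures for the kinetic-model tests

# noise-free penetration series: wl = k * sqrt(t_seconds) on the standard
# 0-120 min immersion grid
exact_pen_series <- function(k, t_min = c(0, 20, 40, 60, 90, 120)) {
  od_series(t_min, wl = k * sqrt(60 * t_min), sg = k / 3 * sqrt(60 * t_min))
}

# noise-free Gompertz growth series
exact_growth_series <- function(logN0 = 6.5, logNm = 3.5, mu_m = 0.8,
                                lambda = 2, times = seq(0, 25,
                                                        length.out = 10),
                                temperature = 4) {
  growth_series(times, gompertz_eval(times, logN0, logNm, mu_m, lambda),
                temperature)
}

# random physically valid mass observation
random_mass_obs <- function() {
  m0 <- runif(1, 2, 10)
  dw <- runif(1, 0.05, 0.3)
  sg <- runif(1, 0, 2)
  wl <- runif(1, 0, (1 - dw) / dw * 0.8)
  m_dry <- dw * m0 * (1 + sg)
  m_wet <- m_dry + m0 * (1 - dw) - wl * m0 * dw
  list(m0 = m0, dw_wb = dw, m_dry = m_dry, m_wet = m_wet,
       wl_true = wl, sg_true = sg)
}
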