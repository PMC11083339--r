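---
title: "Kinetic models behind odshelf: osmotic dehydration, spoilage, and shelf life"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic models behind odshelf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odshelf)
```

## The problem

Fresh-cut leafy vegetables such as spinach are among the most perishable
chilled products: high water activity, a large indigenous microbial load
(~6.5 log10 CFU/g at packing), and fragile tissue give shelf lives of only
a few days at 4 °C. Osmotic dehydration (OD) — immersion in a hypertonic
medium such as concentrated glycerol — removes part of the tissue water and
loads the tissue with solutes, lowering water activity below the ~0.91
threshold where bacterial proliferation slows sharply. A pulsed electric
field (PEF) pre-treatment electroporates the cell membranes and accelerates
this mass transfer. `odshelf` implements the modelling chain a shelf-life
study of such a product needs: mass-transfer kinetics during OD, primary
spoilage models during storage, secondary temperature models, and the
composite shelf-life prediction.

## Mass transfer during osmotic dehydration

Gravimetric observations (initial wet mass $m_0$, treated wet mass
$m_{wet}$, treated dry mass $m_{dry}$, and the dry-weight fraction
$DW_{wb}$ of untreated material) yield two dimensionless indices per gram
of initial dry matter:

$$WL = \frac{m_0 - m_0 DW_{wb} - (m_{wet} - m_{dry})}{m_0 DW_{wb}},
\qquad
SG = \frac{m_{dry} - DW_{wb} m_0}{DW_{wb} m_0}.$$

The two are linked by an exact mass balance
($m_0 DW_{wb}(1+SG) + m_0(1-DW_{wb}) - WL\, m_0 DW_{wb} = m_{wet}$), which
the test suite asserts to $10^{-9}$ and which `simulate_study()` exploits
to materialize synthetic mass tables whose identities hold exactly.
Negative water loss (net uptake) is physically meaningful and is returned
with a warning, never clamped.

Their kinetics follow the empirical *penetration model*:
$WL(t) = k_{WL}\sqrt{t}$ (and likewise $SG$), fitted by least squares
**through the origin** — the law has no intercept, and an intercept-bearing
variant is available only as a diagnostic (`with_intercept = TRUE`).
Immersion times are stored in minutes (the customary 0, 20, 40, 60, 90,
120 min grid) while $k$ is reported per $\sqrt{\text{second}}$, the unit
convention usual for these constants; the minute-to-second conversion
happens inside `fit_penetration()`. The through-origin $R^2$ uses the
uncentred convention, which guarantees $R^2 \le 1$ and equals 1 on
noise-free data.

```{r}
s <- od_series(c(0, 20, 40, 60, 90, 120),
               wl = 0.046 * sqrt(60 * c(0, 20, 40, 60, 90, 120)))
fit_penetration(s, "wl")
```

## Primary spoilage models

**Microbial growth.** Total viable counts (TVC, log10 CFU/g) follow the
modified Gompertz sigmoid in the Zwietering parameterization:

$$\log N(t) = \log N_0 + \log N_m
\exp\!\left(-\exp\!\left(\frac{\mu_m e}{\log N_m}(\lambda - t) +
1\right)\right)$$

with initial load $\log N_0$, amplitude $\log N_m$ (so the stationary
level is $\log N_0 + \log N_m$), maximum specific rate $\mu_m$
(log10 CFU/g/day — the slope of the tangent at the inflection) and lag
$\lambda$ (days — that tangent's time intercept). This is the only
parameterization in which $\mu_m$ is a slope and $\lambda$ a lag, which is
why it was adopted; the value at $t = \lambda$ is always
$\log N_0 + \log N_m e^{-e}$, a parameterization-independent anchor the
tests exploit.

`fit_gompertz()` uses bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`, $\log N_m, \mu_m, \lambda \ge 0$) with data-driven
starting values (first observation, observed amplitude, steepest pairwise
slope, tangent time-intercept floored at 0) and a short ladder of fallback
starts, keeping the lowest-deviance converged solution. Direct use of
`nls.lm` rather than an `nls`-object wrapper matters at boundary solutions
($\lambda = 0$, zero residual), where the model-object construction — not
the optimization — fails on a collinear gradient.

**Fit classification.** Chilled produce that has been hurdled hard (low
water activity, low pH) often shows *stagnant* counts that no growth model
should be forced through. A fit is classified `no_growth_trend` when the
observed amplitude is below 0.5 log10 CFU/g, when the fitted curve is flat
($\log N_m \approx 0$), or when $\mu_m$ is not significantly positive
($\mu_m \le 2\,\mathrm{se}(\mu_m)$, with an inestimable standard error
counting as a failure to demonstrate growth); otherwise `poor_fit` when
$R^2 < 0.7$; otherwise `ok`. Only `ok` fits feed the secondary models. A
series that the optimizer cannot fit at all (e.g. a slow noise-induced
drift that sends the Gompertz parameters running away) is reported as a
per-series failure by `run_pipeline()` rather than silently classified —
those series deserve human eyes. The lag is additionally flagged
unreliable when its standard error exceeds its value, the common outcome
for chill-storage data where the lag is barely identified.

**Sensory decay.** Overall acceptance on the 1–9 hedonic scale declines
(approximately) linearly: $S(t) = S_0 - k_s t$, fitted by ordinary least
squares. The fitted line is deliberately *not* clamped to [1, 9] — the
model is the line; only simulated panel data are clamped, because a real
panel cannot score outside the scale. Per-temperature fitting is the
default; pooling $S_0$ across temperatures is left to the user (fit once,
then pass a common `S0` to the shelf-life functions).

## Secondary (temperature) models

Rate constants from both primary models follow the Arrhenius law

$$k(T) = k_{ref}\exp\!\left(-\frac{E_a}{R}\left(\frac1T -
\frac1{T_{ref}}\right)\right),$$

fitted in linearized form — OLS of $\ln k$ on $1/T - 1/T_{ref}$ — which is
closed-form, reproducible, and standard practice with the three storage
temperatures such studies use. The reference temperature defaults to 4 °C
(the base chill temperature); refitting at a different $T_{ref}$ changes
$k_{ref}$ but leaves $E_a$ and all predictions identical, an invariance the
tests assert to $10^{-9}$. Because the lag is a time, not a rate, its
temperature dependence is modelled through $1/\lambda$
(`fit_lag_model()`); when fewer than two reliable positive lags exist the
model degenerates to a flagged constant $\lambda = 0$, which is the
conservative choice for shelf life (no lag credit). Temperatures are °C in
every user-facing interface; kelvin exists only inside the formula.

## Shelf life

Two endpoints, each inverted from its primary+secondary model at
temperature $T$:

$$SL_s(T) = \frac{S_0 - S_L}{k_s(T)}, \qquad
SL_{TVC}(T) = \frac{\log N_l - \log N_0}{\mu_m(T)} + \lambda(T),$$

with rejection score $S_L = 5$ and microbial limit
$\log N_l = 7.5$ log10 CFU/g by default. The microbial formula is the
linear-growth approximation; the package also ships the exact alternative
— `invert_gompertz_time_to_limit()`, root-finding on the full sigmoid to
$10^{-6}$ d — as an independent cross-check. On the default parameter
grid, where the limit is crossed mid-exponential (one log above a 6.5
start against a 3.5-log amplitude), the two agree within a few percent;
the linear formula is kept as the primary route because its closed form is
what such studies tabulate. A product whose counts never grow gets the
distinguished *stable* value (`Inf`, flagged), never an error — combined
with the sensory endpoint by the minimum rule, ties resolving to
*microbial* as the conservative convention:

```{r}
combined_shelf_life(sl_sensory = 20, sl_microbial = Inf, temperature = 4)
```

**Variable temperature profiles.** For piecewise-constant abuse profiles
(transport, door-openings), the package uses the cumulative-fraction rule:
a day spent at temperature $T$ consumes $1/SL(T)$ of the product's life,
and the product expires when $r(t) = \int_0^t ds/SL(T(s))$ reaches 1. The
rule reduces *exactly* to the constant-temperature formulas on a constant
profile, is invariant to splitting segments, and makes the consumed
fraction additive (so reordering segments never changes whether the
profile is survived, only the hitting time). It is the natural first-order
scheme when only $SL(T)$ is known; it ignores history effects (e.g. lag
re-induction after cooling), which would require a dynamic growth model.

## The synthetic-data generator

`truth_config()` + `simulate_study()` generate complete studies with known
ground truth so every stage is testable without external data. The
defaults describe a chilled leafy-green study:

| quantity | default | rationale |
|---|---|---|
| $\log N_0$ | 6.5 log10 CFU/g | typical initial load of packed leafy produce |
| $\log N_m$ | 3.5 | stationary phase near 10 log10 CFU/g |
| $\mu_m$(4 °C) | 0.4 /d | gives ≈ 4.5 d microbial shelf life at 4 °C, the untreated regime |
| $E_{a,\mu}$ | 80 kJ/mol | upper-mesophilic temperature sensitivity of spoilage flora |
| $\lambda$(4 °C) | 2 d, $E_a$ 60 kJ/mol on $1/\lambda$ | short chill lag, shrinking with temperature |
| $S_0$ | 8 | fresh product scores high on the 9-point scale |
| $k_s$(4 °C) | 0.12 /d, $E_a$ 60 kJ/mol | ≈ 25 d sensory life at 4 °C |
| $k_{WL}$ | 0.0461 g/(g DW √s) | ≈ 0.357 per √min, a typical 60 % glycerol value |
| noise | 0.2 log10 CFU/g, 0.3 score units | triplicate plate-count and 8-panelist scatter |
| design | 4/12/20 °C, 7 sampling days, OD at 0–120 min | the standard storage/immersion design |

Sampling days adapt to temperature — spanning lag + rise + early
stationary phase for growth, and decay to deep rejection for sensory —
as a study team would schedule them; explicit grids can be forced with
`growth_days`/`sensory_days`. Scores are clamped to [1, 9] at generation
(flagged `range_limited` when clamping bites); counts are floored at 0.
Treatment effects are encoded purely as different truth parameters (a
stagnant arm is simply `logNm = 0`); no electroporation physics is
simulated. Gaussian additive noise on the log/score scale is an idealized
error model: real plate counts have Poisson-like components, panels drift
and round to integers, and replicate leaves are correlated. Passing the
recovery tests therefore shows the *estimators* are correct and unbiased
under the assumed error structure, not that real spinach data will be this
well-behaved.

## Numerical choices and validation sizes

* Linear fits (penetration, zero-order, log-linear Arrhenius) are exact
  OLS via `stats::lm`; the Gompertz fit is multi-start bounded
  Levenberg–Marquardt with convergence codes 1–4 accepted and the best
  deviance kept.
* Noise-free closed loops recover generating parameters to $10^{-4}$
  relative (nonlinear) and $10^{-6}$ (linear) — provided the sampling grid
  covers the exponential rise; a steep curve sampled only in its flat
  phases is unidentifiable no matter the optimizer.
* Monte-Carlo validation uses 200 replicates of the default design
  (3 temperatures × 7 days): median relative error ≈ 11 % on $\mu_m$ and
  ≈ 9 % on $E_a$; the single-study shelf-life error at 4 °C has median
  ≈ 11 % and 95th percentile ≈ 49 % (the tail comes from replicates whose
  4 °C series is discarded by the fit-quality rule, a ~2 % event), which
  is where the 50 % single-study tolerance in the integration test comes
  from.
* Penetration fits tolerate a single nonzero-time point (through-origin
  with one observation); fully degenerate input (all times zero) errors.

## Limitations

* One growth model (modified Gompertz) and one sensory model (zero order):
  no Baranyi, logistic or Ratkowsky alternatives, and no species-specific
  flora modelling.
* The microbial shelf-life formula is the linear approximation; the full
  inversion is provided but not propagated through the Arrhenius layer.
* No uncertainty propagation into shelf-life estimates beyond the
  reported standard errors of each stage.
* The profile rule assumes instantaneous adaptation (no lag re-induction
  or history effects).
* Water activity is treated as observational metadata, never predicted
  from water loss.
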