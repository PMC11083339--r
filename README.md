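# odshelf

Kinetic modelling of osmotic dehydration and shelf life for chilled leafy
produce.

Fresh-cut leafy vegetables spoil within days of packing: the indigenous
flora starts near 6.5 log10 CFU/g and water activity is high. Osmotic
dehydration (OD) in a hypertonic medium — optionally accelerated by a
pulsed electric field (PEF) pre-treatment — lowers water activity and can
shift the product from a *microbially limited* to a *sensory limited*
shelf-life regime. `odshelf` is for food scientists and predictive
microbiologists who need the full modelling chain of such a study as
tested, reusable code:

* **Mass transfer** — water loss and solid gain from gravimetric data,
  `WL = (m0 − m0·DW_wb − (m_wet − m_dry))/(m0·DW_wb)`,
  `SG = (m_dry − DW_wb·m0)/(DW_wb·m0)`, and the square-root-of-time
  penetration fit `WL = k_WL·√t` (through the origin).
* **Primary spoilage models** — modified Gompertz for total viable counts,
  `logN(t) = logN0 + logNm·exp(−exp((μm·e/logNm)(λ−t)+1))`, with a
  no-growth-trend classifier for stagnant (hurdled) series; zero-order
  sensory decay `S(t) = S0 − ks·t` on the 1–9 hedonic scale.
* **Secondary models** — Arrhenius temperature dependence
  `k(T) = k_ref·exp(−(Ea/R)(1/T − 1/T_ref))` for any rate constant, fitted
  log-linearly; lag modelled through `1/λ`.
* **Shelf life** — sensory `SLs = (S0 − SL)/ks(T)` (rejection score 5) and
  microbial `SL_TVC = (logNl − logN0)/μm(T) + λ(T)` (limit 7.5 log10
  CFU/g), combined by the minimum rule; piecewise-constant
  temperature-abuse profiles via the cumulative-fraction rule; exact
  Gompertz inversion as a cross-check.
* **Synthetic studies** — `truth_config()` / `simulate_study()` generate
  complete studies (mass tables, storage trials, color readings) with
  known ground truth and realistic noise, so every stage is validated by
  closed-loop parameter recovery.
* **Quality indices** — CIELab ΔE (Euclidean) and relative burst strength.

## Worked example

Simulate a two-arm study — an OD arm whose counts grow, and a PEF–OD arm
whose counts stay stagnant — then run the whole pipeline:

```r
library(odshelf)
paths <- simulate_study(list(truth_config(label = "od_60"),
                             truth_config(logNm = 0, label = "pef_od")),
                        outdir = tempfile(), seed = 7)
rep <- run_pipeline(run_config(od_masses = paths[["od_masses"]],
                               storage_tvc = paths[["storage_tvc"]],
                               storage_sensory = paths[["storage_sensory"]]))
print(rep)
```

```
== Shelf-life modelling report ==

Penetration fits (k in g/(g DW s^0.5)):
 treatment response          k         se_k        r2
     od_60       wl 0.04482769 0.0002694308 0.9998194
     od_60       sg 0.01298885 0.0003407087 0.9965715
    pef_od       wl 0.04627542 0.0005068706 0.9994005
    pef_od       sg 0.01246674 0.0003280563 0.9965497

Growth fits - od_60
  Gompertz fit (4 degC): logN0 = 6.408, logNm = 3.646, mu_m = 0.3483 /d, lambda = 1.017 d
  r2 = 0.9965, quality = ok
  ...
Growth fits - pef_od
  Gompertz fit (4 degC): logN0 = 6.598, logNm = 0.000, mu_m = 0.0000 /d, lambda = 0.000 d (lambda unreliable)
  r2 = NA, quality = no_growth_trend
  ...
Secondary models - od_60
  mu_m: Arrhenius fit: k(4 degC) = 0.3786, Ea = 93.170 kJ/mol (se 12.549), r2 = 0.9822, n = 3
  k_s:  Arrhenius fit: k(4 degC) = 0.1111, Ea = 63.453 kJ/mol (se 2.838), r2 = 0.9980, n = 3
Secondary models - pef_od (microbially stable)
  k_s:  Arrhenius fit: k(4 degC) = 0.1117, Ea = 63.369 kJ/mol (se 3.346), r2 = 0.9972, n = 3

Shelf-life table (days):
 treatment temp_c sl_sensory_d sl_microbial_d sl_combined_d limiting_mode
     od_60      4       26.219          4.214         4.214     microbial
     od_60     12       12.108          1.865         1.865     microbial
     od_60     20        5.833          1.000         1.000     microbial
    pef_od      4       26.670            Inf        26.670       sensory
    pef_od     12       12.329            Inf        12.329       sensory
    pef_od     20        5.945            Inf         5.945       sensory
```

Reading the output: the OD arm's water-loss constant is recovered near its
generating value (0.0461 g/(g DW·√s) ≈ 0.357 per √min); its counts grow
(μm ≈ 0.35/d at 4 °C, activation energy ≈ 93 kJ/mol across 4–20 °C), so
its shelf life is microbially limited — about 4 d at 4 °C, shrinking
with temperature. The PEF–OD arm's counts show no growth trend at any
temperature, so its microbial endpoint is *stable* (`Inf`) and its shelf
life is set by sensory rejection instead: ≈ 27 d at 4 °C, the
shelf-life-extension regime such treatments aim for.

Constant-temperature or abuse-profile predictions come straight from the
fitted models:

```r
shelf_life_sensory(S0 = 8, ks_model = 0.12, T_celsius = 4)   # 25 days
shelf_life_microbial(6.5, 0.5, 1.0, 4)                       # 3 days
shelf_life_under_profile(temperature_profile(c(3, 2, 30), c(4, 20, 8)),
                         S0 = 8, ks_model = ks_fit,
                         logN0 = 6.5, mu_model = mu_fit)
```

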