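# thermadapt

Quantifying thermal adaptation of soil microbial respiration from
temperature response curves.

Soil heterotrophic respiration is the largest biological CO₂ flux to the
atmosphere, and how fast soil microbial communities adapt their temperature
response to a warming climate decides whether warming accelerates or damps
soil carbon loss. `thermadapt` is an R package for ecologists and
biogeochemists who measure substrate-unlimited (glucose-induced) respiration
across a dense temperature gradient and want to (i) fit each soil's full
temperature response curve with a thermodynamic model, (ii) extract the
temperature optimum (T_opt) and inflection point (T_inf) of each curve,
(iii) estimate the *rate of thermal adaptation* — how many °C these metrics
shift per °C of mean environmental soil temperature (MET) — while accounting
for spatial autocorrelation, and (iv) project how much respiration change
under a warming scenario is over- or under-estimated if adaptation is
ignored.

## The model

Respiration rate R_s as a function of absolute temperature T follows
macromolecular rate theory (MMRT), transition-state theory with a non-zero
activation heat capacity ΔC_P‡:

    ln(R_s) = ln(k_B T / h) − ΔH‡_T0 / (R T) − ΔC_P‡ (T − T0) / (R T)
              + ΔS‡_T0 / R + ΔC_P‡ (ln T − ln T0) / R

with ΔH‡_T0 the activation enthalpy and ΔS‡_T0 the activation entropy at
the reference temperature T0 = 300 K, and the activation heat capacity
allowed to vary linearly with temperature,

    ΔC_P‡(T) = A (T − T0) + B,

so that `A = 0` recovers the constant-ΔC_P‡ model (the two variants are
compared per curve by AICc). A negative ΔC_P‡ produces curvature and a
temperature optimum; T_opt is the peak of the fitted curve and T_inf the
peak of its first derivative (the temperature of maximum absolute
temperature sensitivity).

Curve-level metrics are then regressed on MET with a spatial simultaneous
autoregressive (SAR) error model, y = β₀ + β·MET + u, u = λWu + ε, fitted by
maximum likelihood over a k-nearest-neighbour weight matrix W; β is the
adaptation rate in °C per °C. Fitted curves are min–max scaled to [0, 1]
(fraction of a soil's potential respiration), smoothed across MET with a
cubic spline (3 df), and the resulting MET × instantaneous-temperature
surface supports warming scenarios: the row at MET = m₀ is the non-adapted
response, the row at m₀ + Δ the adapted one.

## Worked example

Construct the curve with T_opt = 32.9 °C and T_inf = 22.4 °C (the shape of
a mid-MET pasture soil), then run a small synthetic study end to end:

```r
library(thermadapt)
p <- solve_mmrt_params(32.9, 22.4, amplitude = 6)
print(p)
#> MMRT parameters (T0 = 300 K)
#>   dH       39945.1 J/mol
#>   dS       -98.338 J/mol/K
#>   A         -5.000 J/mol/K^2
#>   B        -6977.5 J/mol/K
summarize_curve(p, eval_range = c(4, 50))
#> Topt = 32.90 C, Tinf = 22.40 C (grid 0.01 C on [4, 50] C)

cfg   <- sim_config(n_national = 10, n_gradient = 8, seed = 42)
study <- simulate_study(cfg)
run   <- run_pipeline(study$incubation, study$sites, seed = 42)
print(run)
#> thermadapt pipeline run
#>   soils in: 18 | converged fits: 18
#>   topt_c ~ MET (SAR): slope 0.360 (SE 0.051)
#>   tinf_c ~ MET (SAR): slope 0.328 (SE 0.049)
print(run$scenarios[[1]])
#> Warming scenario: MET 20 C -> 24.5 C (+4.5 C)
#>   at T = 24.5 C: non-adapted +25.4, adapted +16.3 points of potential vs pre-warming
```

The fitted SAR slopes are the adaptation rates: here ≈ 0.36 °C of T_opt
shift per °C of MET (small cohort; the generator's true value is 0.29, and
estimates tighten at the full 47-curve design). The scenario line reads:
after 4.5 °C of warming of a MET-20 soil, respiration at the new mean
temperature rises by 25 percentage points of the soil's potential maximum if
the community does not adapt, but only 16 points if it does — thermal
adaptation buffers the warming response.

## File formats

`run_pipeline()` accepts data frames or CSV paths and writes one CSV per
stage plus JSON reports.

`incubation.csv` — one row per tube:

| column | meaning |
|---|---|
| `soil_id` | soil/site identifier |
| `tube_id` | tube identifier |
| `temperature_c` | incubation temperature (°C) |
| `treatment` | `control`, `glucose`, or `blank` |
| `co2_ppm` | headspace CO₂ (ppm by volume) |
| `incubation_hours` | optional, default 5 |
| `soil_mass_g` | optional, default 2 |
| `headspace_ml` | optional, default 22 |

`sites.csv` — one row per soil: `soil_id`, `lat`, `lon` (decimal degrees),
`met` (°C), optional `ph`, `cohort`, `t30`, `block_id`.

Outputs: `curves.csv` (`soil_id`, `temperature_c`, `gir` in
µg CO₂-C g⁻¹ h⁻¹), `fits.csv` (thermodynamic parameters, AICc, `topt_c`,
`tinf_c`, `converged`), `adaptation.csv` (metric, model, slope, SE, λ, AIC),
`surface.csv` (long-format `met`, `temp`, `scaled`), one
`scenario_met<m>_plus<d>.csv` per scenario, `quality.csv`, `moran.json`,
`provenance.json`.

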