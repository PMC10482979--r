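---
title: "Methods: models, estimators and design choices in thermadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in thermadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermadapt)
```

This vignette is the package's own account of its science: what is modelled,
which knobs matter, what the synthetic-data generator does and does not
emulate, and where design was genuinely open and a choice had to be made.

## The thermodynamic model

Macromolecular rate theory (MMRT) describes the rate of an enzyme-catalysed
process as transition-state theory with a non-zero activation heat capacity
$\Delta C_P^\ddagger$:

$$\ln R_s = \ln\frac{k_B T}{h} - \frac{\Delta H^\ddagger_{T_0}}{RT}
- \frac{\Delta C_P^\ddagger\,(T - T_0)}{RT} + \frac{\Delta S^\ddagger_{T_0}}{R}
+ \frac{\Delta C_P^\ddagger\,(\ln T - \ln T_0)}{R}.$$

A negative $\Delta C_P^\ddagger$ makes the apparent activation energy fall
with temperature, producing a unimodal curve with an interior optimum
without any explicit denaturation term. The package's "modified" form lets
the heat capacity vary linearly with temperature,
$\Delta C_P^\ddagger(T) = A\,(T - T_0) + B$, substituted *pointwise* into
the rate equation exactly as written above; no extra integral correction
terms for thermodynamic self-consistency are added. Some formulations of
temperature-dependent-$\Delta C_P^\ddagger$ MMRT carry such terms; the
pointwise substitution is the model actually fitted here, and with $A = 0$
it reduces to the constant-heat-capacity model to machine precision
(`mmrt_log_rate()` is tested against an independently coded constant-form
oracle).

Interpreting the curve, two metrics matter:

* **T_opt** — the temperature of maximum rate (curve peak, where the first
  derivative crosses zero);
* **T_inf** — the temperature of steepest rise (peak of the first
  derivative of the *rate*, not of the log rate; the dashed-line convention
  of the field's figures).

`summarize_curve()` reads both off a regular evaluation grid: T_opt as the
argmax of the rate, T_inf as the argmax of the successive differences. Both
are therefore accurate to one grid step (default 0.01 °C; grid-refinement
consistency and agreement with a root-finder on the analytic derivative are
tested properties). When a community-level mixture of enzymes makes the
curve non-unimodal on the range, the largest peak is reported and the
summary flagged `multimodal`; an argmax on a range endpoint sets
`boundary_censored`.

All user-facing temperatures are °C; Kelvin appears only inside the model
functions, through a single conversion pair (`celsius_to_kelvin()`,
offset 273.15).

## From tubes to curves

The measurement design is a temperature-gradient block: per soil, paired
control (water) and glucose-amended Hungate tubes incubated ~5 h at ~2–50 °C
in 1–2 °C increments, plus four blanks, with headspace CO₂ read by IRGA.
Preprocessing is:

1. **Blank correction** (`blank_correct()`): subtract the per-soil mean
   blank concentration; negative corrected values are floored at zero with
   a warning.
2. **Gas-law conversion** (`ppm_to_mass_rate()`): ppm → µg CO₂-C g⁻¹ h⁻¹
   via the ideal gas law at each tube's own incubation temperature and
   1 atm. Defaults: 22 mL headspace (24 mL tube minus ~2 mL soil and
   solution), 5 h, 2 g fresh soil. The conversion constants are explicit
   arguments because the upstream IRGA calibration is lab-specific.
3. **Control subtraction** (`glucose_induced_curves()`): glucose-induced
   respiration gir(T) = rate_glucose(T) − rate_control(T) at temperatures
   paired within 0.25 °C. Non-positive differences are excluded (the model
   is fitted in log space), as are temperatures ≥ 42 °C — a few soils show
   a secondary respiration rise at the hottest temperatures (thermal-stress
   metabolism) that the model does not describe; the cutoff is the entire
   treatment of that phenomenon. Exclusions are counted per soil
   (`n_excluded`), pairing is a checked bijection, and curves with fewer
   than 11 usable points are flagged insufficient.

## Fitting and model comparison

`mmrt_fit()` minimises squared residuals of **ln(gir)** — the model is a
statement about the log rate, and multiplicative measurement noise is the
natural error model for gas-flux ratios — by Levenberg–Marquardt
(`minpack.lm::nlsLM`). MMRT least-squares surfaces are multimodal, so the
fit is multi-start: the enthalpy start comes from the Arrhenius slope of
the rising limb, the entropy start is chosen so the curve passes through
the empirical peak, and B × A start grids are
$\{-500, -1000, -2000, -4000\}$ J mol⁻¹ K⁻¹ ×
$\{0, \pm 5, \pm 20\}$ J mol⁻¹ K⁻², best start by residual sum of squares.
Convergence per start: relative RSS tolerance $10^{-10}$, at most 5000
objective evaluations.

Variants are compared by AICc with the Gaussian log-likelihood up to a
constant, $\mathrm{AIC} = n\ln(\mathrm{rss}/n) + 2k$ and
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$, counting the residual
variance: $k = 5$ for varying and $k = 4$ for constant heat capacity.
`select_variant()` takes the lower AICc, declares $|\Delta \mathrm{AICc}|
\le 2$ "equivalent", and resolves ties and equivalence to the varying
variant — the variant used for the headline analyses.

Two cohort-level policies:

* curves with fewer than 11 usable points are refused rather than fitted
  (`fit_cohort(min_points = 11)`), mirroring the design's minimum usable
  temperature count — this is the path by which a 48-soil study yields 47
  analysed curves;
* an **adequacy guard**: when the AICc-preferred variant's optimum runs off
  the 4–50 °C summary grid (the signature of a runaway positive
  heat-capacity slope overfitting data that stop at 42 °C) while the other
  converged variant has an interior optimum, the other variant is used.
  Without the guard a handful of such fits per cohort report optima of
  ~50 °C and contaminate the adaptation regression.

Fitted-curve summaries are evaluated on 4–50 °C even though fitting stops
below 42 °C: optima genuinely sit at and slightly above the warmest fitted
temperatures, and capping the summary grid at the cutoff would censor them.
Estimates of optima beyond the data support are accordingly noisier — see
Limitations.

## Adaptation inference

With one (T_opt, T_inf) pair per soil and site metadata, adaptation is the
regression of each metric on mean environmental soil temperature (MET).
Because half the soils sit on a metre-scale geothermal transect and the
rest are scattered country-wide, residuals are spatially structured;
`morans_i()` quantifies this (permutation test, default 9999 permutations,
plus the analytic normal approximation via `ape::Moran.I` as an independent
implementation), and the headline estimator is a **spatial simultaneous
autoregressive error model** (`sar_error()`):
$y = \beta_0 + \beta\,\mathrm{MET} + u$, $u = \lambda W u + \varepsilon$,
fitted by maximum likelihood with the log-determinant from the eigenvalues
of $W$ and $\lambda$ profiled out by bounded scalar optimisation
(tolerance $10^{-8}$, $\lambda$ constrained by the reciprocal extreme
eigenvalues). With $\lambda = 0$ the estimator reduces exactly to OLS (a
tested identity), and at fixed $\lambda$ it matches a brute-force GLS
oracle.

Weights default to k-nearest neighbours, $k = 8$, symmetrised and
row-standardised, over great-circle distances; transect positions are
embedded as metre-scale latitude offsets so one distance metric serves both
cohorts. k-NN was chosen over a distance band because the mixed
dense-transect + sparse-national geometry leaves no band radius without
islands; a distance-band constructor is provided for sensitivity analyses.
The error (rather than lag) SAR form follows from the way the spatial
structure enters — through residual relatedness among neighbouring sites,
not through a diffusion of the response itself. OLS results are always
reported alongside (`adaptation_slopes()`).

`compare_predictors()` ranks MET, pH and MET+pH models by AIC (pH is the
obvious confound on a geothermal gradient, where it correlates strongly and
negatively with MET), and `qc_checks()` runs two labelled quality-control
analyses: 30-day-pre-sampling temperature versus annual MET slopes, and a
two-sample t-test of the metrics between the two incubation blocks. Both
are QC, not headline inference; two-sided tests at $\alpha = 0.05$.

## The thermal surface and warming scenarios

Each converged curve is predicted on a 4–42 °C grid (0.1 °C), min–max
scaled to $[0, 1]$ — the scaled value is the fraction of that soil's
potential respiration — and, per instantaneous temperature, a cubic
smoothing spline with 3 effective degrees of freedom is fitted to scaled
rate against MET and evaluated on a 0.1 °C MET grid (`build_surface()`;
df is reduced with a warning when there are fewer than df + 1 distinct MET
values, and cells are clipped to $[0,1]$).

`scenario(surface, met0, delta)` contrasts the surface row at `met0` (a
community that does not adapt to warming) with the row at `met0 + delta`
(one that has). Differences default to **percentage points of the potential
maximum** (`units = "points"`): the scaled scale is already a fraction of
potential, and point differences are well defined everywhere, including
where the non-adapted rate approaches zero. The relative form
(`units = "ratio"`) is available, with near-zero denominators masked at a
threshold (default 0.02). The baseline for "change versus pre-warming" is
the non-adapted row evaluated at $T = \mathrm{met}_0$.

## The synthetic-study generator

`simulate_study()` exists so every stage is testable without field data. It
emulates: 28 scattered national sites plus 20 sites log-spaced along a
metre-scale geothermal transect; MET 11–35 °C (exponential decay with
transect distance; cool-temperate national sites); pH falling linearly with
MET on the gradient (sampled correlations ≤ −0.8) and independent of MET
nationally; spatially correlated site effects
$u = (I - \lambda W)^{-1}\varepsilon$ (λ = 0.3, sd 1.8 °C) added to both
metric targets as a curve-level shift; true optima on the lines
$T_\mathrm{opt} = 33.7 + 0.29\,(\mathrm{MET} - 20)$ and
$T_\mathrm{inf} = 23.2 + 0.27\,(\mathrm{MET} - 20)$ (anchors from the
reference curve shape, 10.5 °C apart); paired tubes at 2–50 °C in 2 °C
steps with a monotone Arrhenius soil-organic-matter baseline under the
control (so control subtraction is non-trivial); lognormal 5 % noise on
every tube's rate; inversion of the same gas-law used by preprocessing, on
top of a 420 ppm ambient baseline with jittered blanks.

True curves are constructed by `solve_mmrt_params()`: the log-rate
derivative is linear in both $\Delta H^\ddagger$ and $B$, so $B$ has a
closed form given the target optimum, and $\Delta H^\ddagger$ is found by a
1-D root search on the achieved inflection — both targets are hit exactly
(to the summary grid), which is what makes round-trip recovery tests sharp.
This joint solve replaces the looser "fix enthalpy from a prior, only
verify the inflection" approach because the configured T_inf slope would
otherwise be uncontrollable. Targets whose optimum falls near the 300 K
reference are unsolvable in this parameterisation (the $B$ coefficient
degenerates there); such a site's random effect is shrunk stepwise toward
the regression line until the target is reachable, with the achieved values
recorded as the truth. pH is generated but has no causal effect on curve
parameters by default, matching the structure the inference is meant to
detect; a pH effect can be added for power studies. The `bad_soil` knob
gives one soil sparse block coverage and a near-zero signal under extreme
noise, producing an unusable curve that exercises the exclusion path.

What the generator does **not** emulate: the secondary high-temperature
respiration rise (the 42 °C cutoff therefore never has to repair a
misspecified model, only drop clean MMRT decay); drift or calibration error
in the IRGA; soil moisture effects and dry-mass normalisation;
non-lognormal outliers; and any causal pH–curve link. Passing tests
therefore demonstrate that the estimators recover the truth under the
stated noise and spatial structure — not that field data meet those
assumptions.

## Numerical choices and degenerate inputs

* Summary grids: 0.01 °C (refusing spacings above 0.05 °C); optima accurate
  to one grid step.
* Derivatives are analytic and tested against central differences at
  relative tolerance $10^{-6}$.
* AICc requires $n > k + 1$; smaller n is an error, and fits with fewer
  than $k + 2$ points are refused outright.
* Collinear designs (rank deficiency, |r| > 0.999 between MET and pH) are
  errors or flags, never silent drops.
* Zero-variance inputs to Moran's I, all-coincident site geometries, flat
  curves offered for scaling, and MET values outside the surface grid all
  raise informative errors.
* Ties in AICc go to the varying-heat-capacity variant; ties in the grid
  argmax resolve to the first (coolest) grid point, made irrelevant by the
  grid-refinement property.
* Pipeline runs are deterministic given a seed; permutation tests take an
  explicit seed.

## Problem sizes used by the test-suite and acceptance script

Simulation-backed checks use sizes chosen to keep the whole suite
comfortably within a laptop-scale run while leaving Monte-Carlo error well
below the asserted bands: 20 replicate 48-soil cohorts for end-to-end slope
recovery (the acceptance script uses 16), 200 curves for noisy parameter
recovery, 100 random parameter sets for the closed-form optimum oracle, 500
spatially-random datasets at 99 permutations each for the uniformity of
Moran p-values, and 60 replicates for SAR λ/β recovery.

## Known limitations

* Optima above the fitted temperature support (here, above ~40 °C) are
  extrapolations of the fitted curve; their estimates are noticeably
  noisier and shrink the estimated adaptation slope slightly at the hot end
  of the MET range. The generator's conditions keep most true optima inside
  the support, as the emulated design did.
* The pointwise linear-$\Delta C_P^\ddagger$ substitution is a
  phenomenological choice; $A$ is weakly identified from a single curve
  (recovered to ~10 % only on noiseless data) and should be interpreted as
  curvature control, not as an enzyme property.
* The SAR neighbourhood definition is a modelling choice the data cannot
  fully pin down; slopes should be (and in the tests are) robust to k-NN
  versus distance-band weights, and both OLS and SAR estimates are always
  reported.
* Scenario projections assume substrate-unlimited potential respiration
  and a static community size: no substrate-supply dynamics, biomass
  change, or carbon-use-efficiency shifts under warming.
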