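---
title: "Modelling nitrogen-limited crop growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogen-limited crop growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cropnp)
```

This vignette documents the models implemented in `cropnp`, the
assumptions behind them, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions a maintainer would want written down.

## The two growth models

### Light- and CO₂-driven growth (the energy cascade)

The modified-energy-cascade family of crop models treats daily biomass
production as a cascade of efficiencies applied to the incident photon
flux.  `cropnp` implements the biomass branch:

$$\frac{d\hat m_B}{dt} = \frac{\check m_C}{w_C}\,\hat{\dot n}_C,\qquad
  \hat{\dot n}_C = 0.0036\, H\, \eta_C\, A(t)\, \Phi_\gamma\,
  Y_Q(\Phi_\gamma, c_{CO2})$$

* $\hat{\dot n}_C$ is the daily areal carbon gain
  [mol\_C d⁻¹ m⁻²]; the constant 0.0036 converts μmol s⁻¹ sustained over
  $H$ hours into mol d⁻¹ ($3600 \cdot 10^{-6} = 0.0036$), which is why
  $H = 24$ h with all efficiencies at 1 and $\Phi_\gamma = 1$ must give
  exactly 0.0864 — the package's unit-anchor test.
* $A(t) = A_{max}(t/t_A)^n$ before canopy closure at $t_A$, then
  $A_{max}$: young stands intercept almost nothing, closed canopies about
  93 %.
* $Y_Q$ is the canopy quantum yield [mol C fixed per mol photons
  absorbed], evaluated from a per-crop response surface over the basis
  $[1/\Phi, 1, \Phi, \Phi^2, \Phi^3] \times [1/c, 1, c, c^2, c^3]$ and
  clamped at 0; crops with canopy senescence ramp it linearly down from
  $t_Q$ to a terminal fraction at maturity $t_M$.
* $\eta_C$ is the 24-h carbon use efficiency; constant for leafy crops,
  declining linearly after $t_Q$ for the legumes.

Total biomass integrates the rate from emergence; edible biomass
accumulates the fraction $f_E$ of growth after organ-formation onset
$t_E$.  Temperature, humidity, transpiration, oxygen production and
stomatal conductance are deliberately out of scope: the biomass branch
assumes they are not growth limiting.

**Crop coefficient provenance.**  The nine bundled crop files
(`inst/extdata/crops/*_synthetic.json`) use the canonical functional
forms above, but the quantum-yield coefficient matrices are a *synthetic
calibration*: each was constructed as
$Y_Q = Y_{max}(1 - k_p\Phi)(1 - K_c/c)$ — a hyperbolic CO₂ saturation
times a linear high-light attenuation, expressible exactly in the
standard basis — anchored to plausible nominal canopy quantum yields
(0.041–0.060 mol mol⁻¹ across crops), with developmental time points,
carbon fractions and harvest indices set to representative literature
magnitudes.  They are suitable for testing the machinery and for
methodological work; users with original coefficient tables should supply
their own files via `mec_crop("path/to/file.json")` (the schema is
documented in `?mec_crop`).  Each file declares a validity box
(Φ ∈ [50, 1000] μmol m⁻² s⁻¹, c ∈ [330, 1300] ppm); evaluation outside it
warns and clamps rather than failing, since planning studies routinely
sweep wide environment grids.

### Nitrogen-driven growth (nitrogen productivity)

Nitrogen-productivity theory posits that, with nitrogen limiting, biomass
growth is proportional to the nitrogen mass the plant currently holds:

$$\frac{dm_B}{dt} = \dot Y_N \, m_N,\qquad
  \dot Y_N = \eta_N(t)\,\mu_N(t)\,\eta_u$$

* $m_N(t)$ follows a three-parameter logistic (rate $r$ [d⁻¹], ceiling
  $K$ [g_N], initial mass $m_{N0}$, global scale $\alpha$), evaluated in
  the overflow-safe form $\alpha K / (1 + ((K-m_{N0})/m_{N0})e^{-rt})$.
  The literal reading $m_N(0) = \alpha\,m_{N0}$ is implemented (α rescales
  the initial condition along with the asymptote).
* $\eta_N(t) = b_\eta + m_\eta t$ (nitrogen use efficiency,
  g_DW g_N⁻¹) and $\mu_N(t) = b_\mu + m_\mu t$ (relative nitrogen
  accumulation rate, d⁻¹) are linear in time — an empirical approximation
  valid over the measured window, not before or after it.
* $\eta_u$ is an uptake-efficiency placeholder for abiotic effects on
  uptake (temperature, pH); no data constrain it, so it defaults to 1 and
  is exposed as a time-constant parameter.

Because the linear forms can turn negative late in life (productivity
does decline near the end of the growth phase), `simulate_np()` clamps a
negative growth rate at zero with a warning by default;
`clamp_negative = FALSE` permits biomass loss for users who want the
un-clamped reading.  The time origin is emergence ($t = 0$ d_AE); initial
biomass defaults to 0 and is configurable.

**Identifiability.**  The triple $(\alpha, K, m_{N0})$ carries an exact
scaling symmetry: $(\alpha, K, m_{N0}) \to (c\alpha, K/c, m_{N0}/c)$
leaves $m_N(t)$ — and therefore every observable — unchanged.  The model
is over-parameterized in this direction, so the default fitting profile
holds $\alpha = 1$ fixed (and $\eta_u = 1$); either can be freed by
supplying bounds for it.  A second, independent ridge is the
$\eta_N\cdot\mu_N$ product: biomass and productivity observations
constrain only the product, never the split.  Consequences are discussed
under *Fitting* below.

### The hybrid limiting-factor simulation

`hybrid_simulate()` evaluates both models' growth rates on a shared grid
(NP output converted to areal through the planting density $\sigma_N$)
and takes the pointwise minimum as the realized rate, accumulating a
single biomass state.  Design choices, made where the flowchart level of
the idea leaves room:

* the comparison is **rate-level**, not curve-level, and both models are
  indexed by calendar time (no developmental-stage re-mapping driven by
  accumulated biomass);
* ties label the step `"both"` (no numerical consequence);
* edible biomass follows the energy-cascade allocation rule ($f_E$ after
  $t_E$) applied to *realized* growth; the edible fraction under nitrogen
  limitation may well differ, so `f_E` is an argument.

With the pointwise-minimum rule the hybrid reproduces the single-model
curves exactly in the degenerate cases and can never exceed either
stand-alone curve — both properties are tested.  One subtlety: the
light-driven rate is exactly zero at $t = 0$ (no canopy), so the very
first instants are always labelled light-limited unless the nitrogen rate
is also zero there.

## Empirical quantities from harvest tables

Harvests are destructive, so no per-plant trajectory exists; all derived
quantities are interval estimates over consecutive harvest pairs,
reported at interval midpoints:

* productivity $\dot Y_N = (\Delta m_B/\Delta t) / \bar m_N$ with
  $\bar m_N$ the two-point arithmetic mean (the "mean nitrogen over the
  interval" is not given a formula anywhere authoritative; the two-point
  mean is the simplest consistent choice);
* NUE $\eta_N = \Delta m_B / \bar m_N$; RNAR
  $\mu_N = \Delta \ln m_N / \Delta t$;
* plant nitrogen mass $m_N$ = fresh weight × fresh-weight nitrogen
  fraction, the form in which the assays report it.

Standard deviations propagate to productivity by first-order (delta
method) propagation through that expression, verified in the tests
against a 10⁵-draw Monte-Carlo oracle.  Condition-average productivity is
the unweighted mean of the interval estimates; pooling alternatives are
one line on the returned interval table.  The loader maps arbitrary
column names through a schema object, converts sowing-based to
emergence-based time (default offset 3 d), and carries any unmapped
columns (nutrient-solution chemistry, pH) as untouched auxiliary data.

## Fitting

`fit_np()` minimizes a weighted squared-residual objective over a bounded
box with a seeded differential-evolution search, then polishes the best
member with L-BFGS-B, returning the better iterate.

**Estimator-consistent predictions.**  The observed productivity series
is an interval estimator, so the model is made to predict it with the
*same* estimator applied to its own trajectory (model biomass forward
difference over the same interval divided by the model's interval-mean
nitrogen).  With instantaneous-model predictions instead, the objective
is nonzero at the true parameters even on noiseless data and the
recovered $r$ is biased by several percent; with consistent estimators,
noiseless recovery is exact — this is tested.  The optional `nue`/`rnar`
channels are the exception: they compare the $\eta_N$/$\mu_N$ *lines*
directly against the empirical series.  They are the only channels that
identify the $\eta_N/\mu_N$ split, but the lines and the logistic
log-derivative cannot agree exactly (the model is overdetermined in that
direction), so they carry an intrinsic mismatch and are not in the
default channel set.

**Weights.**  The channels carry different units; each channel's default
weight is the reciprocal sample standard deviation of its observed
values, so no channel dominates by unit choice.  Weights are overridable.

**Optimizer settings.**  rand/1/bin differential evolution with
population 15 × (free parameters), per-generation mutation dither
F ~ U(0.5, 1), crossover 0.7, Latin-hypercube initialisation, tolerance
10⁻⁸, at most 1000 generations — the configuration popularised by the
widely used SciPy implementation, adopted after fixed-F rand/1/bin proved
prone to a boundary basin ($r$ at its lower bound) in the baseline-curve
fits.  The positive scale parameters $r, K, m_{N0}$ are searched on a
log₁₀ scale (their plausible ranges span orders of magnitude); bounds and
results are always reported on the natural scale.  All stochastic steps
take an explicit integer seed, which the result records.  The default
$m_{N0}$ box is [0.1 mg, 10 mg]: a germinated seedling holds on the order
of a milligram of nitrogen.

**Baseline-curve fits.**  `fit_np_to_mec()` fits the NP biomass
trajectory to a light-driven baseline curve with no nitrogen
observations, so the nitrogen state is latent.  Because only the
$\eta_N\mu_N$ product matters there, the NUE intercept is pinned at a
representative 10 g_DW g_N⁻¹ by default and the other parameters absorb
the scale.  The package reproduces all nine bundled baselines with
relative RMSE below 1 % of final biomass (the acceptance suite asserts
≤ 2 %).  A corollary worth stating plainly: parameters from a
biomass-only baseline fit are a *descriptive* parameterisation of the
curve, not estimates of nitrogen dynamics — which latent trajectory the
optimizer returns within the ridge is arbitrary.  Sensitivity rankings
should therefore be computed around nitrogen-constrained fits (see
below).

## Sensitivity analysis

The quantity of interest is the trapezoidal time integral of total
biomass — a scalar summarising the whole trajectory.  Parameters are
drawn from independent uniform boxes, built either by perturbing a
nominal fit ±10 % per parameter or from the elementwise min/max across a
collection of fits.

**Borgonovo δ estimator.**  The index family is defined
moment-independently (half the expected total-variation distance between
unconditional and parameter-conditional QoI densities); the estimator is
a choice.  `cropnp` partitions each parameter into $M = 20$
equal-frequency classes and estimates densities with Gaussian kernels
sharing the full-sample bandwidth.  Kernel TV estimators have a positive
finite-sample bias, so a bootstrap bias reduction
($2\hat\delta - $ mean of 5 bootstrap replicates) is applied and the
result clipped to [0, 1].  Under this estimator an inert dummy parameter
scores ≈ 0.02–0.04 at n = 5000 (the tests bound it at 0.05), and the
estimate at n = 5000 agrees with an n = 10⁵ run of the same estimator to
within 0.02 on a standard strongly-nonlinear test function.  Rows are
canonicalized by QoI order before estimation, making the result exactly
invariant under joint permutation of sample rows and bit-reproducible
under a fixed seed.

**Classifier-screened sampling.**  Large uniform boxes can produce
non-physical trajectories (negative biomass integrals) that must be
excluded, wasting simulations.  The five-step accelerator: simulate a
small initial design ($N_0 = 200$, order 10²), label samples physical
when the QoI is strictly positive (zero counts as non-physical), train a
probabilistic classifier, draw a large candidate pool
($N_* = 20\,000$), simulate only candidates whose predicted probability
reaches the threshold (default 0.5), and pool all positive-QoI samples
from both stages for the δ estimation.  The classifier is a
single-hidden-layer neural network (`nnet`, 6 hidden units, weight decay
0.01) on min-max-standardized inputs; if only one class is present it
degrades to a constant predictor with a warning, which makes the
screening vacuous — exactly the right behaviour for an all-physical box.
As the threshold tends to 0 the procedure reduces to plain unscreened
sampling.

**Which nominal for the lettuce ranking?**  Around
nitrogen-constrained lettuce fits, the accumulation rate $r$ attains the
largest δ (≈ 0.21 under ±10 % perturbation, ahead of $b_\eta$ and
$b_\mu$ at ≈ 0.19), consistent with nitrogen arrival timing driving the
integrated biomass.  Around biomass-only baseline fits the ranking
instead reflects the arbitrary ridge position — with nominals whose
$\mu_N$ intercept lands near its late-life zero crossing, $\delta(b_\mu)$
inflates above $\delta(r)$.  The acceptance check therefore calibrates
the nominal on the (noiseless) reference experiment with
truth-centred ±50 % bounds — the same protocol as the recovery check —
and asserts the rank of $r$ there.

## The synthetic experiment generator

`generate_experiment()` emulates the structure of a three-condition
hydroponic lettuce study: destructive harvests at 11, 20, 25, 30, 35 and
40 d after emergence (a 43 d harvest is excluded by default — at that age
lettuce bolts and vegetative-growth measurements stop being meaningful),
planting density 19.2 m⁻², fresh-weight water fraction 0.95, PPF
225 μmol m⁻² s⁻¹, CO₂ 525 ppm, photoperiod 16 h d⁻¹.  Per-plant dry
biomass and nitrogen fraction receive multiplicative lognormal noise
parameterised by coefficients of variation (default 0.1, with 8 plants
per harvest), so noise scales with growth and masses stay positive.

The three condition truth sets (`default_np_parameters()`) were chosen
once to land in the qualitative regime such a study reports: highest $r$
and lowest ceiling $K$ under deficiency (scarce nitrogen is scavenged
fast but runs out), similar ceiling but weaker biomass conversion under
excess ammonium (stress), normal condition growing most by harvest;
nitrogen fractions of fresh weight in the few-tenths-of-a-percent range
declining with age; mean productivities of order 1 g_DW d⁻¹ g_N⁻¹.  All
conditions share $\alpha = 1$ and $m_{N0} = 2$ mg.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: plant-to-plant variance structure beyond
independent lognormal noise (no shelf effects, no correlation between a
plant's biomass and its nitrogen fraction), germination loss and plant
selection at transplanting, solution-chemistry feedback (nitrate/ammonium
depletion altering uptake), bolting, measurement-method effects of drying
and assay choice, and any model misspecification (the data are generated
by the NP model itself, so recovery tests validate the estimation
machinery, not the model's adequacy for real lettuce).

## Numerical choices

* **Integration** is fixed-step trapezoid quadrature on the user grid
  (default Δt = 0.1 d): both models' rates are closed-form functions of
  time, so no stiff ODE machinery is warranted.  Halving the step changes
  final biomass by well under 0.1 %; refinement tests pin this.
* **Logistic evaluation** uses the $e^{-rt}$ rearrangement; it is exact
  at $K = m_{N0}$ and immune to overflow at large $rt$; agreement with an
  independently integrated logistic ODE is ~10⁻¹⁰ relative across a
  parameter grid.
* **Edible-biomass integration** splits the grid interval containing
  $t_E$ and interpolates the rate at $t_E$, so edible totals do not
  depend on whether $t_E$ falls on a grid point.
* **Degenerate inputs**: collapsed bounds fix a parameter; a constant QoI
  yields all-zero indices; a single-class label set yields a constant
  classifier (warning); a single-point curve has zero area (warning);
  grids extending past maturity truncate (warning).
* **Tie-breaks** in the hybrid use relative tolerance 10⁻⁹ on step
  increments.

## Problem sizes

The shipped test-suite and acceptance-script runs use: 0.1 d grids
(301–1321 points per curve), 72 parameter combinations for the logistic
oracle, 20 noisy replicates for the recovery study, nine baseline-curve
fits, n = 5000 for the dummy-null index and $N_0 + N_* = 20\,200$ model
evaluations per screened analysis — sizes chosen so each quantity's
estimator noise sits comfortably inside the margins being asserted while
a full run stays in the minutes range on one core.

## Known limitations

* The bundled crop coefficients are a synthetic calibration (above); the
  package's numerical claims about specific crops inherit that status.
* $\eta_N$, $\mu_N$ linearity is an in-window approximation; predictions
  before the first harvest or past bolting are extrapolation.
* The $\eta_N/\mu_N$ split and $(\alpha, K, m_{N0})$ scale are not
  identifiable from biomass/nitrogen/productivity data alone; reported
  splits from default fits are arbitrary within the ridge.
* No mechanistic uptake model: solution-chemistry columns are loaded for
  plotting, never modelled, and $\eta_u$ is a placeholder.
* The hybrid's minimum rule composes two calibrated models; it does not
  model interaction effects (e.g. nitrogen-starved canopies absorbing
  less light) beyond what each model already carries.
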