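---
title: "Methods: Boltzmann temperature scaling, diel oxygen fluxes, and centered mixed models in mesotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Boltzmann temperature scaling, diel oxygen fluxes, and centered mixed models in mesotherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesotherm)
```

`mesotherm` analyses warming experiments in enclosed aquatic ecosystems:
replicate mesocosms held at different temperatures by heaters, crossed with
food-web treatments (algae only A; algae + grazers AG; algae + grazers +
predators AGP), observed weekly. This vignette is the package's account of
its models, its estimators, the choices that were genuinely open, and what
the synthetic-data generator does and does not emulate.

## 1. Metabolic scaling framework

Every temperature covariate in the package is the Boltzmann inverse
thermal energy $1/kT$ (eV$^{-1}$), with $k = 8.617\times10^{-5}$ eV/K and
$T$ in Kelvin. A rate obeying the Boltzmann–Arrhenius form
$b \propto e^{-E/kT}$ is ln-linear in $1/kT$ with slope $-E$; the helper
`activation_energy()` owns this sign convention so it is applied uniformly
(a rate that speeds up with warming has positive $E$; a standing stock
that declines with warming has negative $E$ under the same rule).
Temperatures cross the I/O boundary in °C (how probes report them) and are
converted to Kelvin internally.

At ecosystem scale,

$$B_R = b_0(T_c)\, e^{-E\,(1/kT - 1/kT_c)}\, M_B\, \langle m^{\alpha-1}\rangle ,$$

with total biomass density $M_B$ (g/L) and the mass-corrected average
$\langle m^{\alpha-1}\rangle = \sum m^\alpha / \sum m$, which adjusts
total biomass for the allometric scaling of metabolism with body size
($\alpha$, default 0.75). `ecosystem_rate()` and `biomass_from_rate()` are
exact algebraic inverses, a property the tests assert to $10^{-12}$
relative error. The reference temperature $T_c$ is arbitrary in the
algebra; the package defaults to centering on the grand mean of observed
temperatures (see §3), and the constant is overridable in
`phys_constants()`.

The theoretical trophic-cascade expression
(`cascade_theory_lnratio()`) gives the log ratio of producer biomass with
versus without predators as the difference of two treatment-specific rows,
each $\ln b_0 + \ln\langle m^{\alpha-1}\rangle - (E_b + E_m)/kT$, the
AG row minus the AGP row — the reading consistent with the logarithm of
the corresponding biomass-ratio expression. Setting all four $E$ terms to
zero — the
"first-order" metabolic-scaling null — makes the ratio
temperature-independent, which the tests verify.

## 2. Diel oxygen fluxes

Net ecosystem production (NEP) is estimated from the dawn→dusk change in
dissolved oxygen, ecosystem respiration (ER) from dusk→dawn of the next
day, each corrected for the change in equilibrium saturation between the
two bounding temperatures, converted to molar units
($z = 31.25\ \mu$mol O₂ per mg), and divided by the elapsed time:

$$\mathrm{NEP} = \left|\frac{(\Delta \mathrm{O}_2 - \Delta[\mathrm{O}_2]_E)\, z}{t_{dusk}-t_{dawn}}\right|.$$

Three choices here were genuinely open:

* **Saturation model.** The equilibrium concentration is
  $[\mathrm{O}_2]_E = \exp(7.7117 - 1.31403 \ln(T + 45.93))$ mg/L with $T$
  in °C. This is the standard freshwater saturation form; it is strictly
  decreasing in temperature and loses ≈0.83 mg/L between 20 and 25 °C,
  matching the expected ≈1 mg/L per 5 °C. A "literal" mode evaluating the
  raw expression $\exp([\mathrm{O}_2]_{water} - [\mathrm{O}_2]_{sat}\ln(T+45.93))$
  with user-supplied terms is retained behind
  `equilibrium_oxygen(mode = "literal")` purely for audit: for typical
  inputs that expression is dimensionally incoherent (exponent ≈ −25 at
  20 °C) and it is never the default.
* **Bracket placement.** $z$ multiplies the whole corrected oxygen
  difference and the division by elapsed time comes last; units then come
  out as μmol L⁻¹ h⁻¹. Because the correction is a difference of
  equilibrium values, correcting concentrations before differencing or
  correcting the difference are algebraically identical.
* **Signs.** Both fluxes are reported as positive numbers (absolute value
  taken after the full corrected computation); the signed values and the
  correction components are retained in `diel_fluxes()` output for
  diagnostics.

Times are decimal hours; the second dawn belongs to the following day
(`t_dawn2 = t_dawn + 24` in the generator). Air–water gas exchange is not
modelled: the tanks are closed systems for this purpose.

## 3. Centered design and mixed models

`center_design()` decomposes each observation's $1/kT_{wj}$ into a
between-ecosystem part (tank mean $1/k\bar T_j$ over that tank's observed
weeks, centered on the grand mean of tank means) and a within-ecosystem
part (weekly deviation from the tank mean). The decomposition is exact —
`within + between + grand = 1/kT` row by row — and the within deviations
sum to zero per tank; both are asserted in tests. Separating the two lets
the slope on average tank temperature (the experimentally imposed
gradient) be estimated apart from the slope on weekly weather-driven
fluctuations, which can have the opposite sign. Whether the tank mean
should come from hourly logger data or the weekly means is not decidable
from a weekly table; the package uses the mean of weekly means (the tank's
observed weeks), its only option given the input schema.

`fit_lmm()` fits Gaussian random-intercept models by **maximum
likelihood** (lme4, `REML = FALSE`). ML is required because the candidate
sets differ in fixed effects, so their likelihoods must be comparable; it
also matches the published df accounting, where the parameter count is
fixed effects + random-intercept variance + residual variance (the full
chlorophyll model: 10 fixed effects + 2 variances = 12). The
nested candidate sets built by `model_set_specs()` carry exactly these
parameter counts (3, 4, 5, 5, 6, 6, 8, 9, 11, 12 for the ten-model
response sets; 3–6 for the cascade and zooplankton sets), which the tests
pin down as a regression guard on the df convention.

Treatment coding: A is the reference level; AG and AGP enter as 0/1
indicators. Chlorophyll zeros are dropped from ln models (and counted in
the design attributes) rather than offset; zooplankton counts use
$\ln(x+1)$ so that zero counts — most plausibly detection failures at low
density — enter as 0.

Model ranking uses AICc
($-2\ell + 2p + 2p(p+1)/(n-p-1)$) and Akaike weights. All models of a set
are fitted on the identical listwise-complete row set (complete cases
across the union of terms); fitting each model on its own complete cases
would make the criteria incomparable, and the published per-table constant
$n$ is consistent with a common row set. Models within $\Delta\mathrm{AICc} < 2$
are treated as equivalent; `model_average_conditional()` averages a
coefficient over only the models containing it, with weights renormalised
over that subset (and can be restricted to the equivalence set via
`delta_max`).

Composite (pooled) quantities: for treatment $Z$ the between-ecosystem
slope is $\beta_2 + \beta_5 Z$ and the intercept $\beta_0 + \beta_4 Z$;
the within slope is $\beta_1 + \beta_3 x_B + \beta_6 Z$, evaluated by
default at $x_B = 0$, i.e. at the grand-mean temperature — any other
evaluation point can be passed, and flipping its sign flips only the
$\beta_3$ contribution. Intervals use the delta-method standard error
$\sqrt{c^\top V c}$ with the normal 1.96 multiplier; a t-quantile is
available via the `df` argument of `composite_ci()` for small-sample use.

### Trophic cascade

The cascade response is $\ln(\mathrm{chla}_{AGP}/\mathrm{chla}_{AG})$ for
the tank pair at each heater power, defined only where both members have
positive chlorophyll. Its model set regresses the ratio on
within-power-pair centered $1/kT$, numeric week centered on its mean (the
week coding is not specified by the source; centering is ours), and their
interaction, with a random intercept per power level. Because the set has
no between-power fixed temperature term, the across-power gradient is
carried by the random intercepts. The realized final-week temperature
dependence (`cascade_temperature_dependence()`) is therefore computed by
regressing conditional predictions — fixed effects plus intercept BLUPs —
for that week's observations on their $1/kT$, and negating the slope. This
is our interpretation of "fixed effects plus random effect"; it is flagged
as such, and other constructions (e.g. adding BLUP regressions to a pooled
fixed slope) coincide with it in the linear Gaussian case.

### Zooplankton densities

Densities (counts per 10 L; the package declares this unit once rather
than mixing per-litre and per-10 L axes) are modelled on grand-centered
weekly $1/kT$ without the within/between decomposition, with a predator
indicator (AG vs AGP; AG is the reference). Their temperature dependence
is reported in the *density* convention — the coefficient on $1/kT$
itself, positive when density declines with warming — because that is how
grazer declines are conventionally quoted; `activation_energy()`
documents both conventions side by side.


## 4. The synthetic generator

`synthetic_config()` encodes the study conditions: 30 tanks = 10 heater
power levels (0–450 W in 50 W steps) × three treatments, weeks 2–9 (240
tank-weeks), a declining seasonal baseline with heater offsets chosen so
tank means span ≈19.7–26.1 °C (baseline 22.5 °C at week 2, −0.8 °C/week,
+1.42 °C per 100 W), and 21 of 240 diel series missing. Paired tanks at
the same power share the realized weekly temperature, as in the
experiment.

Generating coefficients follow the fitted values reported for this design:
chlorophyll $\beta_0 = 2.05$, $\beta_1 = -0.52$, $\beta_2 = 1.30$,
$\beta_3 = 1.34$ with treatment-specific between-slopes adding 4.0 (AG)
and 0.3 (AGP) — so the grazer-only treatment loses three orders of
magnitude of standing stock over a 10 °C span while the other treatments
lose about one; NEP and ER use the reported top-model coefficients
(intercepts −6.42 and −6.09, between slopes −1.40 and −1.32, i.e.
$E_{NEP} = 1.40$, $E_{ER} = 1.32$); Daphnia carry a −0.23 predator effect
on the log mean and no temperature trend; copepods decline with a 1.21
coefficient on $1/kT$. Counts are Poisson — no count distribution is
specified by the source, and Poisson is the minimal choice; overdispersion
is a known omission.

Noise levels are **not** reported quantities: the source gives no residual
or tank-level variances. The package fixes them once at tank-intercept SD
0.2 and residual SD 0.3 (0.25 for fluxes) on the ln scale — visible
scatter around strong gradients, and a signal-to-noise under which the
regression design has the power it was built for (ten levels spanning a
wide gradient rather than replication within levels). They are config
entries, not claims about the real experiment.

Two construction details matter for testing. First, the diel series is
built by *inverting the estimators*: dawn oxygen is anchored at the
saturation value for the dawn temperature (an arbitrary but documented
anchor), and dusk and second-dawn readings are constructed so that
`nep_from_diel()`/`er_from_diel()` (with the standard correction) return
the latent fluxes exactly; the round trip is asserted to $10^{-10}$.
Second, every component draws from its own seeded substream, so changing,
say, zooplankton settings cannot perturb the temperature draws; a fixed
root seed gives byte-identical output files.

What the generator does *not* emulate: consumer–resource population
dynamics (the analysis is statistical, not dynamical), species
composition and its turnover, benthic algae, overdispersed or
zero-inflated counts, temporally autocorrelated weather, and
measurement-instrument error structure. Passing tests therefore show that
the estimators and inference machinery are correct under the assumed
ln-linear mixed structure — not that real mesocosm data satisfy that
structure.

## 5. Numerical choices and degenerate inputs

* `fit_lmm()` refuses designs with fewer than two groups; the
  `fix_var_group = 0` escape hatch collapses to ordinary least squares
  (ML variance normalisation), which is also the oracle the tests compare
  against, alongside an independent mixed-model implementation (`nlme`).
* A perfectly noiseless response makes the Gaussian likelihood degenerate;
  the OLS path reports `logLik = Inf` in that case, and the generator's
  deterministic limits are exercised with tiny rather than exactly zero
  noise wherever a mixed model is actually fitted.
* Singular-fit checks are relaxed (`check.conv.singular = "ignore"`)
  because candidate sets legitimately include models whose group variance
  estimates at zero.
* AICc requires $n > p + 1$ and errors otherwise. Ranking refuses fits
  with differing $n$.
* Cascade ratios are undefined (and dropped, with accounting) when either
  pair member has zero or missing chlorophyll; unmatched power levels are
  skipped with a message.
* Validation splits problems into *structural* errors (unknown treatment
  codes, duplicate tank-weeks, missing required columns, empty file) that
  stop the run, and *row-level* violations (unparseable or negative
  values, weeks outside 2–9) that drop and log the row.

## 6. Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full default design (240
rows) throughout; the Monte-Carlo recovery study (`recovery_study()`) uses
100 replicates for bias, 95%-interval coverage, and generating-model
ranking, plus 100 more for the ranking check — sizes chosen so the whole
suite completes in well under a minute on one CPU while holding the
Monte-Carlo error on a coverage estimate near 1.5 percentage points.
Coverage of the Wald composite intervals is expected slightly below
nominal (≈0.92–0.93 with 10 tanks per treatment) because the normal
multiplier ignores the finite number of groups; the t-quantile option is
the remedy when that matters.

## 7. Known limitations

* The mixed models are random-intercept only — no random slopes, no
  temporal autocorrelation, Gaussian errors after transformation.
* Thermal performance curves (e.g. Sharpe–Schoolfield) are deliberately
  out of scope: the exponential Boltzmann model is the hypothesis under
  test, appropriate below thermal optima.
* The deposited observation file of the original experiment is not
  redistributed here; the refit machinery (`read_mesocosm()` with a
  column map, `run_model_set()`) is exercised on synthetic data written in
  a foreign dialect instead, so numeric agreement with the published
  coefficient table is not asserted by the tests.
* Ordination of community composition and body-size models are not
  implemented (out of scope).
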