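# mesotherm

Temperature dependence of community biomass and ecosystem metabolism in
heated mesocosms.

## The problem

Warming accelerates the metabolism of individual organisms, and summed over
a community those per-capita responses become ecosystem-scale oxygen
fluxes. But between the organism and the ecosystem sit population dynamics
and species interactions — grazing, predation, trophic cascades — that can
reshape standing biomass along a temperature gradient even when net fluxes
stay boringly Arrhenius. `mesotherm` is an analysis toolkit for the kind of
experiment that probes this: replicate enclosed aquatic ecosystems
(mesocosms) held at different temperatures by heaters of different power,
crossed with food-web treatments (algae only **A**, algae + grazers
**AG**, algae + grazers + predators **AGP**), sampled weekly for
chlorophyll *a*, dawn/dusk/dawn dissolved oxygen, and zooplankton counts.

It is written for community ecologists who want to go from raw diel oxygen
records and chlorophyll tables to activation-energy estimates and
model-selection tables, or to simulate such experiments with known truth.

## The model

Within the metabolic theory of ecology, a per-capita rate follows the
Boltzmann–Arrhenius form *b* = *b*₀ e^(−E/kT) *m*^α, with activation
energy *E* (eV), the Boltzmann constant *k* = 8.617×10⁻⁵ eV K⁻¹, and body
mass *m* scaling with exponent α. Aggregated over a community, an
ecosystem rate is

> *B_R* = *b*₀(*T_c*) · e^(−E (1/kT − 1/kT_c)) · *M_B* · ⟨*m*^(α−1)⟩,

where *M_B* is total biomass density and ⟨*m*^(α−1)⟩ = Σ*m*^α / Σ*m* is
the mass-corrected average accounting for the outsized metabolic
contribution of small individuals. A rate of this form is ln-linear in
inverse thermal energy 1/kT with slope −*E*.

The statistical core decomposes each ecosystem's weekly inverse
temperature into a **between-ecosystem** component (tank mean, centered on
the grand mean) and a **within-ecosystem** component (weekly deviations
from the tank mean), and fits nested sets of Gaussian random-intercept
mixed models (maximum likelihood) of the form

> ln *Y*(w,j) = β₀ + β₁·(1/kT(w,j) − 1/kT̄(j)) + β₂·(1/kT̄(j)) + β₃·(…×…)
> + β₄·Z(j) + β₅·Z(j)×(1/kT̄(j)) + β₆·Z(j)×(…) + u(j) + e(w,j)

for responses *Y* ∈ {chlorophyll *a*, NEP, ER}, trophic treatment *Z*, and
tank random intercepts *u*. Candidate models are ranked by small-sample
AICc and Akaike weights; coefficients are pooled into composite
treatment-specific slopes (β₂ + β₅Z), whose negation is the apparent
activation energy, with confidence intervals from the coefficient
covariance. Trophic-cascade strength is the log response ratio
ln(chla_AGP / chla_AG) of paired tanks at the same heater power.

NEP (net ecosystem production) and ER (ecosystem respiration) are
estimated from dawn→dusk and dusk→dawn oxygen changes, corrected for the
shift in equilibrium saturation between the bounding temperatures and
converted at *z* = 31.25 μmol O₂ per mg.

## Worked example

Simulate a default experiment (30 tanks = 10 power levels × 3 treatments,
weeks 2–9, 240 tank-weeks) and run the full analysis:

```r
library(mesotherm)

experiment <- generate_experiment(synthetic_config(seed = 42))
analysis   <- mesocosm_analysis(experiment$data)
analysis
#> Mesocosm analysis
#>   phyto_biomass  best PBF     (AICc 140.97, w 1.00) of 10 models
#>   nep            best NEP3    (AICc 55.76, w 0.58) of 10 models
#>   er             best ER3     (AICc 27.84, w 0.40) of 10 models
#>   cascade        best TCmF    (AICc 130.12, w 0.49) of 5 models
#>   zoop_total     best Z1b     (AICc 236.56, w 0.52) of 5 models
#>   daphnia        best D1c     (AICc 229.45, w 0.33) of 5 models
#>   copepod        best C1b     (AICc 236.83, w 0.42) of 5 models
#>   cascade temperature dependence (week 9): E_TC = 3.30 eV
#>   zoop_total     density temperature coefficient: 0.52 eV
#>   daphnia        density temperature coefficient: -0.12 eV
#>   copepod        density temperature coefficient: 0.73 eV
```

The chlorophyll model set: the full model wins decisively here because the
generator put real treatment × temperature structure into the data.

```r
analysis$comparisons$phyto_biomass
#> Model comparison (10 models, 240 obs in 30 groups)
#>  model df  logLik   AICc  delta weight
#>    PBF 12  -57.80 140.97   0.00      1
#>    PB4  6  -94.45 201.27  60.29      0
#>    PB7  9  -93.37 205.52  64.55      0
#>    ...
```

Pooled between-ecosystem activation energies of phytoplankton biomass per
treatment (negative: standing stock falls as temperature rises, most
steeply when grazers lack predators):

```r
subset(analysis$pooled, response == "phyto_biomass")
#>        response treatment   scope model    slope         E    ci_low   ci_high
#>  phyto_biomass         A between   PBF 1.024284 -1.024284 -1.466597 -0.581970
#>  phyto_biomass        AG between   PBF 5.776109 -5.776109 -6.218423 -5.333796
#>  phyto_biomass       AGP between   PBF 1.676150 -1.676150 -2.118463 -1.233836
```

`E` is minus the composite slope on 1/kT̄: a value of −5.8 eV for the AG
treatment means roughly a three-orders-of-magnitude decline in standing
stock over a 10 °C warming, versus about one order in the A and AGP
treatments — the signature of a temperature-strengthened trophic cascade,
here recovered from data generated with exactly that structure
(true slopes 1.30, 5.30, 1.60).

Flux estimation on its own:

```r
s <- diel_series(o2_dawn = 8, o2_dusk = 9, o2_dawn2 = 8.2,
                 temp_dawn = 20, temp_dusk = 25, temp_dawn2 = 19)
nep_from_diel(s)  # micromol O2 / L / h, saturation-corrected
er_from_diel(s)
```

A thin command-line wrapper lives at `inst/cli/mesotherm.R`
(`simulate` / `fluxes` / `analyze` subcommands over the same functions).

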