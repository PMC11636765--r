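# ehcsim

Mechanistic simulation of oral drug pharmacokinetics for compounds that
undergo **enterohepatic circulation (EHC)** — absorption into the systemic
circulation, first-order distribution into the gallbladder, meal-triggered
bolus emptying of bile (and drug) into the duodenum, and reabsorption. The
package is aimed at biopharmaceutics and PBPK modelers who want to ask: *when
the gallbladder empties into a fed-state intestine full of bile micelles, how
much of the recirculated drug is actually available for reabsorption, and
how much does that matter for the plasma profile?*

## The model

The gastrointestinal and disposition states are coupled ODEs integrated with
fixed-step 4th-order Runge–Kutta (Δt = 0.01 h):

- **Dissolution** (stomach and intestine, and the in-vitro vessel) follows a
  Noyes–Whitney z-factor law,
  `dW_diss/dt = z · W_undiss^(2/3) · (C_s − W_diss/V)`, with `z` fitted to
  in-vitro profiles in biorelevant media (`fit_z()`) and dose-scaled by
  `z_vivo = z_vitro · (D_vivo/D_vitro)^(1/3)` (`scale_z()`).
- **Gastric emptying** is first order at 2.8 h⁻¹ fasted (half-emptying
  ~15 min). After a meal it is biphasic: `7.21·(content − 500 mL)` within
  1.5 h (clamped at 0), then `0.452·content`; gastric juice is secreted at
  `540·(1 − exp(−(t − t_meal)^p))` mL/h. Each meal (at 4, 10, 24, 28, 34,
  48, 52, 58, 72 h) adds 584 mL of gastric fluid.
- **Absorption** is `dA/dt = P_eff·3600 · SA · (W/V) · f`, with SA = 800 cm²
  and `f` the **free fraction not entrapped in bile mixed micelles**,
  estimated from fed/fasted simulated-intestinal-fluid solubilities as
  `f = C⁻(FaSSIF-V2)/C⁺(FeSSIF-V2)`, clamped at 1. An unstirred-water-layer
  permeability `P_UWL = 10⁻³·(180/MW)^(1/3)` cm/s guards against UWL-limited
  permeation.
- **Disposition** is a central/peripheral model with first-order elimination
  and first-order distribution into a gallbladder compartment, which empties
  at 21 h⁻¹ during a 0.75 h window after each meal (a near-total bolus,
  fraction `1 − e^(−15.75)`), for meals up to a 72 h EHC cutoff.

Four structural variants are compared by MAPE against observed profiles at
the first post-meal sampling times (with predictions taken 0.1 h after a
meal when sampling and meal coincide):

| Variant | Gallbladder drug | Fed-state reabsorption |
|---|---|---|
| 1 | eliminated (no EHC) | — |
| 2 | emptied to central compartment | — |
| 3 | emptied to intestine | uncompensated (f = 1) |
| 4 | emptied to intestine | micelle-compensated (f < 1) |

Because observed human profiles and fitted disposition constants for the two
reference products are not redistributable inputs, the package ships a
seeded synthetic-data generator (`make_dissolution_profile()`,
`make_observed_pk()`) plus parameter fixtures (`product_fixture()`) whose
systemic constants are clearly flagged synthetic placeholders.

## Worked example

```r
library(ehcsim)

fx <- product_fixture("zetia")     # ezetimibe-like bundle
fx$drug
#> Drug parameters: ezetimibe
#>   MW 409.43 g/mol | logP 4.5 | pKa 9.7
#>   Solubility (mg/mL): FaSSGF 0.00106 | FaSSIF-V2 0.00379 | FeSSIF-V2 0.0223
#>   P_eff 0.000306 cm/s | P_UWL 0.00076 cm/s (UWL not limiting)
#>   Fed-state micelle free fraction f = 0.17

sim4 <- simulate_ehc(fx$drug, fx$formulation, physiology_parameters(),
                     fx$systemic, simulation_config(model_variant = 4, t_end = 80))
sim4
#> EHC oral PK simulation: ezetimibe, model variant 4
#>   dose 10 mg | dt 0.01 h | horizon 80 h | 8001 recorded points
#>   Cmax 6.643e-07 mg/mL at t = 4.00 h | max mass-balance error 1.6e-15
```

The free fraction 0.17 means ~83% of dissolved ezetimibe is entrapped in
micelles in the fed intestine and unavailable for permeation; Cmax lands at
the first meal (4 h), after which recirculation sustains the profile with
secondary peaks after later meals. Scoring variants 4 and 3 against a
synthetic "observed" profile generated with variant-4 truth and 10%
observation noise:

```r
scen <- synthetic_scenario("zetia", truth_variant = 4, noise_cv_pk = 0.1,
                           seed = 42, t_end = 80)
obs  <- make_observed_pk(scen)
meals <- physiology_parameters()$meal_times
mape(obs, sim4, reference_sampling_times("zetia"), meals)
#> MAPE = 6.2% over 6 sampling points
sim3 <- simulate_ehc(fx$drug, fx$formulation, physiology_parameters(),
                     fx$systemic, simulation_config(model_variant = 3, t_end = 80))
mape(obs, sim3, reference_sampling_times("zetia"), meals)
#> MAPE = 19.7% over 6 sampling points
```

Ignoring micelle entrapment (variant 3) roughly triples the error, with the
damage concentrated at the post-meal points (11, 24.1, 48.1, 72.1 h) where
uncompensated reabsorption overshoots.

A command-line interface over the same functions ships at
`system.file("exec", "ehcsim.R", package = "ehcsim")` with subcommands
`simulate`, `fit-z`, `mape` and `synth` (YAML configs, CSV profiles).

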