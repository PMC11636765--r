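# Shared test scenarios, built in code.

# A synthetic fast-dissolving, fully-absorbed drug: dissolution completes and
# the whole dose is absorbed before the first meal, so the gallbladder holds
# a large fraction of the dose at later meals. Used where the product
# fixtures (slow z-factor dissolution, ~1-2% absorbed) would leave a
# property's precondition vacuous.
fast_drug <- function(free_fraction_fed = NULL) {
  drug_parameters("synthetic-fast", molecular_weight = 300,
                  sol_fassgf = 0.05, sol_fassif_v2 = 0.05,
                  sol_fessif_v2 = 0.25, p_eff = 3e-4,
                  free_fraction_fed = free_fraction_fed)
}

fast_formulation <- function(dose = 10) {
  formulation_parameters(dose, z_gastric = 50, z_intestinal = 50)
}

fast_systemic <- function(k_to_gallbladder = 0.3) {
  systemic_parameters(1e4, k_elim = 0.05, k_central_peripheral = 0.2,
                      k_peripheral_central = 0.1,
                      k_to_gallbladder = k_to_gallbladder)
}

simulate_fast <- function(variant, t_end = 36, k_to_gallbladder = 0.3,
                          drug = fast_drug(), dt = 0.01) {
  simulate_ehc(drug, fast_formulation(), physiology_parameters(),
               fast_systemic(k_to_gallbladder),
               simulation_config(model_variant = variant, dt = dt,
                                 t_end = t_end))
}

simulate_fixture <- function(product, variant, t_end = 80, dt = 0.01) {
  fx <- product_fixture(product)
  simulate_ehc(fx$drug, fx$formulation, physiology_parameters(), fx$systemic,
               simulation_config(model_variant = variant, dt = dt,
                                 t_end = t_end))
}

# trapezoidal AUC of the recorded plasma curve
auc <- function(sim) {
  sum(diff(sim$times) * (head(sim$plasma, -1) + tail(sim$plasma, -1)) / 2)
}
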