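#' Simulate-ready parameter bundles for the two reference drug products
#'
#' Returns the full parameter set for a meloxicam product (`"mobic"`) or an
#' ezetimibe product (`"zetia"`). Physicochemical, solubility, permeability
#' and z-factor values are measured/estimated constants for these products:
#' molecular weight, biorelevant solubilities, effective permeability, UWL
#' permeability (derived from MW), micelle free fraction (derived from the
#' FeSSIF-V2/FaSSIF-V2 solubility ratio; the meloxicam ratio exceeds 1 and is
#' regarded as 1), and FaSSGF/FaSSIF-V2 dissolution rate constants from
#' in vitro tests of the 10 mg tablets. For the ezetimibe product the
#' intestinal C_s is the tablet dissolution-test value (0.00493 mg/mL, raised
#' by the sodium dodecyl sulfate excipient) rather than the drug-substance
#' solubility used for the free fraction.
#'
#' The systemic disposition parameters (V/F and the rate constants) are NOT
#' measured values: they are synthetic placeholders chosen once to produce
#' realistic biphasic profiles with visible post-meal secondary peaks, and
#' are flagged as such in the returned bundle. Replace them with estimates
#' from human data for any real prediction.
#'
#' @param product `"mobic"` or `"zetia"`.
#' @param dose_vivo dose administered in vivo (mg); the in vitro z constants
#'   (10 mg tablets) are dose-scaled with [scale_z()] when it differs.
#' @return list with `drug` ([drug_parameters()]), `formulation`
#'   ([formulation_parameters()]), `systemic` ([systemic_parameters()],
#'   synthetic placeholders), `dose_vitro`, and `systemic_is_synthetic = TRUE`.
#' @export
product_fixture <- function(product = c("mobic", "zetia"), dose_vivo = 10) {
  product <- match.arg(product)
  dose_vitro <- 10   # both in vitro dissolution tests used the 10 mg tablet
  if (product == "mobic") {
    drug <- drug_parameters(
      name = "meloxicam", molecular_weight = 351.40,
      log_p = 3.32, pka = c(1.09, 4.18),
      sol_fassgf = 0.00121, sol_fassif_v2 = 0.172, sol_fessif_v2 = 0.0427,
      p_eff = 3.79e-4)
    z_g <- z_constant(0.739, medium = "FaSSGF")
    z_i <- z_constant(0.0350, medium = "FaSSIF-V2")
    cs_intestinal <- 0.172
    # synthetic placeholders: long half-life, moderate recirculation
    systemic <- systemic_parameters(
      volume_of_distribution = 1e4, k_elim = 0.03,
      k_central_peripheral = 0.10, k_peripheral_central = 0.10,
      k_to_gallbladder = 0.05)
  } else {
    drug <- drug_parameters(
      name = "ezetimibe", molecular_weight = 409.43,
      log_p = 4.5, pka = 9.7,
      sol_fassgf = 0.00106, sol_fassif_v2 = 0.00379, sol_fessif_v2 = 0.0223,
      p_eff = 3.06e-4)
    z_g <- z_constant(4.75, medium = "FaSSGF")
    z_i <- z_constant(1.24, medium = "FaSSIF-V2")
    cs_intestinal <- 0.00493   # tablet dissolution-test value
    # synthetic placeholders: extensive recirculation, biphasic profile
    systemic <- systemic_parameters(
      volume_of_distribution = 1e5, k_elim = 0.05,
      k_central_peripheral = 0.20, k_peripheral_central = 0.10,
      k_to_gallbladder = 0.08)
  }
  if (dose_vivo != dose_vitro) {
    z_g <- scale_z(z_g, dose_vitro, dose_vivo)
    z_i <- scale_z(z_i, dose_vitro, dose_vivo)
  }
  list(product = product,
       drug = drug,
       formulation = formulation_parameters(
         dose_mg = dose_vivo, z_gastric = z_g, z_intestinal = z_i,
         cs_gastric = drug$sol_fassgf, cs_intestinal = cs_intestinal),
       systemic = systemic,
       dose_vitro = dose_vitro,
       systemic_is_synthetic = TRUE)
}
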