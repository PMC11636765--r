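#' Free fraction of drug not entrapped in bile mixed micelles
#'
#' The fed-state small intestine is rich in bile salts; above the critical
#' micelle concentration drug can be entrapped in mixed micelles and only the
#' free (non-entrapped) fraction is available for membrane permeation. The
#' free fraction is estimated from saturated solubilities in fed- and
#' fasted-state simulated intestinal fluids as
#' \eqn{f = 1 - (C^+ - C^-)/C^+ = C^-/C^+}, where \eqn{C^+} and \eqn{C^-} are
#' the solubilities in FeSSIF-V2 and FaSSIF-V2 respectively.
#'
#' When the fasted-state solubility exceeds the fed-state solubility (as for
#' ionizable acids whose solubility drops at the lower FeSSIF-V2 pH), the raw
#' ratio exceeds 1 and is clamped to 1: micellar entrapment is then
#' insignificant and all dissolved drug is treated as free.
#'
#' @param sol_fed saturated solubility in FeSSIF-V2 (mg/mL), \eqn{C^+}.
#' @param sol_fasted saturated solubility in FaSSIF-V2 (mg/mL), \eqn{C^-}.
#' @return free fraction in (0, 1].
#' @examples
#' compute_free_fraction(0.0223, 0.00379) # ezetimibe-like, ~0.17
#' compute_free_fraction(0.0427, 0.172)   # meloxicam-like, clamps to 1
#' @export
compute_free_fraction <- function(sol_fed, sol_fasted) {
  stopifnot(is.numeric(sol_fed), is.numeric(sol_fasted))
  if (any(sol_fed <= 0) || any(sol_fasted <= 0)) {
    stop("solubilities must be positive (got sol_fed = ", sol_fed,
         ", sol_fasted = ", sol_fasted, ")", call. = FALSE)
  }
  pmin(1, sol_fasted / sol_fed)
}

#' Unstirred-water-layer permeability from molecular weight
#'
#' Permeation of the unstirred water layer (UWL) on the intestinal brush
#' border can limit overall membrane permeation. Its rate constant is
#' estimated from molecular weight as
#' \eqn{P_{UWL} = 10 \times 10^{-4} (180 / MW)^{1/3}} cm/s.
#'
#' @param molecular_weight molecular weight in g/mol.
#' @return UWL permeability in cm/s.
#' @examples
#' compute_p_uwl(351.40) # 8.00e-4 cm/s
#' compute_p_uwl(409.43) # 7.60e-4 cm/s
#' @export
compute_p_uwl <- function(molecular_weight) {
  stopifnot(is.numeric(molecular_weight))
  if (any(molecular_weight <= 0)) {
    stop("molecular_weight must be positive", call. = FALSE)
  }
  10 * 1e-4 * (180 / molecular_weight)^(1 / 3)
}

#' Decide whether the unstirred water layer limits permeation
#'
#' Compares the effective intestinal permeability with the UWL permeability
#' and returns the smaller of the two as the rate used in the absorption
#' flux, plus a flag indicating whether the UWL is rate limiting
#' (`p_uwl < p_eff`). A tie is resolved as not limiting.
#'
#' @param p_eff effective human intestinal permeability (cm/s).
#' @param p_uwl unstirred-water-layer permeability (cm/s), e.g. from
#'   [compute_p_uwl()].
#' @return list with `uwl_limiting` (logical) and `effective_rate` (cm/s).
#' @export
check_uwl_limitation <- function(p_eff, p_uwl) {
  stopifnot(is.numeric(p_eff), is.numeric(p_uwl), length(p_eff) == 1L,
            length(p_uwl) == 1L)
  if (p_eff <= 0 || p_uwl <= 0) stop("permeabilities must be positive", call. = FALSE)
  list(uwl_limiting = p_uwl < p_eff, effective_rate = min(p_eff, p_uwl))
}

#' Drug physicochemical and permeability parameter set
#'
#' Bundles the constants the simulator needs for one drug: molecular weight,
#' biorelevant solubilities, effective permeability, and the derived UWL
#' permeability and fed-state micelle free fraction. Solubilities are carried
#' at full precision; rounding happens only in display.
#'
#' @param name drug name.
#' @param molecular_weight g/mol.
#' @param sol_fassgf saturated solubility in FaSSGF (mg/mL), gastric \eqn{C_s}.
#' @param sol_fassif_v2 saturated solubility in FaSSIF-V2 (mg/mL), \eqn{C^-}
#'   and the fasted intestinal \eqn{C_s} default.
#' @param sol_fessif_v2 saturated solubility in FeSSIF-V2 (mg/mL), \eqn{C^+}.
#' @param p_eff effective human intestinal permeability (cm/s).
#' @param log_p,pka optional metadata (unitless).
#' @param free_fraction_fed optional override of the fed-state free fraction;
#'   computed from the FeSSIF-V2/FaSSIF-V2 solubilities when `NULL`.
#' @return object of class `drug_parameters`.
#' @examples
#' drug_parameters("ezetimibe", 409.43,
#'   sol_fassgf = 0.00106, sol_fassif_v2 = 0.00379, sol_fessif_v2 = 0.0223,
#'   p_eff = 3.06e-4)
#' @export
drug_parameters <- function(name, molecular_weight, sol_fassgf,
                            sol_fassif_v2, sol_fessif_v2, p_eff,
                            log_p = NA_real_, pka = NA_real_,
                            free_fraction_fed = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  for (nm in c("molecular_weight", "sol_fassgf", "sol_fassif_v2",
               "sol_fessif_v2", "p_eff")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  f <- if (is.null(free_fraction_fed)) {
    compute_free_fraction(sol_fessif_v2, sol_fassif_v2)
  } else {
    stopifnot(is.numeric(free_fraction_fed), free_fraction_fed > 0,
              free_fraction_fed <= 1)
    free_fraction_fed
  }
  structure(
    list(name = name,
         molecular_weight = molecular_weight,
         log_p = log_p, pka = pka,
         sol_fassgf = sol_fassgf,
         sol_fassif_v2 = sol_fassif_v2,
         sol_fessif_v2 = sol_fessif_v2,
         p_eff = p_eff,
         p_uwl = compute_p_uwl(molecular_weight),
         free_fraction_fed = f),
    class = "drug_parameters")
}

#' @export
print.drug_parameters <- function(x, ...) {
  cat("Drug parameters:", x$name, "\n")
  cat(sprintf("  MW %.2f g/mol | logP %s | pKa %s\n", x$molecular_weight,
              format(x$log_p), paste(format(x$pka), collapse = ", ")))
  cat(sprintf("  Solubility (mg/mL): FaSSGF %.4g | FaSSIF-V2 %.4g | FeSSIF-V2 %.4g\n",
              x$sol_fassgf, x$sol_fassif_v2, x$sol_fessif_v2))
  cat(sprintf("  P_eff %.3g cm/s | P_UWL %.3g cm/s (%s)\n", x$p_eff, x$p_uwl,
              if (x$p_uwl < x$p_eff) "UWL limiting" else "UWL not limiting"))
  cat(sprintf("  Fed-state micelle free fraction f = %.3g\n",
              x$free_fraction_fed))
  invisible(x)
}
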