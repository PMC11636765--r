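#' Generate a noisy in vitro dissolution profile
#'
#' Forward-integrates the z-factor dissolution equation (see
#' [simulate_dissolution()]) and adds independent additive Gaussian
#' measurement noise, truncated at 0 (and capped at 105% of dose so the
#' profile container's noisy-overshoot allowance holds). Deterministic given
#' `seed`.
#'
#' @param z dissolution rate constant (mL mg^-2/3 / h).
#' @param solubility \eqn{C_s} (mg/mL).
#' @param dose,volume vessel dose (mg) and volume (mL).
#' @param times sampling times (h).
#' @param noise_sd additive noise standard deviation (mg); 0 gives the exact
#'   forward solution.
#' @param seed RNG seed.
#' @return a [dissolution_profile()], flagged noisy when `noise_sd > 0`.
#' @export
make_dissolution_profile <- function(z, solubility, dose, volume, times,
                                     noise_sd = 0, seed = 1L) {
  stopifnot(noise_sd >= 0)
  clean <- simulate_dissolution(z, solubility, dose, volume, times)
  if (noise_sd == 0) return(clean)
  set.seed(seed)
  obs <- clean$dissolved_mg + stats::rnorm(length(times), sd = noise_sd)
  obs <- pmin(pmax(obs, 0), 1.05 * dose)
  dissolution_profile(times, obs, dose = dose, volume = volume,
                      medium = clean$medium, noisy = TRUE)
}

#' Synthetic study scenario
#'
#' Bundles a product fixture with a ground-truth model variant and noise
#' levels, so that "observed" data with known truth can be generated for any
#' stage of the pipeline.
#'
#' @param product `"mobic"` or `"zetia"` (see [product_fixture()]).
#' @param truth_variant model variant (1-4) used as ground truth.
#' @param noise_cv_pk coefficient of variation of the multiplicative
#'   lognormal PK observation noise.
#' @param noise_sd_dissolution additive dissolution noise sd (mg).
#' @param seed RNG seed recorded in all outputs.
#' @param dose_vivo in vivo dose (mg).
#' @param t_end simulation horizon (h).
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(product = c("mobic", "zetia"),
                               truth_variant = 4, noise_cv_pk = 0.1,
                               noise_sd_dissolution = 0.2, seed = 1L,
                               dose_vivo = 10, t_end = 96) {
  product <- match.arg(product)
  stopifnot(truth_variant %in% 1:4, noise_cv_pk >= 0,
            noise_sd_dissolution >= 0)
  fx <- product_fixture(product, dose_vivo = dose_vivo)
  structure(list(product = product, fixture = fx,
                 truth_variant = as.integer(truth_variant),
                 noise_cv_pk = noise_cv_pk,
                 noise_sd_dissolution = noise_sd_dissolution,
                 seed = as.integer(seed), t_end = t_end),
            class = "synthetic_scenario")
}

#' Generate a synthetic "observed" plasma profile with known ground truth
#'
#' Runs the full simulator under the scenario's truth variant, samples the
#' plasma concentration at the requested times, and applies multiplicative
#' lognormal observation noise with the scenario's CV (mean-preserving:
#' log-mean `-sigma^2/2`). Deterministic given the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @param sampling_times sampling times (h); defaults to the product's
#'   post-meal reference times ([reference_sampling_times()]).
#' @param truth_sim optional precomputed [simulate_ehc()] result for the
#'   truth variant (avoids re-simulating when generating many noise
#'   replicates).
#' @return a [concentration_time_profile()] of kind `"observed"`, with the
#'   scenario seed and the truth simulation attached as attributes `seed`
#'   and `truth`.
#' @export
make_observed_pk <- function(scenario, sampling_times = NULL,
                             truth_sim = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(sampling_times)) {
    sampling_times <- reference_sampling_times(scenario$product)
  }
  fx <- scenario$fixture
  if (is.null(truth_sim)) {
    truth_sim <- simulate_ehc(
      fx$drug, fx$formulation, physiology_parameters(), fx$systemic,
      simulation_config(model_variant = scenario$truth_variant,
                        t_end = scenario$t_end))
  }
  conc <- plasma_concentration(truth_sim, sampling_times)
  if (scenario$noise_cv_pk > 0) {
    set.seed(scenario$seed)
    sigma <- sqrt(log(1 + scenario$noise_cv_pk^2))
    conc <- conc * stats::rlnorm(length(conc), meanlog = -sigma^2 / 2,
                                 sdlog = sigma)
  }
  out <- concentration_time_profile(
    sampling_times, conc,
    label = sprintf("%s synthetic truth=model %d seed=%d", scenario$product,
                    scenario$truth_variant, scenario$seed),
    kind = "observed")
  attr(out, "seed") <- scenario$seed
  attr(out, "truth") <- truth_sim
  out
}
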