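#' Gastrointestinal physiology parameters
#'
#' Constants describing gastric and intestinal fluid dynamics and the meal
#' schedule. Defaults are the fed/fasted human values used throughout this
#' package: first-order fasted gastric emptying at 2.8 /h (half-emptying time
#' ~15 min); biphasic fed emptying (7.21 /h acting on content above a 500 mL
#' floor within 1.5 h of a meal, then 0.452 /h); gastric juice secretion
#' 540 (1 - exp(-(t - t_diet)^p)) mL/h with p = -0.8641; 50 mL resting
#' gastric fluid plus 150 mL co-administered water; 584 mL of gastric fluid
#' added at each meal; meals at 4, 10, 24, 28, 34, 48, 52, 58 and 72 h; 100 mL
#' initial intestinal fluid; 800 cm2 absorptive surface area; the undissolved
#' formulation resides in the small intestine for 4 h.
#'
#' `intestinal_fluid_transit` is the first-order constant of intestinal fluid
#' outflow acting on the excess above `initial_intestinal_volume`, so the
#' intestinal volume relaxes back to its 100 mL baseline between meals.
#'
#' @param k_ge_fasted fasted gastric emptying constant (/h).
#' @param fed_fast_coeff,fed_floor early fed-phase emptying coefficient (/h)
#'   and content floor (mL).
#' @param fed_slow_coeff late fed-phase emptying coefficient (/h).
#' @param fed_regime_switch time after a meal at which fed emptying switches
#'   from the early to the late phase (h).
#' @param secretion_scale gastric juice secretion scale (mL/h).
#' @param secretion_exponent exponent of the secretion time course (unitless,
#'   negative: secretion is highest immediately post-meal and declines).
#' @param resting_gastric_volume,coadministered_water initial gastric fluid
#'   components (mL).
#' @param meal_fluid gastric fluid added per meal (mL).
#' @param meal_times meal schedule (h after dosing), strictly increasing.
#' @param initial_intestinal_volume baseline intestinal fluid volume (mL).
#' @param intestinal_fluid_transit first-order intestinal fluid outflow
#'   constant (/h) acting on volume above baseline.
#' @param intestinal_surface_area absorptive surface area (cm2).
#' @param formulation_residence residence time of undissolved formulation in
#'   the small intestine (h).
#' @return object of class `physiology_parameters`.
#' @export
physiology_parameters <- function(k_ge_fasted = 2.8,
                                  fed_fast_coeff = 7.21,
                                  fed_floor = 500,
                                  fed_slow_coeff = 0.452,
                                  fed_regime_switch = 1.5,
                                  secretion_scale = 540,
                                  secretion_exponent = -2.206 / 2.553,
                                  resting_gastric_volume = 50,
                                  coadministered_water = 150,
                                  meal_fluid = 584,
                                  meal_times = c(4, 10, 24, 28, 34, 48, 52, 58, 72),
                                  initial_intestinal_volume = 100,
                                  intestinal_fluid_transit = 2.0,
                                  intestinal_surface_area = 800,
                                  formulation_residence = 4) {
  pos <- c(k_ge_fasted = k_ge_fasted, fed_fast_coeff = fed_fast_coeff,
           fed_floor = fed_floor, fed_slow_coeff = fed_slow_coeff,
           fed_regime_switch = fed_regime_switch,
           secretion_scale = secretion_scale,
           resting_gastric_volume = resting_gastric_volume,
           coadministered_water = coadministered_water,
           meal_fluid = meal_fluid,
           initial_intestinal_volume = initial_intestinal_volume,
           intestinal_fluid_transit = intestinal_fluid_transit,
           intestinal_surface_area = intestinal_surface_area,
           formulation_residence = formulation_residence)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) stop("physiology parameters must be positive: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  meal_times <- sort(unique(as.numeric(meal_times)))
  if (any(meal_times <= 0)) stop("meal_times must be positive", call. = FALSE)
  structure(c(as.list(pos),
              list(secretion_exponent = secretion_exponent,
                   meal_times = meal_times)),
            class = "physiology_parameters")
}

#' @export
print.physiology_parameters <- function(x, ...) {
  cat("GI physiology parameters\n")
  cat(sprintf("  fasted emptying %.3g /h (t1/2 %.1f min); fed: %.3g/(content-%g mL) <%g h, then %.3g /h\n",
              x$k_ge_fasted, 60 * log(2) / x$k_ge_fasted, x$fed_fast_coeff,
              x$fed_floor, x$fed_regime_switch, x$fed_slow_coeff))
  cat(sprintf("  secretion %g mL/h scale, exponent %.4f\n",
              x$secretion_scale, x$secretion_exponent))
  cat(sprintf("  meals at %s h (+%g mL each)\n",
              paste(x$meal_times, collapse = ", "), x$meal_fluid))
  invisible(x)
}

#' Fasted-state gastric emptying rate
#'
#' First-order outflow, applying identically to drug amount and fluid volume:
#' rate = k * content with the default k = 2.8 /h (half-emptying time
#' ln(2)/2.8 h, about 15 min).
#'
#' @param x_stomach gastric content (mg of drug or mL of fluid).
#' @param k_ge_fasted emptying constant (/h).
#' @return outflow rate (content units per hour).
#' @export
gastric_emptying_rate_fasted <- function(x_stomach, k_ge_fasted = 2.8) {
  if (any(x_stomach < 0)) stop("gastric content must be non-negative", call. = FALSE)
  k_ge_fasted * x_stomach
}

#' Fed-state gastric emptying rate
#'
#' Within `fed_regime_switch` hours of the last meal the emptying rate is
#' `fed_fast_coeff * (content - fed_floor)`, clamped at 0 when content is at
#' or below the floor (a stomach cannot fill by emptying); afterwards it is
#' first order, `fed_slow_coeff * content`.
#'
#' @param x_content gastric content (mL-equivalents).
#' @param time_since_meal hours since the last meal.
#' @param params a [physiology_parameters()] object.
#' @return outflow rate (content units per hour), never negative.
#' @export
gastric_emptying_rate_fed <- function(x_content, time_since_meal,
                                      params = physiology_parameters()) {
  if (any(x_content < 0)) stop("gastric content must be non-negative", call. = FALSE)
  if (any(time_since_meal < 0)) stop("time_since_meal must be non-negative", call. = FALSE)
  ifelse(time_since_meal < params$fed_regime_switch,
         pmax(0, params$fed_fast_coeff * (x_content - params$fed_floor)),
         params$fed_slow_coeff * x_content)
}

#' Gastric juice secretion rate after a meal
#'
#' Secretion declines from its post-prandial maximum as
#' `scale * (1 - exp(-(t - t_diet)^p))` with a negative exponent `p`; the
#' t -> 0+ limit is `scale` (540 mL/h by default) and that limit is returned
#' for non-positive elapsed times.
#'
#' @param time_since_meal hours since the last meal.
#' @param params a [physiology_parameters()] object.
#' @return secretion rate (mL/h) in `[0, secretion_scale]`.
#' @export
gastric_secretion_rate <- function(time_since_meal,
                                   params = physiology_parameters()) {
  s <- params$secretion_scale
  p <- params$secretion_exponent
  out <- numeric(length(time_since_meal))
  zero <- time_since_meal <= 0
  out[zero] <- if (p < 0) s else 0   # limit of the expression as t -> 0+
  out[!zero] <- s * (1 - exp(-(time_since_meal[!zero])^p))
  out
}

#' Apply a meal event to a simulation state
#'
#' Meals are instantaneous state jumps: `meal_fluid` (584 mL by default) is
#' added to the stomach fluid, the prandial regime switches to fed, the time
#' of the last meal is updated, and (in the simulator) the gallbladder
#' emptying window opens. Drug amounts are unchanged by the event itself.
#'
#' @param state an [ehc_state()] object.
#' @param params a [physiology_parameters()] object.
#' @return the updated state.
#' @export
apply_meal_event <- function(state, params = physiology_parameters()) {
  stopifnot(inherits(state, "ehc_state"))
  state$stomach_fluid <- state$stomach_fluid + params$meal_fluid
  state$prandial_state <- "fed"
  state$t_last_meal <- state$clock
  state
}
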