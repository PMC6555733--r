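# Brockway (1987) indirect calorimetry constants, kJ per litre of gas.  The
# urinary-nitrogen (protein) term is neglected: it is not measurable from gas
# exchange alone and its contribution during steady-state walking is ~1%.
BROCKWAY_O2_KJ_PER_L  <- 16.58
BROCKWAY_CO2_KJ_PER_L <- 4.51

#' Metabolic power from breath gas exchange (Brockway equation)
#'
#' Converts oxygen consumption and carbon dioxide production rates into
#' metabolic power: `W = (16.58 * vo2 + 4.51 * vco2) * 1000 / 60` with rates
#' in L/min.  Vectorized; linear and monotone increasing in both arguments.
#'
#' @param vo2 Oxygen uptake, L/min (>= 0).
#' @param vco2 Carbon dioxide production, L/min (>= 0).
#' @return Metabolic power in Watts.
#' @examples
#' brockway_power(1.0, 0.8)   # 336.5 W
#' @export
brockway_power <- function(vo2, vco2) {
  if (any(vo2 < 0) || any(vco2 < 0))
    abort("vo2 and vco2 must be non-negative (L/min)")
  (BROCKWAY_O2_KJ_PER_L * vo2 + BROCKWAY_CO2_KJ_PER_L * vco2) * 1000 / 60
}

#' Invert the Brockway equation at a fixed respiratory exchange ratio
#'
#' Given a target metabolic power and an RER (`vco2/vo2`), returns the unique
#' gas-exchange rates that reproduce it: `vo2 = 60 P / (1000 (16.58 + 4.51
#' rer))`, `vco2 = rer * vo2`.  `brockway_power()` of the result equals the
#' target to machine precision.
#'
#' @param target_power Metabolic power, W (>= 0).
#' @param rer Respiratory exchange ratio in `[0.7, 1.1]`.
#' @return A list with elements `vo2` and `vco2` (L/min).
#' @export
invert_brockway <- function(target_power, rer = 0.85) {
  if (any(target_power < 0)) abort("target_power must be >= 0")
  if (any(rer < 0.7) || any(rer > 1.1))
    abort("rer must lie in [0.7, 1.1]")
  vo2 <- 60 * target_power /
    (1000 * (BROCKWAY_O2_KJ_PER_L + BROCKWAY_CO2_KJ_PER_L * rer))
  list(vo2 = vo2, vco2 = rer * vo2)
}

#' Steady-state energy expenditure of a trial
#'
#' The per-condition ground truth: the unweighted mean of per-breath Brockway
#' power over all breaths in the final `window_s` seconds of the breath record
#' (breaths with `time > max(time) - window_s`).
#'
#' @param breaths Tibble with columns `time` (s), `vo2`, `vco2` (L/min).
#' @param window_s Averaging window, s (default 120 — the last two minutes).
#' @return Steady-state metabolic power, W.
#' @export
steady_state_ee <- function(breaths, window_s = 120) {
  if (nrow(breaths) == 0L) abort("No breaths recorded")
  t_end <- max(breaths$time)
  keep <- breaths$time > t_end - window_s
  if (!any(keep)) abort("No breaths within the final averaging window")
  mean(brockway_power(breaths$vo2[keep], breaths$vco2[keep]))
}

#' Steady-state energy expenditure label per condition
#'
#' Applies [steady_state_ee()] to every trial and returns the condition-level
#' ground-truth table used to label feature vectors.
#'
#' @param trials List of trials.
#' @param window_s Averaging window, s.
#' @return Tibble: `subject_id`, `condition_id`, `mass`, `power_w`.
#' @export
condition_labels <- function(trials, window_s = 120) {
  purrr::map_dfr(trials, function(t) tibble(
    subject_id = t$subject$subject_id,
    condition_id = t$condition$condition_id,
    mass = t$subject$mass,
    power_w = steady_state_ee(t$breaths, window_s = window_s)
  ))
}
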