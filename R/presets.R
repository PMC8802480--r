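## Scenario presets reproducing the canonical patient-ventilator
## interaction phenotypes: synchronous assistance, obstructive
## mechanics with late cycling and ineffective efforts, restrictive
## mechanics with early cycling, cardiogenic auto-triggering, and
## dynamic hyperinflation with ineffective efforts.

#' Scenario presets
#'
#' Deterministic scenarios emulating the mechanics phenotypes seen
#' under pressure support ventilation:
#' \describe{
#'   \item{synchronous}{normal mechanics (tau = 0.5 s), effort and
#'     ventilator well matched.}
#'   \item{obstructive}{tau about 0.9 s, low cycling threshold and
#'     short expirations: late cycling and ineffective efforts from
#'     dynamic hyperinflation.}
#'   \item{restrictive}{tau about 0.3 s, long efforts with a high
#'     cycling threshold: early cycling.}
#'   \item{autotrigger}{no (or negligible) efforts, large cardiac
#'     oscillations coupled to the circuit and a sensitive trigger:
#'     auto-triggered breaths.}
#'   \item{ineffective}{obstructive mechanics with weak efforts at a
#'     high rate: frequent ineffective efforts.}
#' }
#'
#' @param name preset name.
#' @param seed integer seed (fixes all randomness of the scenario).
#' @param duration_s recording length (s).
#' @return A [sim_scenario].
#' @export
scenario_preset <- function(name = c("synchronous", "obstructive",
                                     "restrictive", "autotrigger",
                                     "ineffective"),
                            seed = 1, duration_s = 30) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort_argument(
                     sprintf("unknown preset: %s", name[1L])))
  switch(name,
    synchronous = sim_scenario(
      mechanics = mechanics(resistance_R = 10, compliance_C = 0.05,
                            chest_wall_elastance_Ecw = 5),
      efforts = list(rate_per_min = 20, peak_pmus = 10, rise_time_s = 0.7,
                     relax_tau_s = 0.1, jitter_s = 0.05, start_s = 1.6),
      vent = vent_settings(peep = 5, pressure_support = 10,
                           flow_trigger = 0.03,
                           expiratory_trigger_fraction = 0.25,
                           max_ti_s = 1.5),
      duration_s = duration_s, seed = seed),
    obstructive = sim_scenario(
      mechanics = mechanics(resistance_R = 18, compliance_C = 0.05,
                            chest_wall_elastance_Ecw = 5),
      efforts = list(rate_per_min = 25, peak_pmus = 9, rise_time_s = 0.5,
                     relax_tau_s = 0.08, jitter_s = 0.04, start_s = 1.6,
                     peak_pattern = c(1, 1, 0.45)),
      vent = vent_settings(peep = 5, pressure_support = 12,
                           flow_trigger = 0.05,
                           expiratory_trigger_fraction = 0.05,
                           max_ti_s = 1.4),
      duration_s = duration_s, seed = seed),
    restrictive = sim_scenario(
      mechanics = mechanics(resistance_R = 8, compliance_C = 0.04,
                            chest_wall_elastance_Ecw = 6),
      efforts = list(rate_per_min = 18, peak_pmus = 10, rise_time_s = 1.3,
                     relax_tau_s = 0.12, jitter_s = 0.05, start_s = 1.6),
      vent = vent_settings(peep = 5, pressure_support = 12,
                           flow_trigger = 0.03,
                           expiratory_trigger_fraction = 0.5,
                           max_ti_s = 1.5),
      duration_s = duration_s, seed = seed),
    autotrigger = sim_scenario(
      mechanics = mechanics(resistance_R = 10, compliance_C = 0.05,
                            chest_wall_elastance_Ecw = 5),
      efforts = list(rate_per_min = 6, peak_pmus = 0, rise_time_s = 0.7,
                     relax_tau_s = 0.1, jitter_s = 0, start_s = 2),
      vent = vent_settings(peep = 5, pressure_support = 8,
                           flow_trigger = 0.015,
                           expiratory_trigger_fraction = 0.25,
                           max_ti_s = 1.2,
                           autotrigger_sensitivity = TRUE),
      cardiac_noise_amp = 1.5,
      duration_s = duration_s, seed = seed),
    ineffective = sim_scenario(
      mechanics = mechanics(resistance_R = 20, compliance_C = 0.05,
                            chest_wall_elastance_Ecw = 5),
      efforts = list(rate_per_min = 28, peak_pmus = 5, rise_time_s = 0.5,
                     relax_tau_s = 0.08, jitter_s = 0.04, start_s = 1.6),
      vent = vent_settings(peep = 5, pressure_support = 12,
                           flow_trigger = 0.06,
                           expiratory_trigger_fraction = 0.05,
                           max_ti_s = 1.6),
      duration_s = duration_s, seed = seed))
}
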