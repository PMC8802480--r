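## simulator: synthetic pressure-support-ventilation recordings with
## ground-truth effort and machine timings.
##
## The patient is a single-compartment model obeying the equation of
## motion of the respiratory system
##
##     Paw(t) + Pmus(t) = R * flow(t) + V(t)/C + PEEPtot
##
## with V the volume above the relaxation volume at PEEP. The
## ventilator is a flow-triggered, pressure-targeted state machine with
## first-order pressurization and flow cycling, which is the standard
## PSV behaviour that trigger delay, early/late cycling, ineffective
## efforts and auto-triggering presuppose. Integration runs on a fine
## internal grid (default 1000 Hz, explicit Euler) and is decimated to
## the output rate, so the recorded samples satisfy the defining
## equation to machine precision.

#' Respiratory mechanics of the simulated patient
#'
#' @param resistance_R airway resistance (cmH2O s/L).
#' @param compliance_C respiratory-system compliance (L/cmH2O).
#' @param chest_wall_elastance_Ecw chest-wall elastance (cmH2O/L),
#'   used only to shape the esophageal pressure channel.
#' @param peep_total resting alveolar pressure baseline (cmH2O);
#'   defaults to the ventilator PEEP. Intrinsic PEEP is not a
#'   parameter: it emerges dynamically when expiration is truncated.
#' @return A list of class `vw_mechanics`. The expiratory time constant
#'   of the model is `resistance_R * compliance_C` seconds.
#' @export
mechanics <- function(resistance_R = 10, compliance_C = 0.05,
                      chest_wall_elastance_Ecw = 5, peep_total = NULL) {
  stopifnot_scalar(resistance_R, "resistance_R", positive = TRUE)
  stopifnot_scalar(compliance_C, "compliance_C", positive = TRUE)
  stopifnot_scalar(chest_wall_elastance_Ecw, "chest_wall_elastance_Ecw")
  if (chest_wall_elastance_Ecw < 0)
    abort_argument("chest_wall_elastance_Ecw must be >= 0")
  structure(list(resistance_R = resistance_R, compliance_C = compliance_C,
                 chest_wall_elastance_Ecw = chest_wall_elastance_Ecw,
                 peep_total = peep_total),
            class = "vw_mechanics")
}

#' One patient inspiratory effort
#'
#' Muscle pressure rises smoothly (raised-cosine) from zero to
#' `peak_pmus` over `rise_time_s`, then relaxes exponentially with time
#' constant `relax_tau_s`. The ground-truth effort end is the
#' mid-relaxation time, `onset_s + rise_time_s + relax_tau_s * log(2)`,
#' mirroring the physiological convention that flow reversal in
#' unassisted breathing occurs at about half relaxation of the
#' inspiratory muscles.
#'
#' @param onset_s effort onset (s from recording start).
#' @param rise_time_s duration of the rise to peak (s).
#' @param peak_pmus peak muscle pressure (cmH2O, >= 0); applied as a
#'   negative pleural swing.
#' @param relax_tau_s exponential relaxation time constant (s).
#' @return A list of class `vw_effort`.
#' @export
effort_profile <- function(onset_s, rise_time_s = 0.7, peak_pmus = 10,
                           relax_tau_s = 0.1) {
  stopifnot_scalar(onset_s, "onset_s")
  stopifnot_scalar(rise_time_s, "rise_time_s", positive = TRUE)
  stopifnot_scalar(relax_tau_s, "relax_tau_s", positive = TRUE)
  stopifnot_scalar(peak_pmus, "peak_pmus")
  if (peak_pmus < 0) abort_argument("peak_pmus must be >= 0")
  structure(list(onset_s = onset_s, rise_time_s = rise_time_s,
                 peak_pmus = peak_pmus, relax_tau_s = relax_tau_s),
            class = "vw_effort")
}

#' Ventilator settings for the PSV state machine
#'
#' @param peep set external PEEP (cmH2O).
#' @param pressure_support inspiratory pressure above PEEP (cmH2O).
#' @param flow_trigger inspiratory flow threshold (L/s) that triggers a
#'   breath during the expiratory phase.
#' @param pressurization_rise_s first-order time constant of the rise
#'   to the inspiratory pressure target (s).
#' @param expiratory_trigger_fraction fraction of the peak inspiratory
#'   flow at which the ventilator cycles to expiration, in (0, 1).
#' @param max_ti_s maximum machine inspiratory time (s).
#' @param forced_trigger_delay_s extra delay imposed between trigger
#'   detection and the start of pressurization (s, >= 0).
#' @param autotrigger_sensitivity if `TRUE`, the cardiac disturbance is
#'   coupled into the pneumatic dynamics so that cardiogenic flow
#'   oscillations can reach the trigger.
#' @param min_insp_s,min_exp_s refractory times of the state machine (s).
#' @param release_tau_s first-order time constant of depressurization (s).
#' @param demand_resistance extra series resistance (cmH2O s/L) seen by
#'   inspiratory-direction flow during the expiratory phase; produces
#'   the small Paw dip that precedes triggering on real circuits.
#' @return A list of class `vw_vent`.
#' @export
vent_settings <- function(peep = 5, pressure_support = 10,
                          flow_trigger = 0.03, pressurization_rise_s = 0.1,
                          expiratory_trigger_fraction = 0.25, max_ti_s = 1.5,
                          forced_trigger_delay_s = 0,
                          autotrigger_sensitivity = FALSE,
                          min_insp_s = 0.15, min_exp_s = 0.3,
                          release_tau_s = 0.05, demand_resistance = 2) {
  if (pressure_support < 0) abort_argument("pressure_support must be >= 0")
  if (!(expiratory_trigger_fraction > 0 && expiratory_trigger_fraction < 1))
    abort_argument("expiratory_trigger_fraction must lie in (0, 1)")
  if (forced_trigger_delay_s < 0)
    abort_argument("forced_trigger_delay_s must be >= 0")
  structure(list(peep = peep, pressure_support = pressure_support,
                 flow_trigger = flow_trigger,
                 pressurization_rise_s = pressurization_rise_s,
                 expiratory_trigger_fraction = expiratory_trigger_fraction,
                 max_ti_s = max_ti_s,
                 forced_trigger_delay_s = forced_trigger_delay_s,
                 autotrigger_sensitivity = isTRUE(autotrigger_sensitivity),
                 min_insp_s = min_insp_s, min_exp_s = min_exp_s,
                 release_tau_s = release_tau_s,
                 demand_resistance = demand_resistance),
            class = "vw_vent")
}

#' Simulation scenario
#'
#' @param mechanics a [mechanics] object.
#' @param efforts either a list of [effort_profile]s or a list with
#'   fields `rate_per_min`, `peak_pmus`, `rise_time_s`, `relax_tau_s`,
#'   `jitter_s`, `start_s` and optionally `peak_pattern` (a numeric
#'   multiplier cycled over successive efforts), from which a jittered
#'   effort train is generated deterministically from `seed`.
#' @param vent a [vent_settings] object.
#' @param duration_s recording length (s).
#' @param cardiac_noise_amp amplitude of the damped-sinusoid cardiac
#'   bursts on Pes (cmH2O).
#' @param noise_sd_flow,noise_sd_pes,noise_sd_paw Gaussian sensor noise
#'   on the recorded channels (the underlying state stays clean).
#' @param cardiac_rate_hz cardiac burst rate (Hz).
#' @param sample_rate output sampling rate (Hz).
#' @param internal_rate integration rate (Hz); must be a multiple of
#'   `sample_rate`.
#' @param pes_baseline esophageal pressure baseline (cmH2O).
#' @param seed integer seed fixing all randomness; two runs of the same
#'   scenario are bit-identical.
#' @return A list of class `vw_scenario`.
#' @export
sim_scenario <- function(mechanics = ventwave::mechanics(),
                         efforts = list(rate_per_min = 20),
                         vent = vent_settings(), duration_s = 30,
                         cardiac_noise_amp = 0.5, noise_sd_flow = 0.01,
                         noise_sd_pes = 0.05, noise_sd_paw = 0.02,
                         cardiac_rate_hz = 1.2, sample_rate = 100,
                         internal_rate = 1000, pes_baseline = 5, seed = 1) {
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  if (internal_rate %% sample_rate != 0)
    abort_argument("internal_rate must be an integer multiple of sample_rate")
  structure(list(mechanics = mechanics, efforts = efforts, vent = vent,
                 duration_s = duration_s,
                 cardiac_noise_amp = cardiac_noise_amp,
                 noise_sd_flow = noise_sd_flow, noise_sd_pes = noise_sd_pes,
                 noise_sd_paw = noise_sd_paw,
                 cardiac_rate_hz = cardiac_rate_hz,
                 sample_rate = sample_rate, internal_rate = internal_rate,
                 pes_baseline = pes_baseline, seed = as.integer(seed)),
            class = "vw_scenario")
}

## Resolve the effort specification of a scenario into a list of
## vw_effort objects (deterministic in scenario$seed).
resolve_efforts <- function(scenario) {
  ef <- scenario$efforts
  if (length(ef) && inherits(ef[[1]], "vw_effort")) return(ef)
  rate <- ef$rate_per_min %||% 20
  period <- 60 / rate
  start <- ef$start_s %||% 1.5
  jitter <- ef$jitter_s %||% 0.05
  peak <- ef$peak_pmus %||% 10
  rise <- ef$rise_time_s %||% 0.7
  relax <- ef$relax_tau_s %||% 0.1
  pattern <- ef$peak_pattern %||% 1
  onsets <- seq(start, scenario$duration_s, by = period)
  jit <- with_seed(scenario$seed + 7L, stats::rnorm(length(onsets), 0, jitter))
  onsets <- onsets + jit
  peaks <- peak * rep_len(pattern, length(onsets))
  out <- list()
  for (i in seq_along(onsets)) {
    if (peaks[i] <= 0) next
    out[[length(out) + 1L]] <-
      effort_profile(onsets[i], rise_time_s = rise, peak_pmus = peaks[i],
                     relax_tau_s = relax)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate the muscle-pressure train at arbitrary times.
pmus_eval <- function(efforts, t) {
  p <- numeric(length(t))
  for (ef in efforts) {
    if (ef$peak_pmus <= 0) next
    tpk <- ef$onset_s + ef$rise_time_s
    rel <- t - ef$onset_s
    rise_idx <- rel >= 0 & rel < ef$rise_time_s
    p[rise_idx] <- p[rise_idx] +
      ef$peak_pmus * (1 - cos(pi * rel[rise_idx] / ef$rise_time_s)) / 2
    dec_idx <- t >= tpk
    p[dec_idx] <- p[dec_idx] +
      ef$peak_pmus * exp(-(t[dec_idx] - tpk) / ef$relax_tau_s)
  }
  p
}

#' Generate the muscle-pressure train and truth effort table
#'
#' The ground-truth end of each effort is the mid-relaxation time: the
#' instant at which muscle pressure has relaxed to 50% of its peak,
#' i.e. `onset + rise_time + relax_tau * log(2)`. Zero-amplitude
#' efforts and efforts whose mid-relaxation falls beyond the recording
#' are excluded from the truth table.
#'
#' @param scenario a [sim_scenario].
#' @return A list with `time` (s), `pmus` (cmH2O, at the scenario
#'   output rate) and `efforts` (an [event_table] with source
#'   `"truth"`).
#' @export
make_effort_train <- function(scenario) {
  efforts <- resolve_efforts(scenario)
  tt <- seq(0, scenario$duration_s, by = 1 / scenario$sample_rate)
  keep <- logical(length(efforts))
  starts <- ends <- numeric(length(efforts))
  for (i in seq_along(efforts)) {
    ef <- efforts[[i]]
    starts[i] <- ef$onset_s
    ends[i] <- ef$onset_s + ef$rise_time_s + ef$relax_tau_s * log(2)
    # an effort is scoreable ground truth only if its relaxation (and
    # hence its mid-relaxation end) is contained in the recording
    keep[i] <- ef$peak_pmus > 0 && ef$onset_s >= 0 &&
      ends[i] + 0.5 <= scenario$duration_s
  }
  list(time = tt, pmus = pmus_eval(efforts, tt),
       efforts = event_table("effort", starts[keep], ends[keep], "truth"))
}

## Cardiac disturbance: damped sinusoid bursts at the cardiac rate.
cardiac_eval <- function(t, amp, rate_hz) {
  if (amp <= 0) return(numeric(length(t)))
  phase <- (t * rate_hz) %% 1 / rate_hz     # time since last beat
  amp * exp(-phase / 0.12) * sin(2 * pi * 7 * phase)
}

#' Simulate a pressure-support ventilation recording
#'
#' Integrates the single-compartment equation of motion driven by the
#' patient effort train and the ventilator state machine, and returns
#' the recorded waveforms together with ground truth.
#'
#' @param scenario a [sim_scenario].
#' @return A list of class `psv_sim` with elements:
#'   \describe{
#'     \item{recording}{a [vent_recording] (flow, Paw, Pes) with sensor
#'       noise applied;}
#'     \item{truth}{list with `efforts` and `machine_breaths` event
#'       tables and `classes`, the breath classification obtained by
#'       applying the pairing rules to the truth tables;}
#'     \item{state}{data.frame of noise-free state series (`time`,
#'       `flow`, `paw`, `pes`, `pmus`, `pdist`, `volume`) at the output
#'       rate, satisfying the equation of motion exactly;}
#'     \item{scenario}{the scenario that produced it.}
#'   }
#' @export
simulate_recording <- function(scenario) {
  if (!inherits(scenario, "vw_scenario"))
    abort_argument("`scenario` must be a vw_scenario")
  mech <- scenario$mechanics; vent <- scenario$vent
  R <- mech$resistance_R; C <- mech$compliance_C
  peep_tot <- mech$peep_total %||% vent$peep
  dR <- vent$demand_resistance
  dt <- 1 / scenario$internal_rate
  n <- as.integer(round(scenario$duration_s * scenario$internal_rate)) + 1L
  t <- (seq_len(n) - 1L) * dt

  efforts <- resolve_efforts(scenario)
  pmus <- pmus_eval(efforts, t)
  card <- cardiac_eval(t, scenario$cardiac_noise_amp, scenario$cardiac_rate_hz)
  pdist <- if (vent$autotrigger_sensitivity) card else numeric(n)

  a_ins <- 1 - exp(-dt / vent$pressurization_rise_s)
  a_exp <- 1 - exp(-dt / vent$release_tau_s)
  p_ins <- vent$peep + vent$pressure_support

  flow <- paw_rec <- vol <- numeric(n)
  paw <- vent$peep; V <- 0
  state <- 0L                     # 0 = expiration, 1 = inspiration
  exp_start <- -Inf; insp_start <- NA_real_
  pending <- NA_real_; peakflow <- 0
  ti_start <- ti_end <- numeric(0)

  for (k in seq_len(n)) {
    if (state == 1L) paw <- paw + (p_ins - paw) * a_ins
    else             paw <- paw + (vent$peep - paw) * a_exp
    num <- paw + pmus[k] + pdist[k] - V / C - peep_tot
    if (state == 0L && num > 0) {
      f <- num / (R + dR)
      paw_rec[k] <- paw - dR * f
    } else {
      f <- num / R
      paw_rec[k] <- paw
    }
    flow[k] <- f
    vol[k] <- V

    if (state == 0L) {
      if (!is.na(pending)) {
        if (t[k] >= pending) {
          state <- 1L; insp_start <- t[k]; peakflow <- 0
          ti_start <- c(ti_start, t[k]); pending <- NA_real_
        }
      } else if (t[k] - exp_start >= vent$min_exp_s && f > vent$flow_trigger) {
        if (vent$forced_trigger_delay_s > 0) {
          pending <- t[k] + vent$forced_trigger_delay_s
        } else {
          state <- 1L; insp_start <- t[k]; peakflow <- 0
          ti_start <- c(ti_start, t[k])
        }
      }
    } else {
      peakflow <- max(peakflow, f)
      it <- t[k] - insp_start
      if ((it >= vent$min_insp_s &&
           f <= vent$expiratory_trigger_fraction * peakflow) ||
          it >= vent$max_ti_s) {
        state <- 0L; exp_start <- t[k]
        ti_end <- c(ti_end, t[k])
      }
    }
    V <- V + f * dt
  }

  # drop an unfinished machine breath at the recording edge
  n_br <- min(length(ti_start), length(ti_end))
  ti_start <- ti_start[seq_len(n_br)]; ti_end <- ti_end[seq_len(n_br)]

  dec <- as.integer(scenario$internal_rate / scenario$sample_rate)
  idx <- seq(1L, n, by = dec)
  pes_clean <- scenario$pes_baseline +
    mech$chest_wall_elastance_Ecw * vol - pmus + card

  noise <- with_seed(scenario$seed, list(
    flow = stats::rnorm(length(idx), 0, scenario$noise_sd_flow),
    paw  = stats::rnorm(length(idx), 0, scenario$noise_sd_paw),
    pes  = stats::rnorm(length(idx), 0, scenario$noise_sd_pes)))

  rec <- vent_recording(
    flow = flow[idx] + noise$flow,
    paw  = paw_rec[idx] + 0.1 * card[idx] + noise$paw,
    pes  = pes_clean[idx] + noise$pes,
    sample_rate = scenario$sample_rate,
    meta = list(seed = scenario$seed))

  train <- make_effort_train(scenario)
  machine <- if (n_br > 0)
    event_table("machine_breath", ti_start, ti_end, "machine")
  else event_table()
  classes <- if (nrow(train$efforts) || n_br > 0)
    pair_events(train$efforts, machine) else NULL

  structure(list(
    recording = rec,
    truth = list(efforts = train$efforts, machine_breaths = machine,
                 classes = classes),
    state = data.frame(time = t[idx], flow = flow[idx], paw = paw_rec[idx],
                       pes = pes_clean[idx], pmus = pmus[idx],
                       pdist = pdist[idx], volume = vol[idx]),
    scenario = scenario), class = "psv_sim")
}

#' @export
print.psv_sim <- function(x, ...) {
  cat(sprintf("<psv_sim> %.0f s, %d truth efforts, %d machine breaths\n",
              rec_duration(x$recording), nrow(x$truth$efforts),
              nrow(x$truth$machine_breaths)))
  if (!is.null(x$truth$classes))
    print(table(class = x$truth$classes$class))
  invisible(x)
}

#' Equation-of-motion residual of a simulation
#'
#' Recomputes `Paw + Pmus + Pdist - R*flow - V/C - PEEPtot` at every
#' output sample from the noise-free state series; the simulator's
#' contract is that this is zero to numerical precision.
#'
#' @param sim a `psv_sim` object.
#' @return Numeric vector of residuals (cmH2O).
#' @export
eom_residual <- function(sim) {
  mech <- sim$scenario$mechanics; vent <- sim$scenario$vent
  peep_tot <- mech$peep_total %||% vent$peep
  st <- sim$state
  dR <- vent$demand_resistance
  # the recorded Paw already absorbs the demand-valve resistance, so the
  # single-R equation holds with the recorded channel
  st$paw + st$pmus + st$pdist - mech$resistance_R * st$flow -
    st$volume / mech$compliance_C - peep_tot
}
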