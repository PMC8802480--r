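## Validation sweep: a fixed battery of simulated scenarios used to
## characterize detector performance against ground truth.

#' Scenario battery for detector validation
#'
#' Twenty deterministic scenarios: the five interaction phenotypes
#' ([scenario_preset]) at two seeds each, plus ten synchronous-pattern
#' scenarios sweeping the expiratory time constant over 0.2-1.2 s
#' (resistance 10 cmH2O s/L, compliance set to tau/R), used for the
#' mechanics-recovery check.
#'
#' @param seed base seed; all scenario seeds derive from it.
#' @param duration_s per-scenario recording length (s).
#' @return Named list of [sim_scenario] objects; tau-sweep entries
#'   carry their nominal time constant in `$mechanics`.
#' @export
validation_scenarios <- function(seed = 1, duration_s = 30) {
  seed <- as.integer(seed)
  out <- list()
  presets <- c("synchronous", "restrictive", "obstructive", "ineffective",
               "autotrigger")
  for (p in presets) for (k in 0:1) {
    out[[sprintf("%s_%d", p, k + 1)]] <-
      scenario_preset(p, seed = seed + k, duration_s = duration_s)
  }
  taus <- seq(0.2, 1.2, length.out = 10)
  for (i in seq_along(taus)) {
    R <- 10; C <- taus[i] / R
    out[[sprintf("tau_%03.0fms", 1000 * taus[i])]] <- sim_scenario(
      mechanics = mechanics(resistance_R = R, compliance_C = C),
      efforts = list(rate_per_min = 14, peak_pmus = 10, rise_time_s = 0.7,
                     relax_tau_s = 0.1, jitter_s = 0.05, start_s = 1.5),
      vent = vent_settings(expiratory_trigger_fraction = 0.25,
                           max_ti_s = 1.5),
      duration_s = duration_s, seed = seed + 100L + i)
  }
  out
}

## match detected events to truth by nearest start within a tolerance;
## returns per-truth deltas (NA where undetected) and the count of
## unmatched detections
match_events <- function(truth, detected, tol = 0.3) {
  n <- nrow(truth)
  ds <- de <- rep(NA_real_, n)
  used <- logical(nrow(detected))
  if (n && nrow(detected)) {
    for (i in seq_len(n)) {
      d <- abs(detected$start_s - truth$start_s[i]); d[used] <- Inf
      j <- which.min(d)
      if (length(j) && is.finite(d[j]) && d[j] <= tol) {
        used[j] <- TRUE
        ds[i] <- detected$start_s[j] - truth$start_s[i]
        de[i] <- detected$end_s[j] - truth$end_s[i]
      }
    }
  }
  list(d_start = ds, d_end = de, n_false_positive = sum(!used))
}

#' Run the validation sweep
#'
#' Simulates every scenario, runs both the waveform method and the
#' esophageal-pressure reference against ground truth, classifies
#' breaths from the waveform-derived events, and collects the headline
#' performance quantities.
#'
#' @param scenarios list from [validation_scenarios].
#' @param wave_cfg,pes_cfg detector configurations.
#' @param timing_tol_s timing-agreement tolerance (s, default 0.1).
#' @return A list with detection and timing fractions for both
#'   methods, the breath-class Cohen's kappa against truth, the
#'   maximum relative error of the expiratory-time-constant recovery
#'   on the tau-sweep scenarios, the maximum equation-of-motion
#'   residual, and the maximum asynchrony-time bookkeeping error.
#' @export
run_validation <- function(scenarios = validation_scenarios(),
                           wave_cfg = wave_config(),
                           pes_cfg = pes_config(), timing_tol_s = 0.1) {
  acc <- list(truth = 0L,
              wave_det = 0L, wave_ok = 0L, wave_fp = 0L, wave_matched = 0L,
              pes_det = 0L, pes_ok = 0L, pes_fp = 0L, pes_matched = 0L)
  confusion <- NULL
  tau_errs <- numeric(0)
  max_resid <- 0
  max_comp_err <- 0
  n_breaths <- 0L

  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    sim <- simulate_recording(sc)
    rec <- sim$recording
    truth <- sim$truth$efforts
    max_resid <- max(max_resid, max(abs(eom_residual(sim))))

    wave <- suppressWarnings(detect_efforts_waveform(rec, wave_cfg))
    pes <- suppressWarnings(detect_efforts_pes(rec, pes_cfg))
    mw <- match_events(truth, wave)
    mp <- match_events(truth, pes)
    acc$truth <- acc$truth + nrow(truth)
    acc$wave_det <- acc$wave_det + sum(!is.na(mw$d_start))
    acc$wave_ok <- acc$wave_ok + sum(abs(mw$d_start) <= timing_tol_s &
                                       abs(mw$d_end) <= timing_tol_s,
                                     na.rm = TRUE)
    acc$wave_fp <- acc$wave_fp + mw$n_false_positive
    acc$pes_det <- acc$pes_det + sum(!is.na(mp$d_start))
    acc$pes_ok <- acc$pes_ok + sum(abs(mp$d_start) <= timing_tol_s &
                                     abs(mp$d_end) <= timing_tol_s,
                                   na.rm = TRUE)
    acc$pes_fp <- acc$pes_fp + mp$n_false_positive

    ## breath classification: waveform-derived machine + efforts vs truth
    machine_w <- detect_machine_phases(rec$paw, rec$sample_rate, wave_cfg,
                                       rec$t0)
    rec_wave <- pair_events(wave, machine_w)
    rec_truth <- sim$truth$classes
    if (!is.null(rec_truth) && nrow(rec_truth) && nrow(rec_wave)) {
      agr <- agreement(rec_wave, rec_truth)
      confusion <- if (is.null(confusion)) agr$confusion
        else confusion + agr$confusion
      n_breaths <- n_breaths + nrow(rec_truth)
      ## asynchrony-time bookkeeping: components must sum to the total
      summ <- interaction_summary(rec_truth, rec_duration(rec))
      max_comp_err <- max(max_comp_err,
                          abs(sum(summ$component_times_s) -
                                summ$total_asynchrony_time_s))
    }

    if (startsWith(nm, "tau_")) {
      tau_nom <- sc$mechanics$resistance_R * sc$mechanics$compliance_C
      est <- expiratory_time_constant(rec, sim$truth$machine_breaths,
                                      efforts = truth)
      tau_errs <- c(tau_errs, abs(est$tau_e_s - tau_nom) / tau_nom)
    }
  }

  kappa <- if (!is.null(confusion)) agreement_stats(confusion)$kappa else NA

  list(
    n_truth_efforts = acc$truth,
    n_breaths = n_breaths,
    wave_detected_pct = 100 * acc$wave_det / acc$truth,
    wave_timing_ok_pct = 100 * acc$wave_ok / acc$wave_det,
    wave_false_positives = acc$wave_fp,
    pes_detected_pct = 100 * acc$pes_det / acc$truth,
    pes_timing_ok_pct = 100 * acc$pes_ok / acc$pes_det,
    pes_false_positives = acc$pes_fp,
    class_kappa = kappa,
    tau_recovery_max_rel_err = max(tau_errs),
    eom_residual_max = max_resid,
    asynchrony_time_component_err = max_comp_err)
}
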