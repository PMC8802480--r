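## High-level analysis object: detect, pair, classify, summarize.

#' Analyze patient-ventilator interaction in one recording
#'
#' Runs effort detection with the chosen method, detects machine
#' phases on Paw, pairs efforts with machine breaths, flags minor
#' asynchronies and summarizes the recording.
#'
#' @param rec a [vent_recording].
#' @param method `"waveform"` (flow + Paw only), `"pes"` (esophageal
#'   reference; requires the Pes channel) or `"truth"` (use the
#'   supplied `efforts` table, e.g. simulator ground truth).
#' @param efforts effort [event_table] used when `method = "truth"`.
#' @param wave_cfg,pes_cfg detector configurations.
#' @param match_tolerance_s pairing tolerance (s), see [pair_events].
#' @param delay_threshold_s minor-asynchrony threshold (s), see
#'   [compute_delays].
#' @return An object of class `pv_interaction`: list with `efforts`,
#'   `machine_breaths`, `records` (breath records with flags),
#'   `summary` (an [interaction_summary]) and `method`.
#' @export
pv_interaction <- function(rec, method = c("waveform", "pes", "truth"),
                           efforts = NULL, wave_cfg = wave_config(),
                           pes_cfg = pes_config(), match_tolerance_s = 0.3,
                           delay_threshold_s = 0.25) {
  method <- match.arg(method)
  machine <- detect_machine_phases(rec$paw, rec$sample_rate, wave_cfg, rec$t0)
  ef <- switch(method,
    waveform = detect_efforts_waveform(rec, wave_cfg),
    pes = detect_efforts_pes(rec, pes_cfg),
    truth = {
      if (is.null(efforts))
        abort_argument("method = 'truth' requires an `efforts` table")
      efforts
    })
  records <- pair_events(ef, machine, match_tolerance_s)
  if (nrow(records) &&
      any(records$class %in% c("assisted", "double-triggered")))
    records <- compute_delays(records, delay_threshold_s)
  summ <- if (nrow(records))
    interaction_summary(records, rec_duration(rec)) else NULL
  structure(list(efforts = ef, machine_breaths = machine, records = records,
                 summary = summ, method = method, recording = rec),
            class = "pv_interaction")
}

#' @export
print.pv_interaction <- function(x, ...) {
  cat(sprintf("<pv_interaction> method = %s\n", x$method))
  if (!is.null(x$summary)) print(x$summary) else cat("  no breaths detected\n")
  invisible(x)
}

#' @export
summary.pv_interaction <- function(object, ...) object$summary

#' @export
plot.pv_interaction <- function(x, ...) {
  plot(x$recording, events = x$efforts, ...)
}
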