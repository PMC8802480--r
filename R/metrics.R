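## interaction_metrics: pairing of efforts with machine breaths, breath
## classification, asynchrony statistics, expiratory time constant and
## agreement between two event sources.

normalize_machine <- function(machine) {
  if (is.null(machine) || (is.data.frame(machine) && !nrow(machine)))
    return(data.frame(ti_start_s = numeric(), ti_end_s = numeric()))
  if (is.data.frame(machine)) {
    if (all(c("start_s", "end_s") %in% names(machine)))
      return(data.frame(ti_start_s = machine$start_s, ti_end_s = machine$end_s))
    if (all(c("ti_start_s", "ti_end_s") %in% names(machine)))
      return(machine[, c("ti_start_s", "ti_end_s")])
  }
  if (is.list(machine))
    return(data.frame(
      ti_start_s = vapply(machine, `[[`, 0, "ti_start_s"),
      ti_end_s = vapply(machine, `[[`, 0, "ti_end_s")))
  abort_argument("cannot interpret `machine` as machine breaths")
}

#' Pair patient efforts with machine breaths and classify breaths
#'
#' A machine breath is attributed to a patient effort when its
#' inspiratory start falls inside `[effort start, effort end +
#' match_tolerance_s]`. One effort with one breath is an assisted
#' breath; one effort that captures two or more breaths is
#' double-triggered (timing errors are computed against the first
#' breath's start and the last breath's end); an effort with no breath
#' is an ineffective effort; a breath with no effort is auto-triggered.
#' Every effort and every machine breath appears in exactly one record.
#'
#' @param efforts an [event_table] of efforts (any source).
#' @param machine machine breaths: an [event_table] with kind
#'   `machine_breath`, or a data.frame with `ti_start_s`/`ti_end_s`.
#' @param match_tolerance_s tolerance beyond the effort end (s).
#' @return A data.frame of class `breath_records` with one row per
#'   breath record: `class`, effort and machine interval bounds,
#'   `n_machine`, `dti_start_s`, `dti_end_s`.
#' @export
pair_events <- function(efforts, machine, match_tolerance_s = 0.3) {
  mb <- normalize_machine(machine)
  if (nrow(mb) > 1L) {
    mb <- mb[order(mb$ti_start_s), , drop = FALSE]
    if (any(mb$ti_start_s[-1L] < mb$ti_end_s[-nrow(mb)] - 1e-9))
      abort_data("machine breaths overlap")
  }
  ef <- if (is.null(efforts) || !nrow(efforts))
    data.frame(start_s = numeric(), end_s = numeric())
  else as.data.frame(efforts)[order(efforts$start_s), c("start_s", "end_s")]

  owner <- rep(NA_integer_, nrow(mb))
  for (j in seq_len(nrow(mb))) {
    hit <- which(ef$start_s <= mb$ti_start_s[j] &
                   mb$ti_start_s[j] <= ef$end_s + match_tolerance_s)
    if (length(hit)) owner[j] <- hit[length(hit)]   # latest qualifying effort
  }

  rows <- list()
  for (i in seq_len(nrow(ef))) {
    br <- which(owner == i)
    if (!length(br)) {
      rows[[length(rows) + 1L]] <- data.frame(
        class = "ineffective", effort_start_s = ef$start_s[i],
        effort_end_s = ef$end_s[i], machine_start_s = NA_real_,
        machine_end_s = NA_real_, n_machine = 0L,
        dti_start_s = NA_real_, dti_end_s = NA_real_)
    } else {
      cls <- if (length(br) >= 2L) "double-triggered" else "assisted"
      ms <- mb$ti_start_s[br[1L]]; me <- mb$ti_end_s[br[length(br)]]
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, effort_start_s = ef$start_s[i],
        effort_end_s = ef$end_s[i], machine_start_s = ms,
        machine_end_s = me, n_machine = length(br),
        dti_start_s = ms - ef$start_s[i], dti_end_s = me - ef$end_s[i])
    }
  }
  for (j in which(is.na(owner))) {
    rows[[length(rows) + 1L]] <- data.frame(
      class = "auto-triggered", effort_start_s = NA_real_,
      effort_end_s = NA_real_, machine_start_s = mb$ti_start_s[j],
      machine_end_s = mb$ti_end_s[j], n_machine = 1L,
      dti_start_s = NA_real_, dti_end_s = NA_real_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    class = character(), effort_start_s = numeric(), effort_end_s = numeric(),
    machine_start_s = numeric(), machine_end_s = numeric(),
    n_machine = integer(), dti_start_s = numeric(), dti_end_s = numeric())
  key <- ifelse(is.na(out$effort_start_s), out$machine_start_s,
                out$effort_start_s)
  out <- out[order(key), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("breath_records", "data.frame")
  out
}

#' Flag minor asynchronies from timing differences
#'
#' Applies the +/-250 ms convention: a trigger delay is
#' `dti_start_s > threshold`, early cycling `dti_end_s < -threshold`
#' and late cycling `dti_end_s > threshold`, all strict inequalities.
#'
#' @param records a `breath_records` data.frame from [pair_events];
#'   must contain at least one assisted or double-triggered record.
#' @param threshold_s flag threshold in seconds (default 0.250).
#' @return `records` with logical columns `trigger_delay`,
#'   `early_cycling`, `late_cycling` (NA for breaths without delays).
#' @export
compute_delays <- function(records, threshold_s = 0.25) {
  if (!nrow(records) || !any(records$class %in% c("assisted", "double-triggered")))
    abort_contract("compute_delays requires assisted or double-triggered records")
  has <- records$class %in% c("assisted", "double-triggered")
  records$trigger_delay <- ifelse(has, records$dti_start_s > threshold_s, NA)
  records$early_cycling <- ifelse(has, records$dti_end_s < -threshold_s, NA)
  records$late_cycling  <- ifelse(has, records$dti_end_s > threshold_s, NA)
  records
}

#' Summarize patient-ventilator interaction over a recording
#'
#' The asynchrony index is the percentage of breaths affected by major
#' asynchronies (auto-triggered, double-triggered, ineffective). Total
#' asynchrony time is the sum of the absolute trigger and cycling
#' timing errors of assisted (and double-triggered) breaths plus the
#' durations of auto-triggered breaths and of ineffective efforts,
#' expressed as a percentage of recording time.
#'
#' @param records a `breath_records` data.frame.
#' @param recording_duration_s recording length (s).
#' @param tau_e_s optional expiratory time constant to carry along.
#' @return A list of class `interaction_summary`.
#' @export
interaction_summary <- function(records, recording_duration_s,
                                tau_e_s = NA_real_) {
  stopifnot_scalar(recording_duration_s, "recording_duration_s",
                   positive = TRUE)
  if (!nrow(records))
    abort_contract("asynchrony index is undefined for zero breaths")
  n <- table(factor(records$class, levels = c(
    "assisted", "auto-triggered", "double-triggered", "ineffective")))
  n_total <- nrow(records)
  ai <- 100 * (n[["auto-triggered"]] + n[["double-triggered"]] +
                 n[["ineffective"]]) / n_total

  has_delay <- records$class %in% c("assisted", "double-triggered")
  trig_s <- sum(abs(records$dti_start_s[has_delay]))
  cyc_s  <- sum(abs(records$dti_end_s[has_delay]))
  inef <- records$class == "ineffective"
  inef_s <- sum(records$effort_end_s[inef] - records$effort_start_s[inef])
  auto <- records$class == "auto-triggered"
  auto_s <- sum(records$machine_end_s[auto] - records$machine_start_s[auto])
  comp <- c(trigger_delay = trig_s, cycling = cyc_s,
            ineffective = inef_s, auto_triggered = auto_s)
  structure(list(
    n_total = n_total, n_assisted = n[["assisted"]],
    n_auto = n[["auto-triggered"]], n_double = n[["double-triggered"]],
    n_ineffective = n[["ineffective"]],
    asynchrony_index_pct = as.numeric(ai),
    total_asynchrony_time_s = sum(comp),
    total_asynchrony_time_pct = 100 * sum(comp) / recording_duration_s,
    component_times_s = comp,
    recording_duration_s = recording_duration_s,
    tau_e_s = tau_e_s,
    mechanics_class = if (is.na(tau_e_s)) NA_character_
      else mechanics_class(tau_e_s)), class = "interaction_summary")
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Patient-ventilator interaction over %.1f s\n",
    "  breaths: %d (assisted %d, auto-triggered %d, double-triggered %d, ineffective %d)\n",
    "  asynchrony index: %.1f%%\n",
    "  total asynchrony time: %.2f s (%.1f%% of recording)\n"),
    x$recording_duration_s, x$n_total, x$n_assisted, x$n_auto, x$n_double,
    x$n_ineffective, x$asynchrony_index_pct, x$total_asynchrony_time_s,
    x$total_asynchrony_time_pct))
  if (!is.na(x$tau_e_s))
    cat(sprintf("  expiratory time constant: %.2f s (%s)\n",
                x$tau_e_s, x$mechanics_class))
  invisible(x)
}

#' Mechanics class from the expiratory time constant
#'
#' Restrictive below 0.4 s, normal from 0.4 to 0.7 s (inclusive),
#' obstructive above 0.7 s.
#' @param tau_e_s expiratory time constant (s).
#' @return `"restrictive"`, `"normal"` or `"obstructive"`.
#' @export
mechanics_class <- function(tau_e_s) {
  ifelse(tau_e_s < 0.4, "restrictive",
         ifelse(tau_e_s <= 0.7, "normal", "obstructive"))
}

#' Expiratory time constant from the flow-volume relation
#'
#' During passive expiration the single-compartment model gives
#' `flow = -(V - V_eq) / tau`, so the time constant is the negative
#' inverse slope of the least-squares fit of flow against cumulative
#' volume over the middle portion of each passive expiration; the
#' per-breath estimates are averaged.
#'
#' @param rec a [vent_recording].
#' @param machine machine breaths (see [pair_events]).
#' @param efforts optional effort [event_table]; expirations containing
#'   an effort are excluded. When `NULL`, an expiration is accepted as
#'   passive if a single exponential decay segment covers most of it.
#' @param frac_range fraction of the peak expiratory flow magnitude
#'   delimiting the fitted middle portion.
#' @param post_peak_skip_s time skipped after the expiratory flow peak
#'   (s); residual inspiratory-muscle relaxation persists for roughly
#'   three relaxation time constants after cycling and biases the
#'   early flow-volume relation upward.
#' @return A list with `tau_e_s`, `mechanics_class` and the per-breath
#'   estimates `tau_breaths`.
#' @export
expiratory_time_constant <- function(rec, machine, efforts = NULL,
                                     frac_range = c(0.1, 0.9),
                                     post_peak_skip_s = 0.3) {
  mb <- normalize_machine(machine)
  if (!nrow(mb)) abort_capability("no machine breaths: cannot delimit expirations")
  tt <- rec_time(rec)
  # light smoothing attenuates sensor noise, whose leverage otherwise
  # dilutes the flow-volume slope at short time constants
  flow <- moving_average(rec$flow, round(0.05 * rec$sample_rate))
  vol <- cumsum(flow) / rec$sample_rate
  decays <- if (is.null(efforts))
    detect_decay_segments(rec$flow, rec$sample_rate) else NULL
  taus <- numeric(0)
  for (j in seq_len(nrow(mb))) {
    e0 <- mb$ti_end_s[j]
    e1 <- if (j < nrow(mb)) mb$ti_start_s[j + 1L] else tt[length(tt)]
    if (e1 - e0 < 0.4) next
    if (!is.null(efforts) && nrow(efforts)) {
      if (any(efforts$start_s < e1 & efforts$end_s > e0 &
                efforts$start_s > e0 - 0.2)) next
    } else if (!is.null(decays)) {
      cov <- 0
      if (nrow(decays)) {
        ds <- pmax(decays$start_s, e0); de <- pmin(decays$end_s, e1)
        cov <- max(0, max(de - ds))
      }
      if (cov < 0.6 * (e1 - e0)) next
    }
    idx <- which(tt >= e0 & tt <= e1 & flow < 0)
    if (length(idx) < 10L) next
    pk_i <- idx[which.max(abs(flow[idx]))]
    idx <- idx[tt[idx] >= tt[pk_i] + post_peak_skip_s]   # decay limb only
    if (length(idx) < 10L) next
    pk <- max(abs(flow[idx]))
    sel <- idx[abs(flow[idx]) >= frac_range[1L] * pk &
                 abs(flow[idx]) <= frac_range[2L] * pk]
    if (length(sel) < 10L) next
    fit <- stats::lm.fit(cbind(1, vol[sel]), flow[sel])
    slope <- fit$coefficients[2L]
    if (is.finite(slope) && slope < 0) taus <- c(taus, -1 / slope)
  }
  if (!length(taus))
    abort_capability("no passive expiratory phase available")
  tau <- mean(taus)
  list(tau_e_s = tau, mechanics_class = mechanics_class(tau),
       tau_breaths = taus)
}

## ---- agreement -------------------------------------------------------------

#' Agreement statistics from a confusion matrix
#'
#' Cohen's kappa with the standard observed/expected-agreement formula,
#' plus per-class one-vs-rest sensitivity, specificity, positive and
#' negative predictive values (in percent). Rows are reference classes,
#' columns are test classes; the matrix is squared over the union of
#' row and column names so an asymmetric category (such as "missed")
#' is handled naturally.
#'
#' @param confusion a numeric matrix with dimnames (reference in rows,
#'   test in columns).
#' @return A list of class `agreement_report`.
#' @export
agreement_stats <- function(confusion) {
  if (is.null(dimnames(confusion)))
    abort_argument("confusion matrix must have dimnames")
  cls <- union(rownames(confusion), colnames(confusion))
  m <- matrix(0, length(cls), length(cls), dimnames = list(cls, cls))
  m[rownames(confusion), colnames(confusion)] <- confusion
  n <- sum(m)
  if (n == 0) abort_contract("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  per <- do.call(rbind, lapply(cls, function(k) {
    tp <- m[k, k]; fn <- sum(m[k, ]) - tp
    fp <- sum(m[, k]) - tp; tn <- n - tp - fn - fp
    data.frame(class = k,
               sensitivity = 100 * tp / (tp + fn),
               specificity = 100 * tn / (tn + fp),
               ppv = 100 * tp / (tp + fp),
               npv = 100 * tn / (tn + fn))
  }))
  structure(list(confusion = m, n = n, kappa = as.numeric(kappa),
                 per_class = per), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat(sprintf("Agreement over %d breaths: Cohen's kappa = %.*f\n",
              x$n, digits, x$kappa))
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Agreement between two breath classifications
#'
#' Aligns two sets of breath records from the same recording by greedy
#' nearest-start matching within a tolerance, builds the confusion
#' matrix of reference versus test classes (unmatched reference records
#' fall in a `"missed"` column) and computes Cohen's kappa and
#' per-class diagnostics. Unmatched test records (spurious detections)
#' are reported in the `n_unmatched_test` field.
#'
#' @param test,reference `breath_records` data.frames.
#' @param match_tolerance_s maximum start-time difference for a match.
#' @return An `agreement_report` (see [agreement_stats]).
#' @export
agreement <- function(test, reference, match_tolerance_s = 0.5) {
  if (!nrow(test) || !nrow(reference))
    abort_contract("agreement requires nonempty test and reference records")
  key <- function(r) ifelse(is.na(r$effort_start_s), r$machine_start_s,
                            r$effort_start_s)
  kt <- key(test); kr <- key(reference)
  ord_r <- order(kr)
  match_t <- rep(NA_integer_, length(kr))
  used <- logical(length(kt))
  for (i in ord_r) {
    d <- abs(kt - kr[i]); d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= match_tolerance_s) {
      match_t[i] <- j; used[j] <- TRUE
    }
  }
  cls <- c("assisted", "auto-triggered", "double-triggered", "ineffective")
  ref_lab <- factor(reference$class, levels = cls)
  test_lab <- factor(ifelse(is.na(match_t), "missed",
                            test$class[match_t]),
                     levels = c(cls, "missed"))
  confusion <- table(reference = ref_lab, test = test_lab)
  rep <- agreement_stats(unclass(confusion))
  rep$n_unmatched_test <- sum(!used)
  rep
}

#' Area under the ROC curve
#'
#' Threshold sweep over the scores with trapezoidal integration, which
#' for binary labels equals the Mann-Whitney concordance probability
#' with the midrank tie convention.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param labels binary reference labels (logical or 0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    abort_argument("scores and labels must be equal-length and complete")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    abort_contract("ROC requires at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))       # tie groups
  tp <- tapply(l, grp, sum); fp <- tapply(!l, grp, sum)
  ctp <- c(0, cumsum(tp)); cfp <- c(0, cumsum(fp))
  tpr <- ctp / n_pos; fpr <- cfp / n_neg
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' Sample size for estimating a proportion
#'
#' Normal-approximation sample size for a two-sided confidence interval
#' of a proportion with the given half-width:
#' `n = z^2 p (1 - p) / half_width^2`, rounded up.
#'
#' @param conf_level confidence level (default 0.99).
#' @param half_width CI half-width on the proportion scale (default 0.02).
#' @param p anticipated proportion (default 0.5, the worst case).
#' @param z optional critical value overriding `qnorm`; clinical
#'   protocols conventionally use the two-decimal value (2.58 for 99%).
#' @return Required number of observations (integer).
#' @export
sample_size_proportion <- function(conf_level = 0.99, half_width = 0.02,
                                   p = 0.5, z = NULL) {
  if (!(conf_level > 0 && conf_level < 1))
    abort_argument("conf_level must lie in (0, 1)")
  stopifnot_scalar(half_width, "half_width", positive = TRUE)
  if (is.null(z)) z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ceiling(z^2 * p * (1 - p) / half_width^2 - 1e-9)
}
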