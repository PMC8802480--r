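## pes_reference: patient effort timing from the esophageal pressure
## channel (the reference method).
##
## The effort start is a sudden negative deflection of Pes; the effort
## end is the midpoint of the fast increase in Pes after its
## inspiratory nadir (mid-relaxation of the inspiratory muscles).
## Because raw Pes also carries the chest-wall recoil component
## (Ecw * V), whose expiratory slope can rival a weak effort's, the
## detector first removes an internally estimated chest-wall component
## and applies its thresholds to the compensated signal.

#' Configuration of the esophageal-pressure detector
#'
#' @param smooth_window_s centered moving-average window (s).
#' @param onset_slope_thresh negative-going slope threshold (cmH2O/s,
#'   magnitude) on the compensated Pes derivative.
#' @param onset_min_drop minimum drop (cmH2O) below the local pre-onset
#'   level that the deflection must reach; rejects cardiac artifacts.
#' @param drop_window_s window (s) within which the drop must be
#'   reached.
#' @param relax_plateau_slope_frac the post-nadir plateau is declared
#'   where the smoothed slope first falls below this fraction of its
#'   post-nadir maximum.
#' @param min_effort_s efforts shorter than this are discarded (s).
#' @param refractory_s minimum separation between onsets (s).
#' @param compensate_chest_wall subtract the internally estimated
#'   chest-wall recoil component (Ecw*V) before thresholding.
#' @return A list of class `pes_config`.
#' @export
pes_config <- function(smooth_window_s = 0.05, onset_slope_thresh = 2,
                       onset_min_drop = 2, drop_window_s = 0.5,
                       relax_plateau_slope_frac = 0.1, min_effort_s = 0.3,
                       refractory_s = 0.8, compensate_chest_wall = TRUE) {
  for (nm in c("smooth_window_s", "onset_slope_thresh", "onset_min_drop",
               "drop_window_s", "relax_plateau_slope_frac", "min_effort_s",
               "refractory_s"))
    stopifnot_scalar(get(nm), nm, positive = TRUE)
  structure(as.list(environment())[c(
    "smooth_window_s", "onset_slope_thresh", "onset_min_drop",
    "drop_window_s", "relax_plateau_slope_frac", "min_effort_s",
    "refractory_s", "compensate_chest_wall")], class = "pes_config")
}

require_pes <- function(rec) {
  if (is.null(rec$pes))
    abort_capability("recording has no esophageal pressure channel")
  invisible(rec)
}

## Chest-wall-compensated Pes: Pes - k*V with k estimated as the robust
## ratio of the Pes derivative to flow over expiratory samples (during
## passive expiration dPes/dt = Ecw*flow).
pes_compensated <- function(rec, cfg) {
  pes <- rec$pes
  if (!isTRUE(cfg$compensate_chest_wall)) return(pes)
  flow <- rec$flow
  if (stats::sd(flow) < 1e-8) return(pes)
  d <- smooth_deriv(pes, rec$sample_rate, cfg$smooth_window_s * 2)
  # substantial expiratory flow only: small flows make the ratio
  # explode under cardiac oscillation
  m <- flow < -0.25
  if (sum(m) < 20L) m <- flow < -0.1
  if (sum(m) < 20L) return(pes)
  k <- stats::median(d[m] / flow[m])
  if (!is.finite(k)) return(pes)
  k <- min(max(k, 0), 30)
  pes - k * cumsum(flow) / rec$sample_rate
}

#' Detect effort onsets on esophageal pressure (patient Ti-start)
#'
#' An onset is a sudden negative deflection: the smoothed derivative of
#' (chest-wall-compensated) Pes falls below `-onset_slope_thresh` and
#' the signal then drops at least `onset_min_drop` below its local
#' pre-onset level within `drop_window_s`. Onsets are separated by at
#' least `refractory_s`; each reported time is backtracked to the local
#' pre-deflection maximum.
#'
#' @param rec a [vent_recording] with a Pes channel.
#' @param cfg a [pes_config].
#' @return Numeric vector of onset times (s).
#' @export
detect_pes_ti_start <- function(rec, cfg = pes_config()) {
  require_pes(rec)
  tt <- rec_time(rec)
  rate <- rec$sample_rate
  ## cardiogenic oscillations (~1-8 Hz bursts) would dominate both the
  ## derivative and any local-maximum search, so onset logic runs on a
  ## heavily smoothed copy of the compensated signal; the window is
  ## centered, so no systematic time shift is introduced
  ph <- moving_average(pes_compensated(rec, cfg), round(0.21 * rate))
  dh <- smooth_deriv(ph, rate, cfg$smooth_window_s)
  n <- length(ph)
  wdrop <- as.integer(round(cfg$drop_window_s * rate))
  wpre <- as.integer(round(0.3 * rate))
  onsets <- numeric(0)
  steep <- dh < -cfg$onset_slope_thresh
  r <- rle(steep)
  run_start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  last_accept <- -Inf
  for (k in which(r$values)) {
    i <- run_start[k]
    if (i < 2L || i > n - 2L) next
    # the deflection must reach the minimum drop below the local
    # pre-onset level within the drop window
    base <- max(ph[max(1L, i - wpre):i])
    lo <- min(ph[i:min(n, i + wdrop)])
    if (base - lo < cfg$onset_min_drop) next
    # slope footpoint: walk back to where the fall had not yet begun
    j <- i
    while (j > 1L && dh[j - 1L] < -0.5 * cfg$onset_slope_thresh &&
             tt[i] - tt[j - 1L] < 0.35) j <- j - 1L
    onset_t <- tt[j]
    if (onset_t - last_accept < cfg$refractory_s) next
    onsets <- c(onsets, onset_t)
    last_accept <- onset_t
  }
  onsets
}

#' Detect the effort end on esophageal pressure (patient Ti-end)
#'
#' Locates the inspiratory nadir of (compensated) Pes after the onset,
#' finds the post-nadir plateau as the point where the smoothed slope
#' first collapses below `relax_plateau_slope_frac` times its
#' post-nadir maximum, and returns the first time Pes crosses the
#' midpoint between nadir and plateau: the midpoint of the fast
#' increase after the nadir, i.e. mid-relaxation.
#'
#' @param rec a [vent_recording] with a Pes channel.
#' @param onset onset time (s) from [detect_pes_ti_start].
#' @param cfg a [pes_config].
#' @param next_onset search limit (s), typically the next onset.
#' @return End time (s); raises a detection error when no recovery to
#'   a plateau exists before `next_onset`.
#' @export
detect_pes_ti_end <- function(rec, onset, cfg = pes_config(),
                              next_onset = Inf) {
  require_pes(rec)
  tt <- rec_time(rec)
  rate <- rec$sample_rate
  p <- moving_average(pes_compensated(rec, cfg),
                      round(cfg$smooth_window_s * rate))
  d <- smooth_deriv(p, rate, cfg$smooth_window_s)
  idx <- which(tt >= onset & tt <= min(next_onset, onset + 8))
  if (length(idx) < 5L) abort_detection("window too short after onset")
  nad <- idx[which.min(p[idx])]
  post <- idx[idx > nad]
  if (length(post) < 3L)
    abort_detection("no recovery after the Pes nadir (monotonic fall)")
  dmax <- max(d[post])
  if (dmax <= 0)
    abort_detection("no recovery after the Pes nadir (monotonic fall)")
  rise_started <- FALSE
  plat <- NA_integer_
  for (j in post) {
    if (!rise_started && d[j] >= 0.5 * dmax) rise_started <- TRUE
    if (rise_started && d[j] < cfg$relax_plateau_slope_frac * dmax) {
      plat <- j; break
    }
  }
  if (is.na(plat)) plat <- post[length(post)]
  target <- p[nad] + 0.5 * (p[plat] - p[nad])
  seg <- nad:plat
  cross <- which(p[seg] >= target)
  cross <- cross[cross > 1L]
  if (!length(cross))
    abort_detection("no midpoint crossing between nadir and plateau")
  j <- seg[cross[1L]]
  # linear interpolation of the crossing
  p1 <- p[j - 1L]; p2 <- p[j]
  frac <- if (p2 != p1) (target - p1) / (p2 - p1) else 0
  tt[j - 1L] + frac * (tt[j] - tt[j - 1L])
}

#' Detect patient efforts from esophageal pressure
#'
#' Composition of [detect_pes_ti_start] and [detect_pes_ti_end]:
#' returns a sorted, non-overlapping effort table; efforts whose end
#' cannot be located are dropped with a warning, and efforts shorter
#' than `min_effort_s` are discarded.
#'
#' @param rec a [vent_recording] with a Pes channel.
#' @param cfg a [pes_config].
#' @return An [event_table] with source `"pes"`.
#' @export
detect_efforts_pes <- function(rec, cfg = pes_config()) {
  require_pes(rec)
  onsets <- detect_pes_ti_start(rec, cfg)
  t_end_rec <- rec$t0 + rec_duration(rec)
  starts <- ends <- numeric(0)
  for (i in seq_along(onsets)) {
    nxt <- if (i < length(onsets)) onsets[i + 1L] else Inf
    e <- tryCatch(detect_pes_ti_end(rec, onsets[i], cfg, nxt),
                  ventwave_detection_error = function(err) {
                    warning(conditionMessage(err), call. = FALSE)
                    NA_real_
                  })
    if (is.na(e)) next
    e <- min(e, nxt - 1 / rec$sample_rate)
    if (e - onsets[i] < cfg$min_effort_s) next
    if (onsets[i] < rec$t0 + 0.25 || e > t_end_rec - 0.25) next
    starts <- c(starts, onsets[i]); ends <- c(ends, e)
  }
  event_table("effort", starts, ends, "pes")
}
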