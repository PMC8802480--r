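## waveform_method: detection of patient effort start/end and of the
## ventilator inspiratory phase from airway pressure and flow alone.
##
## The principle: an exponential decay of flow is the signature of a
## passive respiratory system (inspiratory or expiratory). A patient
## effort announces itself as a sudden positive deflection of flow that
## interrupts such a decay (or a negative Paw deflection during a
## stable expiratory Paw phase), and it ends where a passive
## exponential decay of flow resumes.

#' Configuration of the waveform detector
#'
#' @param decay_min_len_s minimum length of an exponential decay
#'   segment (s).
#' @param decay_r2_thresh minimum R^2 of the log-linear fit over a
#'   decay segment.
#' @param decay_log_rmse_tol alternative acceptance gate: a window also
#'   qualifies when the log-space RMSE of the fit is below this value
#'   (points track the exponential within a few percent), which keeps
#'   shallow decay stretches with little dynamic range from being
#'   rejected by the R^2 criterion.
#' @param amplitude_floor flow magnitude (L/s) below which samples are
#'   excluded from decay fitting.
#' @param max_tau_s fitted time constants above this are treated as
#'   plateaus, not decays.
#' @param flow_deviation_thresh flow excess over the decay-extrapolated
#'   value (L/s) that qualifies as a "sudden positive deflection".
#' @param flow_deviation_sustain_s minimum duration the deviation must
#'   be sustained (s); also rejects brief cardiogenic oscillations.
#' @param paw_drop_thresh negative Paw deflection (cmH2O) below the
#'   stable expiratory baseline that qualifies as an effort mark.
#' @param paw_stable_band half-band (cmH2O) within which Paw counts as
#'   stable.
#' @param paw_rise_thresh minimum pressurization amplitude (cmH2O) for
#'   a machine breath.
#' @param min_effort_s efforts shorter than this are discarded (s).
#' @param smooth_s moving-average smoothing window (s).
#' @param passive_cover_frac fraction of the inspiration that must be
#'   covered by a decay segment for [is_passive_inflation].
#' @param tau_consistency acceptable ratio range of an inspiratory
#'   decay's time constant to the recording's expiratory time constant
#'   (implements the passivity check during the inspiratory phase).
#' @param relative_thresholds if `TRUE`, flow thresholds are expressed
#'   relative to the recording's flow amplitude (0.9 quantile of
#'   `abs(flow)`) instead of absolute L/s, making detected times
#'   invariant under flow rescaling.
#' @param max_extrap_s how far beyond a decay segment its extrapolation
#'   is considered valid (s).
#' @return A list of class `wave_config`.
#' @export
wave_config <- function(decay_min_len_s = 0.2, decay_r2_thresh = 0.98,
                        decay_log_rmse_tol = 0.04,
                        amplitude_floor = 0.02, max_tau_s = 5,
                        flow_deviation_thresh = 0.05,
                        flow_deviation_sustain_s = 0.1,
                        paw_drop_thresh = 0.5, paw_stable_band = 0.5,
                        paw_rise_thresh = 1, min_effort_s = 0.3,
                        smooth_s = 0.05, passive_cover_frac = 0.85,
                        tau_consistency = c(0.5, 2),
                        relative_thresholds = FALSE, max_extrap_s = 2.5) {
  cfg <- as.list(environment())
  if (!(decay_r2_thresh > 0 && decay_r2_thresh < 1))
    abort_argument("decay_r2_thresh must lie in (0, 1)")
  structure(cfg, class = "wave_config")
}

## Remove the residual extrapolation offset/drift from a deviation
## series, estimated over its initial still-passive stretch; applied
## only when the estimate is plausibly an artifact (small offset,
## bounded drift), so a deviation already in progress is preserved.
detrend_passive <- function(dev, tvec, rate, thr, force = FALSE) {
  n0 <- min(length(dev), as.integer(0.12 * rate))
  if (n0 < 4L) return(dev)
  b0 <- stats::median(dev[seq_len(n0)])
  if (!is.finite(b0)) return(dev)
  # an offset as large as the detection threshold is treated as a real
  # deviation already in progress, unless the caller re-anchors by
  # design (backward extrapolation across a volume-state change)
  if (!force && abs(b0) >= thr) return(dev)
  dev - b0
}

## flow scale used in relative-threshold mode
flow_scale <- function(flow) {
  s <- as.numeric(stats::quantile(abs(flow), 0.9))
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Detect exponential-decay segments of flow
#'
#' Finds maximal intervals over which `log(abs(flow))` is linear with
#' negative slope (log-linear least squares, region growing), flow does
#' not change sign and the magnitude stays above the amplitude floor.
#' Such segments mark passive (relaxed) phases of the respiratory
#' system.
#'
#' @param flow flow series (L/s).
#' @param sample_rate sampling rate (Hz).
#' @param cfg a [wave_config].
#' @param t0 time of the first sample (s).
#' @return A data.frame of class `decay_segments` with columns
#'   `start_s`, `end_s`, `tau_s`, `amplitude` (fitted magnitude at the
#'   segment start, L/s), `fit_r2`, `phase` (`"inspiratory"` or
#'   `"expiratory"`), plus the fit coefficients used for extrapolation.
#' @export
detect_decay_segments <- function(flow, sample_rate, cfg = wave_config(),
                                  t0 = 0) {
  if (any(!is.finite(flow))) abort_argument("flow must be finite")
  scale <- if (cfg$relative_thresholds) flow_scale(flow) else 1
  f <- flow / scale
  fs <- moving_average(f, round(cfg$smooth_s * sample_rate))
  n <- length(fs)
  dt <- 1 / sample_rate
  min_len <- max(3L, as.integer(round(cfg$decay_min_len_s * sample_rate)))
  tol <- cfg$flow_deviation_thresh

  segs <- list()
  above <- abs(fs) >= cfg$amplitude_floor
  sgn <- sign(fs)
  run_id <- cumsum(c(TRUE, diff(above) != 0 | diff(sgn) != 0))
  for (ids in split(seq_len(n), run_id)) {
    if (!above[ids[1L]] || length(ids) < min_len) next
    s <- sgn[ids[1L]]
    x <- (ids - 1L) * dt
    y <- log(abs(fs[ids]))
    m <- length(ids)
    # prefix sums for O(1) window regression
    cx <- cumsum(x); cy <- cumsum(y)
    cxx <- cumsum(x * x); cxy <- cumsum(x * y); cyy <- cumsum(y * y)
    wstat <- function(i, j) {   # 1-based within run, inclusive
      k <- j - i + 1
      sx <- cx[j] - if (i > 1) cx[i - 1] else 0
      sy <- cy[j] - if (i > 1) cy[i - 1] else 0
      sxx <- cxx[j] - if (i > 1) cxx[i - 1] else 0
      sxy <- cxy[j] - if (i > 1) cxy[i - 1] else 0
      syy <- cyy[j] - if (i > 1) cyy[i - 1] else 0
      vx <- sxx - sx * sx / k
      vy <- syy - sy * sy / k
      cvxy <- sxy - sx * sy / k
      b <- if (vx > 0) cvxy / vx else 0
      a <- (sy - b * sx) / k
      r2 <- if (vy > 1e-12) max(0, min(1, cvxy^2 / (vx * vy))) else 0
      sse <- max(0, vy - if (vx > 0) cvxy^2 / vx else 0)
      list(a = a, b = b, r2 = r2, rmse = sqrt(sse / k))
    }
    ok_window <- function(i, j) {
      w <- wstat(i, j)
      w$b < 0 && -1 / w$b <= cfg$max_tau_s &&
        (w$r2 >= cfg$decay_r2_thresh || w$rmse <= cfg$decay_log_rmse_tol)
    }
    i <- 1L
    while (i + min_len - 1L <= m) {
      j <- i + min_len - 1L
      if (!ok_window(i, j)) { i <- i + max(1L, min_len %/% 4L); next }
      # grow the segment while new samples track the fitted exponential;
      # a sustained one-sided (positive) residual is an emerging effort,
      # and the segment is trimmed back to where it began
      pos_run <- 0L
      repeat {
        if (j >= m) break
        w <- wstat(i, j)
        pred <- s * exp(w$a + w$b * x[j + 1L])
        resid <- fs[ids[j + 1L]] - pred
        if (abs(resid) > tol) break
        if (resid > 0.4 * tol) {
          pos_run <- pos_run + 1L
          if (pos_run >= 5L) { j <- j - pos_run + 1L; break }
        } else pos_run <- 0L
        if (!ok_window(i, j + 1L)) break
        j <- j + 1L
      }
      w <- wstat(i, j)
      segs[[length(segs) + 1L]] <- data.frame(
        start_s = t0 + x[i], end_s = t0 + x[j],
        tau_s = -1 / w$b,
        amplitude = scale * exp(w$a + w$b * x[i]),
        fit_r2 = w$r2,
        phase = if (s > 0) "inspiratory" else "expiratory",
        sign = s, log_a = w$a + log(scale), log_b = w$b,
        stringsAsFactors = FALSE)
      i <- j + 1L
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else data.frame(
    start_s = numeric(), end_s = numeric(), tau_s = numeric(),
    amplitude = numeric(), fit_r2 = numeric(), phase = character(),
    sign = numeric(), log_a = numeric(), log_b = numeric(),
    stringsAsFactors = FALSE)
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("decay_segments", "data.frame")
  out
}

## evaluate the extrapolated exponential of segment `seg` (one row) at
## times tt (absolute seconds, with the segment's own t0 baked in)
decay_extrapolate <- function(seg, tt, t0 = 0) {
  seg$sign * exp(seg$log_a + seg$log_b * (tt - t0))
}

## refit the segment's exponential on the portion of it nearest the
## extrapolation zone, to minimize extrapolation bias: `side = "end"`
## anchors on the last `anchor_s` of the segment (forward
## extrapolation), `side = "start"` on the first (backward).
decay_local_refit <- function(seg, tt, fs, t0, anchor_s = 0.5,
                              side = c("end", "start")) {
  side <- match.arg(side)
  win <- if (side == "end")
    c(max(seg$start_s, seg$end_s - anchor_s), seg$end_s)
  else c(seg$start_s, min(seg$end_s, seg$start_s + anchor_s))
  idx <- which(tt >= win[1L] & tt <= win[2L] & seg$sign * fs > 1e-6)
  if (length(idx) < 5L) return(seg)
  y <- log(seg$sign * fs[idx]); xx <- tt[idx] - t0
  fit <- stats::lm.fit(cbind(1, xx), y)
  b <- fit$coefficients[2L]
  if (!is.finite(b) || b >= 0) return(seg)
  seg$log_a <- fit$coefficients[1L]; seg$log_b <- b
  seg
}

#' Detect ventilator inspiratory phases from airway pressure
#'
#' The machine inspiratory start is the onset of a sustained
#' pressurization above the running expiratory baseline; the machine
#' inspiratory end is the onset of the sustained depressurization back
#' toward that baseline.
#'
#' @param paw airway-pressure series (cmH2O).
#' @param sample_rate sampling rate (Hz).
#' @param cfg a [wave_config].
#' @param t0 time of the first sample (s).
#' @return A data.frame of class `machine_breaths` with `ti_start_s`,
#'   `ti_end_s` and `peak_paw`.
#' @export
detect_machine_phases <- function(paw, sample_rate, cfg = wave_config(),
                                  t0 = 0) {
  if (any(!is.finite(paw))) abort_argument("paw must be finite")
  n <- length(paw)
  dt <- 1 / sample_rate
  ps <- moving_average(paw, round(0.03 * sample_rate))
  base <- as.numeric(stats::quantile(ps, 0.1))
  top <- as.numeric(stats::quantile(ps, 0.9))
  empty <- data.frame(ti_start_s = numeric(), ti_end_s = numeric(),
                      peak_paw = numeric())
  class(empty) <- c("machine_breaths", "data.frame")
  if (top - base < cfg$paw_rise_thresh) return(empty)
  mid <- (base + top) / 2
  hi <- ps > mid
  edges <- diff(hi)
  ups <- which(edges == 1L) + 1L
  downs <- which(edges == -1L) + 1L
  if (!length(ups)) return(empty)

  onset_of_rise <- function(u) {
    lo <- max(1L, u - as.integer(2 / dt))
    pre <- ps[lo:u]; pre <- pre[pre < mid]
    b <- if (length(pre)) stats::median(pre) else base
    j <- u
    while (j > 1L && ps[j - 1L] > b + 0.15 && ps[j - 1L] < ps[j]) j <- j - 1L
    # last sample at/below the local baseline, then the rise begins
    while (j > 1L && ps[j - 1L] > b + 0.15) j <- j - 1L
    j
  }
  onset_of_fall <- function(v) {
    lo <- max(1L, v - as.integer(1.5 / dt))
    pre <- ps[lo:v]; pre <- pre[pre > mid]
    p <- if (length(pre)) as.numeric(stats::quantile(pre, 0.9)) else top
    j <- v
    while (j > 1L && ps[j - 1L] < p - 0.15 && ps[j - 1L] > ps[j]) j <- j - 1L
    while (j > 1L && ps[j - 1L] < p - 0.15) j <- j - 1L
    j
  }

  rows <- list()
  for (u in ups) {
    v <- downs[downs > u]
    if (!length(v)) break
    v <- v[1L]
    i0 <- onset_of_rise(u); i1 <- onset_of_fall(v)
    if (i1 <= i0) next
    rows[[length(rows) + 1L]] <- data.frame(
      ti_start_s = t0 + (i0 - 1L) * dt, ti_end_s = t0 + (i1 - 1L) * dt,
      peak_paw = max(paw[i0:min(n, v)]))
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  if (nrow(out) > 1L)
    out <- out[c(TRUE, diff(out$ti_start_s) > 0), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("machine_breaths", "data.frame")
  out
}

## representative time constant of expiratory decay segments (NA if
## none). Short transition segments (relaxation tails) carry biased
## apparent time constants, so prefer segments of substantial duration.
expiratory_tau_of <- function(decays) {
  ex <- decays[decays$phase == "expiratory", , drop = FALSE]
  if (!nrow(ex)) return(NA_real_)
  long <- ex$end_s - ex$start_s >= 0.4
  stats::median(if (any(long)) ex$tau_s[long] else ex$tau_s)
}

## is a decay segment a credible passive phase? A passive decay of
## either phase must carry the respiratory system's own time constant:
## effort-rise artifacts masquerade as fast decays, relaxation tails as
## slow ones, and both are excluded by the consistency check.
segment_qualifies <- function(seg, tau_exp, cfg) {
  if (is.na(tau_exp)) return(TRUE)
  ratio <- seg$tau_s / tau_exp
  ratio >= cfg$tau_consistency[1L] && ratio <= cfg$tau_consistency[2L]
}

qualifying_segments <- function(decays, cfg) {
  tau_exp <- expiratory_tau_of(decays)
  if (!nrow(decays)) return(decays)
  ok <- vapply(seq_len(nrow(decays)), function(i)
    segment_qualifies(decays[i, ], tau_exp, cfg), logical(1))
  decays[ok, , drop = FALSE]
}

#' Detect effort onsets (wave Ti-start)
#'
#' An onset is declared where (a) flow exceeds the value extrapolated
#' from the preceding exponential-decay segment by at least
#' `flow_deviation_thresh` for at least `flow_deviation_sustain_s`
#' (the sudden positive deflection interrupting a passive decay), or
#' (b) Paw falls at least `paw_drop_thresh` below a stable local
#' baseline during the expiratory phase. When both rules fire within
#' one effort window the earlier time wins. Flow deviations caused by
#' the ventilator's own pressurization are excluded by bounding each
#' decay's extrapolation zone at the next machine inspiratory start.
#'
#' @param rec a [vent_recording].
#' @param decays segments from [detect_decay_segments] (computed from
#'   `rec` if `NULL`).
#' @param machine_breaths machine phases from [detect_machine_phases]
#'   (computed from `rec` if `NULL`).
#' @param cfg a [wave_config].
#' @return Numeric vector of onset times (s).
#' @export
detect_wave_ti_start <- function(rec, decays = NULL, machine_breaths = NULL,
                                 cfg = wave_config()) {
  ## footpoint of a rising deviation: muscle force develops smoothly
  ## from zero slope, so the early deviation grows quadratically and
  ## sqrt(dev) is linear in t; extrapolating it to zero locates the
  ## onset below the detection threshold.
  footpoint <- function(tvec, dev, jb, hit, wall = Inf) {
    t_b <- tvec[jb]
    hi <- min(length(dev), hit + as.integer(0.1 * rec$sample_rate))
    span <- jb:hi
    # the ventilator's own pressurization wall is not part of the
    # effort's rise; fit only what precedes it
    span <- span[dev[span] <= 4 * cfg$flow_deviation_thresh &
                   tvec[span] < wall]
    if (length(span) < 4L) return(t_b)
    y <- sqrt(pmax(dev[span], 0))
    z <- tvec[span] - t_b               # centered for conditioning
    fit <- stats::lm.fit(cbind(1, z), y)
    b <- fit$coefficients[2L]
    if (!is.finite(b) || b <= 0) return(t_b)
    root <- t_b - fit$coefficients[1L] / b
    # conservative refinement: shave at most 80 ms off the backtracked
    # point, never move it later
    if (root < t_b - 0.08 || root > t_b) t_b else root
  }
  if (is.null(decays))
    decays <- detect_decay_segments(rec$flow, rec$sample_rate, cfg, rec$t0)
  if (is.null(machine_breaths))
    machine_breaths <- detect_machine_phases(rec$paw, rec$sample_rate, cfg,
                                             rec$t0)
  tt <- rec_time(rec)
  dt <- 1 / rec$sample_rate
  scale <- if (cfg$relative_thresholds) flow_scale(rec$flow) else 1
  fs <- moving_average(rec$flow, round(cfg$smooth_s * rec$sample_rate)) / scale
  thr <- cfg$flow_deviation_thresh
  sustain <- max(1L, as.integer(round(cfg$flow_deviation_sustain_s *
                                        rec$sample_rate)))
  onsets <- numeric(0)
  rules <- character(0)

  tau_exp <- expiratory_tau_of(decays)

  ## quiescent lead-in: before any decay segment or machine breath the
  ## passive expectation is zero flow, and a sustained positive
  ## deflection from it is an effort
  lead_end <- min(c(decays$start_s, machine_breaths$ti_start_s,
                    tt[length(tt)]))
  idx <- which(tt <= lead_end + cfg$flow_deviation_sustain_s + 0.2)
  if (length(idx) >= sustain) {
    hit <- first_sustained(fs[idx] >= thr, sustain)
    if (!is.na(hit) && tt[idx[hit]] <= lead_end) {
      j <- hit
      while (j > 1L && fs[idx[j - 1L]] > 0.1 * thr) j <- j - 1L
      wall <- if (nrow(machine_breaths)) machine_breaths$ti_start_s[1L] - 0.02
        else Inf
      onsets <- c(onsets, max(footpoint(tt[idx], fs[idx], j, hit, wall),
                              tt[idx[hit]] - 0.18))
      rules <- c(rules, "lead")
    }
  }

  ## rule (a): deviation from the extrapolated decay; only segments that
  ## are credible passive phases serve as extrapolation sources, and
  ## only such segments mark the resumption of passivity
  qsegs <- qualifying_segments(decays, cfg)
  for (si in seq_len(nrow(qsegs))) {
    seg <- qsegs[si, ]
    ## the region-growing fit can absorb the first ~100 ms of a weak
    ## effort (its flow contribution is below the growth tolerance) and
    ## bend the fitted exponential; anchor the extrapolation on the
    ## segment body excluding the tail and re-scan from inside the tail
    seg_len <- seg$end_s - seg$start_s
    tail_back <- min(0.3, max(0, seg_len - 0.25))
    core <- seg
    core$end_s <- seg$end_s - tail_back
    zone_start <- core$end_s + dt
    nxt_machine <- machine_breaths$ti_start_s[
      machine_breaths$ti_start_s > seg$end_s + 1e-9]
    nxt_seg <- qsegs$start_s[qsegs$start_s > seg$end_s + 1e-9]
    ## the extrapolation horizon is bounded to limit drift, except when
    ## the prediction has already decayed below the amplitude floor (the
    ## passive expectation is then simply zero flow, valid indefinitely)
    ext_cap <- seg$end_s + cfg$max_extrap_s
    if (abs(decay_extrapolate(seg, ext_cap, rec$t0)) < cfg$amplitude_floor)
      ext_cap <- Inf
    zone_end <- min(c(ext_cap, nxt_machine, tt[length(tt)]))
    # a crossing that begins at/after the next decay segment is just
    # passivity resuming (possibly with a different apparent tau)
    if (length(nxt_seg)) zone_end <- min(zone_end, nxt_seg[1L] - 0.05)
    ## the deviation run may continue past the zone (e.g. into the
    ## pressurization it triggers); only the crossing must begin inside
    idx <- which(tt >= zone_start - 1e-9 &
                   tt <= zone_end + cfg$flow_deviation_sustain_s + 0.2 + 1e-9)
    if (length(idx) < sustain) next
    segl <- decay_local_refit(core, tt, fs * scale, rec$t0, side = "end")
    pred <- decay_extrapolate(segl, tt[idx], rec$t0) / scale
    dev <- fs[idx] - pred
    dev <- detrend_passive(dev, tt[idx], rec$sample_rate, thr)
    hit <- first_sustained(dev >= thr, sustain)
    if (is.na(hit) || tt[idx[hit]] > zone_end) next
    # backtrack to where the deviation emerged from the noise
    j <- hit
    while (j > 1L && dev[j - 1L] > 0.1 * thr) j <- j - 1L
    wall <- nxt_machine[nxt_machine > tt[idx[j]]]
    wall <- if (length(wall)) wall[1L] - 0.02 else Inf
    onsets <- c(onsets, max(footpoint(tt[idx], dev, j, hit, wall),
                            tt[idx[hit]] - 0.18))
    rules <- c(rules, "flow_fwd")
  }

  ## rule (a'): efforts beginning before enough passive decay has
  ## accumulated ahead of them are caught against the next passive
  ## segment extrapolated backward: a sustained positive deviation that
  ## rises out of passivity inside the gap is an effort bump
  for (si in seq_len(nrow(qsegs))) {
    seg <- qsegs[si, ]
    lb <- seg$start_s - cfg$max_extrap_s
    prev_seg <- qsegs$end_s[qsegs$end_s < seg$start_s - 1e-9]
    if (length(prev_seg)) lb <- max(lb, prev_seg[length(prev_seg)] + dt)
    prev_ce <- machine_breaths$ti_end_s[machine_breaths$ti_end_s <
                                          seg$start_s - 1e-9]
    # skip the cycling transient, which is not yet a pure decay
    if (length(prev_ce)) lb <- max(lb, prev_ce[length(prev_ce)] + 0.15)
    idx <- which(tt >= lb - 1e-9 & tt < seg$start_s - 1e-9)
    if (length(idx) < sustain + 5L) next
    segl <- decay_local_refit(seg, tt, fs * scale, rec$t0, side = "start")
    pred <- decay_extrapolate(segl, tt[idx], rec$t0) / scale
    dev <- fs[idx] - pred
    dev <- detrend_passive(dev, tt[idx], rec$sample_rate, thr)
    hit <- first_sustained(dev >= thr, sustain)
    if (is.na(hit) || hit <= 5L) next
    # must rise out of passivity, not continue a preceding deviation
    pre <- dev[max(1L, hit - as.integer(0.15 * rec$sample_rate)):(hit - 1L)]
    if (min(pre) >= 0.5 * thr) next
    j <- hit
    while (j > 1L && dev[j - 1L] > 0.1 * thr) j <- j - 1L
    onsets <- c(onsets, max(footpoint(tt[idx], dev, j, hit),
                            tt[idx[hit]] - 0.18))
    rules <- c(rules, "flow_bwd")
  }

  ## rule (b): negative Paw deflection during stable expiratory Paw
  paw_s <- moving_average(rec$paw, round(cfg$smooth_s * rec$sample_rate))
  mb <- machine_breaths
  exp_windows <- if (nrow(mb)) {
    starts <- c(rec$t0, mb$ti_end_s)
    ends <- c(mb$ti_start_s, tt[length(tt)])
    data.frame(s = starts, e = ends)[ends - starts > 0.4, ]
  } else data.frame(s = rec$t0, e = tt[length(tt)])
  for (w in seq_len(nrow(exp_windows))) {
    idx <- which(tt >= exp_windows$s[w] + 0.1 & tt <= exp_windows$e[w])
    if (length(idx) < sustain) next
    b <- stats::median(paw_s[idx])
    stable <- diff(range(paw_s[idx[seq_len(min(length(idx),
      as.integer(0.2 / dt)))]])) <= 2 * cfg$paw_stable_band
    if (!stable) next
    drop <- b - paw_s[idx]
    hit <- first_sustained(drop >= cfg$paw_drop_thresh,
                           max(1L, sustain %/% 2L))
    if (is.na(hit)) next
    j <- hit
    while (j > 1L && drop[j - 1L] > 0.2 * cfg$paw_drop_thresh) j <- j - 1L
    onsets <- c(onsets, tt[idx[j]])
    rules <- c(rules, "paw")
  }

  ## merge: onsets belong to the same effort unless passivity (a
  ## qualifying decay segment) resumed between them; earliest wins
  if (!length(onsets)) return(numeric(0))
  ord <- order(onsets)
  onsets <- onsets[ord]; rules <- rules[ord]
  keep_i <- 1L
  for (k in seq_along(onsets)[-1L]) {
    last <- onsets[keep_i[length(keep_i)]]
    resumed <- any(qsegs$start_s > last & qsegs$start_s < onsets[k])
    if (onsets[k] - last > cfg$min_effort_s && resumed)
      keep_i <- c(keep_i, k)
  }
  rules <- rules[keep_i]
  onsets <- onsets[keep_i]

  ## suppress onsets that merely announce a passive (auto-triggered)
  ## inflation: a pure exponential decay during the whole inspiration
  ## indicates auto-triggering, not an effort
  if (nrow(machine_breaths)) {
    keep <- vapply(onsets, function(on) {
      j <- which(machine_breaths$ti_start_s > on &
                   machine_breaths$ti_start_s <= on + 1)
      if (!length(j)) return(TRUE)
      !is_passive_inflation(machine_breaths[j[1L], ], decays, rec, cfg)
    }, logical(1))
    onsets <- onsets[keep]; rules <- rules[keep]
  }
  attr(onsets, "rule") <- rules
  onsets
}

#' Detect the effort end (wave Ti-end) for one onset
#'
#' The effort end is pinpointed at the start of the first passive
#' exponential decay of flow after the onset, irrespective of flow
#' direction. The marker is refined by extrapolating the fitted
#' exponential backward from the segment and placing the end at the
#' midpoint of the transition between the effort-perturbed flow and the
#' passive decay (the 50% point of the residual), mirroring the
#' mid-relaxation convention of the esophageal reference. Inspiratory
#' decay segments qualify only when their time constant is consistent
#' with the recording's expiratory time constant (passivity check).
#'
#' @param rec a [vent_recording].
#' @param onset onset time (s) from [detect_wave_ti_start].
#' @param decays segments from [detect_decay_segments].
#' @param machine_breaths machine phases (used to bound the backward
#'   refinement at the machine cycling point).
#' @param cfg a [wave_config].
#' @param next_onset time of the following onset, if any; the end must
#'   precede it.
#' @return End time (s); raises a detection error if no qualifying
#'   decay segment exists before `next_onset`.
#' @export
detect_wave_ti_end <- function(rec, onset, decays, machine_breaths = NULL,
                               cfg = wave_config(), next_onset = Inf) {
  tt <- rec_time(rec)
  scale <- if (cfg$relative_thresholds) flow_scale(rec$flow) else 1
  fs <- moving_average(rec$flow, round(cfg$smooth_s * rec$sample_rate)) / scale
  qsegs <- qualifying_segments(decays, cfg)
  cand <- which(qsegs$start_s > onset + 0.05 & qsegs$start_s < next_onset)
  # an inspiratory end marker must be an unambiguous exponential
  # (strict fit), not a shallow stretch admitted by the RMSE gate
  cand <- cand[qsegs$phase[cand] == "expiratory" |
                 qsegs$fit_r2[cand] >= cfg$decay_r2_thresh]
  seg <- if (length(cand)) qsegs[cand[1L], ] else NULL
  if (is.null(seg))
    abort_detection(sprintf(
      "no passive decay segment found after onset at %.2f s", onset))

  ## backward refinement: 50% point of the residual over the extrapolated decay
  floor_t <- onset
  if (!is.null(machine_breaths) && nrow(machine_breaths)) {
    if (seg$phase == "expiratory") {
      ce <- machine_breaths$ti_end_s[machine_breaths$ti_end_s > onset &
                                       machine_breaths$ti_end_s < seg$start_s]
      if (length(ce)) floor_t <- max(floor_t, ce[length(ce)])
    } else {
      cs <- machine_breaths$ti_start_s[machine_breaths$ti_start_s <= seg$start_s]
      if (length(cs)) floor_t <- max(floor_t, cs[length(cs)] + 0.1)
    }
  }
  idx <- which(tt >= floor_t - 1e-9 & tt <= seg$start_s + 1e-9)
  if (length(idx) < 3L) return(seg$start_s)
  if (seg$phase == "inspiratory") {
    # start no earlier than the peak of the effort-driven flow
    pk <- idx[which.max(fs[idx])]
    idx <- idx[idx >= pk]
    if (length(idx) < 3L) return(seg$start_s)
  }
  r <- fs[idx] - decay_extrapolate(seg, tt[idx], rec$t0) / scale
  rmax <- max(r)
  if (rmax < cfg$flow_deviation_thresh) return(seg$start_s)
  ## When the marker derives from the expiratory decay after a machine
  ## cycling, distinguish two regimes by the residual remaining once
  ## the cycling release transient has passed:
  ##   * early cycling: the effort peak sits at/after the cycling
  ##     point, the residual is still large, and the midpoint rule on
  ##     the observed residual applies;
  ##   * relaxation straddling the cycling point: the midpoint is
  ##     hidden inside the machine inspiration. The flow still carries
  ##     the relaxation-start kink (the sharp slope minimum where the
  ##     muscle begins to relax) and the relaxation time constant (the
  ##     decay rate of the post-cycling residual), which identify the
  ##     mid-relaxation time as kink + tau_relax * log(2).
  if (seg$phase == "expiratory" && floor_t > onset + 0.1) {
    post_i <- which(tt[idx] >= floor_t + 0.15)
    r_post <- if (length(post_i)) max(r[post_i]) else 0
    if (r_post >= 6 * cfg$flow_deviation_thresh) {
      ## early cycling: the effort is still active after the cycling
      ## release, its residual peak is visible post-transient, and the
      ## midpoint of its relaxation marks the effort end
      r2 <- r[post_i]
      cross2 <- which(r2 >= 0.5 * max(r2))
      j2 <- cross2[length(cross2)]
      if (j2 < length(post_i)) {
        ra <- r2[j2]; rb <- r2[j2 + 1L]
        frac <- if (ra != rb) (ra - 0.5 * max(r2)) / (ra - rb) else 0
        return(tt[idx[post_i[j2]]] +
                 frac * (tt[idx[post_i[j2 + 1L]]] - tt[idx[post_i[j2]]]))
      }
      return(tt[idx[post_i[j2]]])
    }
    if (TRUE) {
      dfs <- smooth_deriv(fs, rec$sample_rate, cfg$smooth_s)
      # exclude the cycling release edge (and its smoothing spread)
      kidx <- which(tt >= onset + 0.25 & tt <= floor_t - 0.08)
      if (length(kidx) >= 5L) {
        k_at <- which.min(dfs[kidx])
        # a slope minimum on the window edge is not a relaxation kink
        if (k_at <= 2L || k_at >= length(kidx) - 1L) return(tt[idx[1L]])
        tpk <- tt[kidx[k_at]]
        tau_r <- 0.1
        fit_i <- which(tt[idx] >= floor_t + 0.12 & r > 0.01)
        if (length(fit_i) >= 5L) {
          f <- stats::lm.fit(cbind(1, tt[idx[fit_i]] - floor_t),
                             log(r[fit_i]))
          b1 <- f$coefficients[2L]
          if (is.finite(b1) && b1 < 0) tau_r <- min(max(-1 / b1, 0.03), 0.3)
        }
        end_k <- tpk + tau_r * log(2)
        if (end_k > onset + cfg$min_effort_s && end_k <= seg$start_s)
          return(end_k)
      }
      return(tt[idx[1L]])
    }
  }
  cross <- which(r >= 0.5 * rmax)
  if (!length(cross)) return(seg$start_s)
  j <- cross[length(cross)]
  if (j < length(idx)) {
    # linear interpolation of the 50% crossing
    r1 <- r[j]; r2 <- r[j + 1L]
    frac <- if (r1 != r2) (r1 - 0.5 * rmax) / (r1 - r2) else 0
    tt[idx[j]] + frac * (tt[idx[j + 1L]] - tt[idx[j]])
  } else tt[idx[j]]
}

#' Is a machine breath a passive inflation?
#'
#' `TRUE` when a flow decay segment covers at least
#' `passive_cover_frac` of the interval from the peak inspiratory flow
#' to the machine inspiratory end: a pure exponential decay during the
#' whole inspiration indicates auto-triggering.
#'
#' @param breath one row of a `machine_breaths` data.frame (or a list
#'   with `ti_start_s`, `ti_end_s`).
#' @param decays segments from [detect_decay_segments].
#' @param rec the [vent_recording] (used to locate the peak flow).
#' @param cfg a [wave_config].
#' @return Logical.
#' @export
is_passive_inflation <- function(breath, decays, rec, cfg = wave_config()) {
  t1 <- breath$ti_start_s; t2 <- breath$ti_end_s
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1) return(FALSE)
  tt <- rec_time(rec)
  idx <- which(tt >= t1 & tt <= t2)
  if (length(idx) < 3L) return(FALSE)
  t_peak <- tt[idx[which.max(rec$flow[idx])]]
  span <- t2 - t_peak
  if (span <= 0.05) return(FALSE)
  qsegs <- qualifying_segments(decays, cfg)
  if (!nrow(qsegs)) return(FALSE)
  s <- pmax(qsegs$start_s, t_peak)
  e <- pmin(qsegs$end_s, t2)
  ok <- e > s
  if (!any(ok)) return(FALSE)
  ## a passive inflation decays from its peak onward: the decay must
  ## begin promptly at the peak. A breath triggered by a real effort
  ## shows the decay only once the effort releases.
  prompt <- min(s[ok]) <= t_peak + 0.1
  if (!prompt) return(FALSE)
  cover <- sum(pmax(0, e - s)) / span
  if (cover >= cfg$passive_cover_frac) return(TRUE)
  ## cardiogenic oscillations fragment the segmentation; when the
  ## measured ripple is large, accept a prompt but fragmented decay
  fs <- moving_average(rec$flow, round(0.21 * rec$sample_rate))
  bidx <- which(tt >= t1 & tt <= t2)
  ripple <- as.numeric(stats::quantile(abs(rec$flow[bidx] - fs[bidx]), 0.9))
  ripple > 1.2 * cfg$flow_deviation_thresh && cover >= 0.5
}

#' Detect patient efforts from flow and airway pressure
#'
#' Full waveform-method pipeline: decay segmentation, machine-phase
#' detection, onset detection and end detection, returning a sorted,
#' non-overlapping effort table. Efforts whose end cannot be located
#' are dropped with a warning; efforts shorter than `min_effort_s` and
#' partial events at the recording edges are discarded.
#'
#' @param rec a [vent_recording].
#' @param cfg a [wave_config].
#' @return An [event_table] with source `"waveform"`. The decay
#'   segments and machine breaths used are attached as attributes
#'   `"decays"` and `"machine_breaths"`.
#' @export
detect_efforts_waveform <- function(rec, cfg = wave_config()) {
  decays <- detect_decay_segments(rec$flow, rec$sample_rate, cfg, rec$t0)
  machine <- detect_machine_phases(rec$paw, rec$sample_rate, cfg, rec$t0)
  onsets <- detect_wave_ti_start(rec, decays, machine, cfg)
  t_end_rec <- rec$t0 + rec_duration(rec)
  starts <- ends <- numeric(0)
  for (i in seq_along(onsets)) {
    nxt <- if (i < length(onsets)) onsets[i + 1L] else Inf
    e <- tryCatch(
      detect_wave_ti_end(rec, onsets[i], decays, machine, cfg, nxt),
      ventwave_detection_error = function(err) {
        warning(conditionMessage(err), call. = FALSE)
        NA_real_
      })
    if (is.na(e)) next
    e <- min(e, nxt - 1 / rec$sample_rate)
    if (e - onsets[i] < cfg$min_effort_s) next
    if (onsets[i] < rec$t0 + 0.25 || e > t_end_rec - 0.25) next  # edge events
    starts <- c(starts, onsets[i]); ends <- c(ends, e)
  }
  out <- event_table("effort", starts, ends, "waveform")
  attr(out, "decays") <- decays
  attr(out, "machine_breaths") <- machine
  out
}
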