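# Shared fixtures: small deterministic recordings and matching helpers.

# nearest-start matching of detected events against truth; returns
# per-truth start/end deltas (NA when undetected)
match_to_truth <- function(truth, detected, tol = 0.3) {
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
  list(d_start = ds, d_end = de, n_unmatched = sum(!used))
}

# a small clean synchronous simulation reused across files
sim_synchronous <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_recording(scenario_preset("synchronous", seed = 1,
                                                   duration_s = 30))
    cache
  }
})

# recording with an analytic exponential expiratory decay interrupted
# by a half-sine bump (an ineffective effort in miniature)
flow_decay_with_bump <- function(rate = 100, tau = 0.5, a0 = -0.8,
                                 t_bump = 0.6, bump_amp = 0.25,
                                 bump_len = 0.4) {
  t <- seq(0, 2, by = 1 / rate)
  flow <- a0 * exp(-t / tau)
  in_bump <- t >= t_bump & t <= t_bump + bump_len
  flow[in_bump] <- flow[in_bump] +
    bump_amp * sin(pi * (t[in_bump] - t_bump) / bump_len)
  list(t = t, flow = flow, clean = a0 * exp(-t / tau))
}
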