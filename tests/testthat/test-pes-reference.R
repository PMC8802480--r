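test_that("Pes onsets land on the simulated effort onsets", {
  sim <- sim_synchronous()
  truth <- sim$truth$efforts
  on <- detect_pes_ti_start(sim$recording)
  expect_equal(length(on), nrow(truth))
  for (i in seq_len(nrow(truth)))
    expect_lt(min(abs(on - truth$start_s[i])), 0.08)
})

test_that("cardiac oscillation below the drop threshold yields no onsets", {
  t <- seq(0, 20, by = 0.01)
  rec <- vent_recording(flow = rep(0, length(t)),
                        paw = rep(5, length(t)),
                        pes = 8 + 0.5 * sin(2 * pi * 1.2 * t),
                        sample_rate = 100)
  cfg <- pes_config(onset_min_drop = 1)
  expect_equal(length(detect_pes_ti_start(rec, cfg)), 0)
})

test_that("two well-separated efforts give exactly two ordered onsets", {
  sc <- sim_scenario(efforts = list(rate_per_min = 20, peak_pmus = 10,
                                    jitter_s = 0, start_s = 2),
                     duration_s = 7.5, cardiac_noise_amp = 0, seed = 3)
  sim <- simulate_recording(sc)
  on <- detect_pes_ti_start(sim$recording)
  expect_equal(length(on), 2)
  expect_true(on[1] < on[2])
})

test_that("the effort end sits at the midpoint of the fast Pes recovery", {
  sim <- sim_synchronous()
  truth <- sim$truth$efforts
  cfg <- pes_config()
  on <- detect_pes_ti_start(sim$recording, cfg)
  e2 <- detect_pes_ti_end(sim$recording, on[2], cfg, next_onset = on[3])
  expect_lt(abs(e2 - truth$end_s[2]), 0.08)
})

test_that("a symmetric triangular dip ends at the 50% recovery point", {
  t <- seq(0, 10, by = 0.01)
  pes <- rep(8, length(t))
  down <- t >= 4 & t <= 5
  up <- t > 5 & t <= 6
  pes[down] <- 8 - 4 * (t[down] - 4)
  pes[up] <- 4 + 4 * (t[up] - 5)
  rec <- vent_recording(flow = rep(0, length(t)), paw = rep(5, length(t)),
                        pes = pes, sample_rate = 100)
  end <- detect_pes_ti_end(rec, onset = 4)
  # brute-force scan of the sampled trace for the 50% recovery crossing
  nadir_i <- which.min(pes)
  target <- min(pes) + 0.5 * (8 - min(pes))
  bf <- t[nadir_i + which(pes[(nadir_i + 1):length(pes)] >= target)[1]]
  expect_lt(abs(end - bf), 0.05)
})

test_that("a monotonically falling Pes raises a detection error", {
  t <- seq(0, 5, by = 0.01)
  rec <- vent_recording(flow = rep(0, length(t)), paw = rep(5, length(t)),
                        pes = 10 - t, sample_rate = 100)
  expect_error(detect_pes_ti_end(rec, onset = 1),
               class = "ventwave_detection_error")
})

test_that("detection requires the Pes channel", {
  rec <- vent_recording(flow = c(0, 0.1, 0), paw = c(5, 6, 5),
                        sample_rate = 100)
  expect_error(detect_pes_ti_start(rec), class = "ventwave_capability_error")
  expect_error(detect_efforts_pes(rec), class = "ventwave_capability_error")
})

test_that("Pes detection is translation-equivariant", {
  sim <- sim_synchronous()
  rec <- sim$recording
  shifted <- rec
  shifted$t0 <- rec$t0 + 37.5
  ev <- suppressWarnings(detect_efforts_pes(rec))
  ev2 <- suppressWarnings(detect_efforts_pes(shifted))
  expect_equal(ev2$start_s, ev$start_s + 37.5, tolerance = 1e-9)
  expect_equal(ev2$end_s, ev$end_s + 37.5, tolerance = 1e-9)
})

test_that("Pes efforts are sorted, non-overlapping and inside the recording", {
  for (p in c("synchronous", "obstructive", "ineffective")) {
    sim <- simulate_recording(scenario_preset(p, seed = 2, duration_s = 30))
    ev <- suppressWarnings(detect_efforts_pes(sim$recording))
    expect_true(all(ev$end_s > ev$start_s))
    if (nrow(ev) > 1)
      expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))
    expect_true(all(ev$start_s >= 0 & ev$end_s <= rec_duration(sim$recording)))
  }
  # a recording with zero efforts yields an empty table
  auto <- simulate_recording(scenario_preset("autotrigger", seed = 1))
  expect_equal(nrow(suppressWarnings(detect_efforts_pes(auto$recording))), 0)
})

test_that("Pes reference recovers simulated efforts across a parameter sweep", {
  n_truth <- n_det <- n_ok <- 0
  for (peak in c(4, 10, 16)) for (tau in c(0.3, 0.9)) {
    sc <- sim_scenario(
      mechanics = mechanics(resistance_R = 10, compliance_C = tau / 10),
      efforts = list(rate_per_min = 15, peak_pmus = peak, rise_time_s = 0.7,
                     relax_tau_s = 0.1, jitter_s = 0.05, start_s = 1.5),
      duration_s = 20, noise_sd_pes = 0.1, seed = 11 + peak)
    sim <- simulate_recording(sc)
    ev <- suppressWarnings(detect_efforts_pes(sim$recording))
    m <- match_to_truth(sim$truth$efforts, ev)
    n_truth <- n_truth + nrow(sim$truth$efforts)
    n_det <- n_det + sum(!is.na(m$d_start))
    n_ok <- n_ok + sum(abs(m$d_start) <= 0.1 & abs(m$d_end) <= 0.1,
                       na.rm = TRUE)
  }
  expect_gte(n_det / n_truth, 0.99)
  expect_gte(n_ok / n_det, 0.95)
})
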