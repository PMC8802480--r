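test_that("a pure exponential flow yields one long decay segment with the right tau", {
  t <- seq(0, 2, by = 0.01)
  flow <- -0.8 * exp(-t / 0.5)
  seg <- detect_decay_segments(flow, 100)
  expect_gte(nrow(seg), 1)
  main <- seg[which.max(seg$end_s - seg$start_s), ]
  expect_gte((main$end_s - main$start_s) / 2, 0.9 * 0.5 * log(0.8 / 0.02) / 2)
  expect_equal(main$tau_s, 0.5, tolerance = 0.02)
  expect_equal(main$phase, "expiratory")
})

test_that("an effort bump splits the decay at the interruption point", {
  fx <- flow_decay_with_bump()
  seg <- detect_decay_segments(fx$flow, 100)
  expect_gte(nrow(seg), 2)
  # brute-force oracle: the first sample whose deviation from the true
  # exponential exceeds the deviation threshold
  bf_boundary <- fx$t[which(fx$flow - fx$clean > 0.05)[1]]
  expect_lt(abs(seg$end_s[1] - bf_boundary), 0.06)
  expect_gt(seg$start_s[2], seg$end_s[1])
})

test_that("zero or constant flow produces no decay segments", {
  expect_equal(nrow(detect_decay_segments(rep(0, 500), 100)), 0)
  expect_equal(nrow(detect_decay_segments(rep(0.5, 500), 100)), 0)
})

test_that("machine phases are located at pressurization and depressurization", {
  t <- seq(0, 4, by = 0.01)
  paw <- ifelse(t >= 1 & t < 2, 15, 5)
  mb <- detect_machine_phases(paw, 100)
  expect_equal(nrow(mb), 1)
  expect_lt(abs(mb$ti_start_s - 1), 0.02)
  expect_lt(abs(mb$ti_end_s - 2), 0.02)

  # first-order pressurization: onset found by the detector agrees with
  # a brute-force first-crossing search on the analytic curve
  paw2 <- 5 + 10 * (1 - exp(-pmax(0, t - 1) / 0.15)) * (t < 2.5) +
    10 * exp(-pmax(0, t - 2.5) / 0.05) * (t >= 2.5)
  mb2 <- detect_machine_phases(paw2, 100)
  bf_onset <- t[which(paw2 > 5 + 0.15)[1]]
  expect_lt(abs(mb2$ti_start_s[1] - bf_onset), 0.02)

  expect_equal(nrow(detect_machine_phases(rep(7, 500), 100)), 0)
})

test_that("waveform onsets match simulated effort onsets", {
  sim <- sim_synchronous()
  truth <- sim$truth$efforts
  on <- detect_wave_ti_start(sim$recording)
  m <- match_to_truth(truth, data.frame(start_s = as.numeric(on),
                                        end_s = as.numeric(on) + 1))
  expect_gte(mean(!is.na(m$d_start)), 0.99)
  expect_lt(max(abs(m$d_start), na.rm = TRUE), 0.1)
})

test_that("auto-triggered breaths produce machine breaths but no efforts", {
  sim <- simulate_recording(scenario_preset("autotrigger", seed = 1))
  ev <- suppressWarnings(detect_efforts_waveform(sim$recording))
  mb <- detect_machine_phases(sim$recording$paw, sim$recording$sample_rate)
  expect_equal(nrow(ev), 0)
  expect_gt(nrow(mb), 3)
})

test_that("passive inflations are recognized and active ones are not", {
  auto <- simulate_recording(scenario_preset("autotrigger", seed = 1))
  dec_a <- detect_decay_segments(auto$recording$flow,
                                 auto$recording$sample_rate)
  mb_a <- detect_machine_phases(auto$recording$paw,
                                auto$recording$sample_rate)
  expect_true(any(sapply(seq_len(nrow(mb_a)), function(j)
    is_passive_inflation(mb_a[j, ], dec_a, auto$recording))))

  sync <- sim_synchronous()
  dec_s <- detect_decay_segments(sync$recording$flow, 100)
  mb_s <- detect_machine_phases(sync$recording$paw, 100)
  expect_false(any(sapply(seq_len(nrow(mb_s)), function(j)
    is_passive_inflation(mb_s[j, ], dec_s, sync$recording))))

  # degenerate zero-length inspiration
  expect_false(is_passive_inflation(
    data.frame(ti_start_s = 1, ti_end_s = 1), dec_s, sync$recording))
})

test_that("effort ends land at the start of the resumed passive decay", {
  sim <- sim_synchronous()
  ev <- suppressWarnings(detect_efforts_waveform(sim$recording))
  m <- match_to_truth(sim$truth$efforts, ev)
  expect_lt(max(abs(m$d_end), na.rm = TRUE), 0.1)
})

test_that("late and early cycling end markers stay within tolerance", {
  for (p in c("obstructive", "restrictive")) {
    sim <- simulate_recording(scenario_preset(p, seed = 1, duration_s = 30))
    ev <- suppressWarnings(detect_efforts_waveform(sim$recording))
    m <- match_to_truth(sim$truth$efforts, ev)
    expect_gte(mean(!is.na(m$d_start)), 0.99)
    expect_lt(stats::quantile(abs(m$d_end), 0.95, na.rm = TRUE), 0.1)
  }
})

test_that("waveform detection is translation-equivariant", {
  sim <- sim_synchronous()
  rec <- sim$recording
  shifted <- rec
  shifted$t0 <- rec$t0 + 12.25
  ev <- suppressWarnings(detect_efforts_waveform(rec))
  ev2 <- suppressWarnings(detect_efforts_waveform(shifted))
  # equivariant to within the sampling grid (floating-point boundary
  # membership can shift window contents by one sample)
  expect_equal(nrow(ev2), nrow(ev))
  expect_lt(max(abs(ev2$start_s - (ev$start_s + 12.25))), 0.015)
  expect_lt(max(abs(ev2$end_s - (ev$end_s + 12.25))), 0.015)
})

test_that("relative thresholds make detection invariant to flow rescaling", {
  sim <- sim_synchronous()
  rec <- sim$recording
  cfg <- wave_config(relative_thresholds = TRUE)
  scaled <- rec
  scaled$flow <- rec$flow * 3
  ev <- suppressWarnings(detect_efforts_waveform(rec, cfg))
  ev2 <- suppressWarnings(detect_efforts_waveform(scaled, cfg))
  expect_equal(ev2$start_s, ev$start_s, tolerance = 1e-9)
  expect_equal(ev2$end_s, ev$end_s, tolerance = 1e-9)
})

test_that("fitted expiratory decay tau matches the mechanics R*C", {
  sim <- sim_synchronous()   # R = 10, C = 0.05
  seg <- detect_decay_segments(sim$recording$flow, 100)
  ex <- seg[seg$phase == "expiratory" & seg$end_s - seg$start_s > 0.5, ]
  expect_gt(nrow(ex), 3)
  expect_lt(max(abs(ex$tau_s - 0.5) / 0.5), 0.05)
})

test_that("waveform efforts agree with Pes efforts and truth on clean data", {
  sim <- sim_synchronous()
  wv <- suppressWarnings(detect_efforts_waveform(sim$recording))
  ps <- suppressWarnings(detect_efforts_pes(sim$recording))
  truth <- sim$truth$efforts
  mw <- match_to_truth(truth, wv, tol = 0.3)
  mp <- match_to_truth(truth, ps, tol = 0.3)
  expect_true(all(abs(mw$d_start) <= 0.1, na.rm = TRUE))
  expect_true(all(abs(mp$d_start) <= 0.1, na.rm = TRUE))
  # pairwise waveform vs pes
  mwp <- match_to_truth(ps, wv, tol = 0.3)
  expect_true(all(abs(mwp$d_start) <= 0.15, na.rm = TRUE))
})
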