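test_that("a driveless, untriggerable scenario stays at rest", {
  sc <- sim_scenario(
    efforts = list(rate_per_min = 6, peak_pmus = 0),
    vent = vent_settings(flow_trigger = 10),   # unreachable threshold
    duration_s = 8, cardiac_noise_amp = 0, noise_sd_flow = 0,
    noise_sd_paw = 0, noise_sd_pes = 0, seed = 1)
  sim <- simulate_recording(sc)
  expect_true(all(abs(sim$state$flow) < 1e-12))
  expect_true(all(abs(sim$state$paw - 5) < 1e-9))
  expect_true(all(abs(sim$state$pes - sim$scenario$pes_baseline) < 1e-9))
  expect_equal(nrow(sim$truth$machine_breaths), 0)
})

test_that("passive inflation matches the single-compartment step response", {
  # a brief triggering twitch, then a passive lung: peak inspiratory
  # flow approaches PS/R and the subsequent decay carries tau = R*C
  R <- 10; C <- 0.05; PS <- 10
  sc <- sim_scenario(
    mechanics = mechanics(resistance_R = R, compliance_C = C),
    efforts = list(rate_per_min = 3, peak_pmus = 1.2, rise_time_s = 0.1,
                   relax_tau_s = 0.02, jitter_s = 0, start_s = 1),
    vent = vent_settings(pressure_support = PS, flow_trigger = 0.03,
                         pressurization_rise_s = 0.02,
                         expiratory_trigger_fraction = 0.05, max_ti_s = 3),
    duration_s = 8, cardiac_noise_amp = 0, noise_sd_flow = 0,
    noise_sd_paw = 0, noise_sd_pes = 0, seed = 1)
  sim <- simulate_recording(sc)
  st <- sim$state
  expect_equal(max(st$flow), PS / R, tolerance = 0.03)
  # log-linear fit over the mid decay of inspiratory flow
  pk <- which.max(st$flow)
  idx <- which(st$time > st$time[pk] + 0.3 & st$flow > 0.1)
  fit <- stats::lm(log(st$flow[idx]) ~ st$time[idx])
  expect_equal(-1 / unname(coef(fit)[2]), R * C, tolerance = 0.02)
})

test_that("recorded state satisfies the equation of motion to numerical precision", {
  for (p in c("synchronous", "obstructive", "autotrigger")) {
    sim <- simulate_recording(scenario_preset(p, seed = 2, duration_s = 20))
    expect_lt(max(abs(eom_residual(sim))), 1e-6)
  }
})

test_that("identical scenarios with identical seeds are bit-identical", {
  a <- simulate_recording(scenario_preset("obstructive", seed = 5,
                                          duration_s = 12))
  b <- simulate_recording(scenario_preset("obstructive", seed = 5,
                                          duration_s = 12))
  expect_identical(a$recording, b$recording)
  expect_identical(a$state, b$state)
  expect_identical(a$truth$efforts, b$truth$efforts)
  c <- simulate_recording(scenario_preset("obstructive", seed = 6,
                                          duration_s = 12))
  expect_false(identical(a$recording$flow, c$recording$flow))
})

test_that("volume is conserved over a closed breath", {
  sc <- sim_scenario(
    efforts = list(rate_per_min = 4, peak_pmus = 10, rise_time_s = 0.7,
                   relax_tau_s = 0.1, jitter_s = 0, start_s = 1),
    duration_s = 14, cardiac_noise_amp = 0, noise_sd_flow = 0,
    noise_sd_paw = 0, noise_sd_pes = 0, seed = 1)
  sim <- simulate_recording(sc)
  st <- sim$state
  # expiration is complete well before the recording ends (> 20 tau)
  expect_lt(abs(st$volume[nrow(st)]), 1e-3)
  # cumulative flow equals the volume state by construction
  expect_lt(abs(sum(st$flow[-nrow(st)]) / 100 - st$volume[nrow(st)]), 5e-3)
})

test_that("the effort train carries exact analytic ground truth", {
  sc <- sim_scenario(efforts = list(
    rate_per_min = 10, peak_pmus = 8, rise_time_s = 0.6, relax_tau_s = 0.1,
    jitter_s = 0, start_s = 1), duration_s = 12, seed = 1)
  train <- make_effort_train(sc)
  expect_equal(train$efforts$start_s[1], 1)
  expect_equal(train$efforts$end_s[1], 1 + 0.6 + 0.1 * log(2),
               tolerance = 1e-9)
  expect_true(all(train$pmus >= 0))

  # zero-amplitude efforts are excluded from truth
  sc0 <- sim_scenario(efforts = list(rate_per_min = 10, peak_pmus = 0,
                                     jitter_s = 0, start_s = 1),
                      duration_s = 12, seed = 1)
  expect_equal(nrow(make_effort_train(sc0)$efforts), 0)
})

test_that("a forced trigger delay strictly increases machine trigger latency", {
  starts <- sapply(c(0, 0.1, 0.25), function(d) {
    sc <- sim_scenario(
      efforts = list(rate_per_min = 6, peak_pmus = 10, jitter_s = 0,
                     start_s = 2),
      vent = vent_settings(forced_trigger_delay_s = d),
      duration_s = 8, cardiac_noise_amp = 0, noise_sd_flow = 0, seed = 1)
    simulate_recording(sc)$truth$machine_breaths$start_s[1]
  })
  expect_true(all(diff(starts) > 0))
})

test_that("presets reproduce their interaction phenotypes", {
  # restrictive mechanics with long efforts: early cycling
  restr <- simulate_recording(scenario_preset("restrictive", seed = 1))
  expect_true(any(restr$truth$classes$dti_end_s < -0.25, na.rm = TRUE))

  # obstructive mechanics with a low cycling threshold: late cycling
  # and ineffective efforts from dynamic hyperinflation
  obst <- simulate_recording(scenario_preset("obstructive", seed = 1))
  expect_true(any(obst$truth$classes$dti_end_s > 0.25, na.rm = TRUE))
  expect_true(any(obst$truth$classes$class == "ineffective"))

  # cardiogenic auto-triggering: machine breaths without any effort
  auto <- simulate_recording(scenario_preset("autotrigger", seed = 1))
  expect_equal(nrow(auto$truth$efforts), 0)
  expect_gt(nrow(auto$truth$machine_breaths), 3)

  expect_error(scenario_preset("nonsense"), class = "ventwave_argument_error")
})
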