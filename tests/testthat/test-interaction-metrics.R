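test_that("pairing classifies assisted, double-triggered, auto-triggered and ineffective", {
  efforts <- event_table("effort", 1.0, 1.8, "truth")
  machine <- data.frame(ti_start_s = 1.2, ti_end_s = 2.0)
  rec <- pair_events(efforts, machine)
  expect_equal(rec$class, "assisted")
  expect_equal(rec$dti_start_s, 0.2, tolerance = 1e-12)
  expect_equal(rec$dti_end_s, 0.2, tolerance = 1e-12)

  machine2 <- data.frame(ti_start_s = c(1.1, 1.5), ti_end_s = c(1.4, 2.0))
  rec2 <- pair_events(efforts, machine2)
  expect_equal(rec2$class, "double-triggered")
  expect_equal(rec2$n_machine, 2L)
  expect_equal(rec2$dti_start_s, 0.1, tolerance = 1e-12)
  expect_equal(rec2$dti_end_s, 0.2, tolerance = 1e-12)

  machine3 <- data.frame(ti_start_s = 3.0, ti_end_s = 4.0)
  rec3 <- pair_events(efforts, machine3)
  expect_setequal(rec3$class, c("ineffective", "auto-triggered"))

  # every effort and machine breath appears exactly once
  expect_equal(sum(rec3$n_machine), 1L)
  expect_equal(sum(!is.na(rec3$effort_start_s)), 1L)

  expect_error(
    pair_events(efforts, data.frame(ti_start_s = c(1, 1.5),
                                    ti_end_s = c(2, 2.5))),
    class = "ventwave_data_error")
})

test_that("minor-asynchrony flags follow the strict 250 ms convention", {
  rec <- pair_events(event_table("effort", c(1, 5, 9), c(2, 6, 10), "truth"),
                     data.frame(ti_start_s = c(1.3, 5.2, 9.25),
                                ti_end_s = c(1.7, 5.7, 9.75)))
  rec <- compute_delays(rec)
  expect_equal(rec$trigger_delay, c(TRUE, FALSE, FALSE))  # 0.3 / 0.2 / 0.25
  expect_equal(rec$early_cycling, c(TRUE, TRUE, FALSE))  # -0.25 is not early

  rec2 <- pair_events(event_table("effort", 1, 2, "truth"),
                      data.frame(ti_start_s = 1.2, ti_end_s = 1.7))
  rec2$dti_end_s <- -0.3
  expect_true(compute_delays(rec2)$early_cycling)
  rec2$dti_start_s <- 0.2; rec2$dti_end_s <- 0.2
  flags <- compute_delays(rec2)
  expect_false(flags$trigger_delay || flags$early_cycling || flags$late_cycling)

  auto_only <- pair_events(event_table(), data.frame(ti_start_s = 1,
                                                     ti_end_s = 2))
  expect_error(compute_delays(auto_only), class = "ventwave_contract_error")
})

test_that("asynchrony index and total asynchrony time follow their definitions", {
  # 8 assisted + 1 ineffective + 1 auto-triggered out of 10 -> 20%
  efforts <- event_table("effort", seq(0, 8), seq(0, 8) + 0.8, "truth")
  machine <- data.frame(ti_start_s = c(seq(0, 7) + 0.1, 20),
                        ti_end_s = c(seq(0, 7) + 0.9, 21))
  rec <- pair_events(efforts, machine)
  expect_equal(as.vector(table(rec$class)[c("assisted", "auto-triggered",
                                            "ineffective")]), c(8L, 1L, 1L))
  s <- interaction_summary(rec, 100)
  expect_equal(s$asynchrony_index_pct, 20)
  expect_equal(s$n_total, 10L)

  # worked arithmetic: sums of |dTi| plus event durations over time
  rec2 <- rec
  rec2$dti_start_s[rec2$class == "assisted"] <- 1.0 / 8
  rec2$dti_end_s[rec2$class == "assisted"] <- -1.5 / 8
  rec2$effort_end_s[rec2$class == "ineffective"] <-
    rec2$effort_start_s[rec2$class == "ineffective"] + 2.0
  rec2$machine_end_s[rec2$class == "auto-triggered"] <-
    rec2$machine_start_s[rec2$class == "auto-triggered"] + 0.5
  s2 <- interaction_summary(rec2, 100)
  expect_equal(s2$total_asynchrony_time_pct, 5.0, tolerance = 1e-12)
  expect_equal(sum(s2$component_times_s), s2$total_asynchrony_time_s)

  expect_error(interaction_summary(rec[0, ], 100),
               class = "ventwave_contract_error")
})

test_that("summary equals an independent per-breath accumulation oracle", {
  sim <- simulate_recording(scenario_preset("obstructive", seed = 1))
  rec <- pair_events(sim$truth$efforts, sim$truth$machine_breaths)
  s <- interaction_summary(rec, rec_duration(sim$recording))
  # independent accumulation, one breath at a time
  tot <- 0
  for (i in seq_len(nrow(rec))) {
    tot <- tot + switch(rec$class[i],
      "assisted" = ,
      "double-triggered" = abs(rec$dti_start_s[i]) + abs(rec$dti_end_s[i]),
      "ineffective" = rec$effort_end_s[i] - rec$effort_start_s[i],
      "auto-triggered" = rec$machine_end_s[i] - rec$machine_start_s[i])
  }
  expect_equal(s$total_asynchrony_time_s, tot, tolerance = 1e-9)
  n_major <- sum(rec$class != "assisted")
  expect_equal(s$asynchrony_index_pct, 100 * n_major / nrow(rec),
               tolerance = 1e-9)
})

test_that("expiratory time constant recovers R*C and classifies mechanics", {
  sc <- sim_scenario(
    mechanics = mechanics(resistance_R = 10, compliance_C = 0.05),
    efforts = list(rate_per_min = 14, peak_pmus = 10, jitter_s = 0,
                   start_s = 1.5),
    duration_s = 25, seed = 4)
  sim <- simulate_recording(sc)
  est <- expiratory_time_constant(sim$recording, sim$truth$machine_breaths,
                                  efforts = sim$truth$efforts)
  expect_equal(est$tau_e_s, 0.5, tolerance = 0.05 * 0.5)
  expect_equal(est$mechanics_class, "normal")

  expect_equal(mechanics_class(0.8), "obstructive")
  expect_equal(mechanics_class(0.35), "restrictive")
  expect_equal(mechanics_class(0.4), "normal")
  expect_equal(mechanics_class(0.7), "normal")

  expect_error(expiratory_time_constant(sim$recording, NULL),
               class = "ventwave_capability_error")
})

test_that("Cohen's kappa behaves under perfect agreement and label permutation", {
  m <- diag(c(40, 10, 5))
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(agreement_stats(m)$kappa, 1)
  expect_true(all(agreement_stats(m)$per_class$sensitivity == 100))

  m2 <- matrix(c(30, 4, 2, 25, 1, 8), 2, 3,
               dimnames = list(c("x", "y"), c("x", "y", "z")))
  k1 <- agreement_stats(m2)$kappa
  # permuting class labels consistently in rows and columns
  perm <- c("y", "x", "z")
  m3 <- m2[c("y", "x"), perm]
  expect_equal(agreement_stats(m3)$kappa, k1, tolerance = 1e-12)

  expect_error(agreement_stats(matrix(0, 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b")))),
               class = "ventwave_contract_error")
})

test_that("record-level agreement handles identity and missed detections", {
  sim <- simulate_recording(scenario_preset("obstructive", seed = 1))
  rec <- pair_events(sim$truth$efforts, sim$truth$machine_breaths)
  agr <- agreement(rec, rec)
  expect_equal(agr$kappa, 1)
  expect_true(all(agr$per_class$sensitivity[
    agr$per_class$class %in% rec$class] == 100))

  # dropping some records sends them to the "missed" column
  agr2 <- agreement(rec[-c(1, 2), ], rec)
  expect_equal(sum(agr2$confusion[, "missed"]), 2)
  expect_lt(agr2$kappa, 1)

  expect_error(agreement(rec[0, ], rec), class = "ventwave_contract_error")
})

test_that("ROC AUC equals the exhaustive concordant-pair fraction", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "ventwave_contract_error")

  # property: Mann-Whitney identity on random sets, including ties
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    scores <- sample(round(rnorm(n), 1))        # coarse -> ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    bf <- mean(outer(scores[labels], scores[!labels],
                     function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(scores, labels), bf, tolerance = 1e-12)
  }

  # chance level for labels independent of scores
  set.seed(7)
  s <- rnorm(4000); l <- sample(c(TRUE, FALSE), 4000, replace = TRUE)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.03)
})

test_that("proportion-CI sample size reproduces the normal-approximation formula", {
  # worst-case p at 95%/5%: the textbook 385
  expect_equal(sample_size_proportion(0.95, 0.05), 385)
  # 99% confidence, +/-2%: exact quantile vs the conventional 2.58
  expect_equal(sample_size_proportion(0.99, 0.02), 4147)
  expect_equal(ceiling(2.58^2 * 0.25 / 0.02^2 - 0.5), 4160)
  expect_lt(abs(sample_size_proportion(0.99, 0.02, z = 2.58) - 4160), 2)
  expect_error(sample_size_proportion(conf_level = 1.2),
               class = "ventwave_argument_error")
})
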