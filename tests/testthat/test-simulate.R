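test_that("a quiet speaker produces a constant track", {
  m <- noise_free_model(trend_amplitude = 0, g_mid = 0, g_whole = 0,
                        f1_baseline = 640)
  tr <- simulate_trial(m, trial_row(kind = "none", hz = 0))
  expect_true(all(tr$f1 == 640))
  expect_equal(tr$voice_onset_frame, 1L)
  expect_equal(length(tr$f1), 667)
})

test_that("an instantaneous compensator steps at the latency", {
  m <- noise_free_model(trend_amplitude = 0, g_whole = 0.05,
                        comp_latency_ms = 250, comp_tau_ms = 0,
                        f1_baseline = 600)
  tr <- simulate_trial(m, trial_row(kind = "whole_utterance", hz = 200))
  t_ms <- (seq_along(tr$f1) - 1) * 3
  expect_true(all(tr$f1[t_ms < 250] == 600))
  expect_true(all(tr$f1[t_ms >= 250] == 590))
})

test_that("the transient response matches the piecewise closed form", {
  m <- noise_free_model(trend_amplitude = 0, g_mid = 0.08,
                        comp_latency_ms = 250, comp_tau_ms = 100,
                        f1_baseline = 580)
  tr <- simulate_trial(m, trial_row(kind = "mid_utterance", hz = -200,
                                    onset = 300))
  t_ms <- (seq_along(tr$f1) - 1) * 3
  expected <- 580 + oracle_comp(t_ms, p = -200, g = 0.08, t_p = 300,
                                dur = 400, L = 250, tau = 100)
  expect_equal(tr$f1, expected, tolerance = 1e-12)
  # response rises during the (delayed) perturbation and decays after it
  expect_true(all(tr$f1[t_ms < 550] == 580))
  expect_gt(max(tr$f1), 580 + 0.9 * 16)
  expect_lt(tr$f1[t_ms == 1998], 580 + 1)
})

test_that("adaptation states follow the learning recursion and plateau", {
  cfg <- schedule_config(rng_seed = 5)
  sched <- build_adaptation_session(cfg, "P01", 2) # +200 Hz hold
  m <- noise_free_model(adapt_rate = 0.01, adapt_retention = 0.9, g_whole = 0)
  sim <- simulate_adaptation_session(m, sched)

  s <- 0
  replay <- numeric(nrow(sched))
  for (k in seq_len(nrow(sched))) {
    replay[k] <- s
    s <- 0.9 * s - 0.01 * sched$pert_hz[k]
  }
  expect_equal(sim$states, replay, tolerance = 1e-12)

  hold_end <- max(which(sched$phase == "hold"))
  expect_equal(sim$states[hold_end], -20, tolerance = 0.01) # -beta*p/(1-r)

  # washout decay is monotone in magnitude
  wash <- sim$states[sched$phase == "washout"]
  expect_true(all(diff(abs(wash)) <= 1e-12))

  m0 <- noise_free_model(adapt_rate = 0, g_whole = 0)
  expect_true(all(simulate_adaptation_session(m0, sched)$states == 0))
})

test_that("cohort coupling knobs shape the parameter draws", {
  eq <- cohort_config(n_participants = 60, rng_seed = 2, rho_mid_whole = 1,
                      mean = list(g_mid = 0.05, g_whole = 0.05),
                      sd = list(g_mid = 0.02, g_whole = 0.02))
  ds <- simulate_cohort(eq, tracks = FALSE)
  expect_lt(max(abs(ds$ground_truth$g_mid - ds$ground_truth$g_whole)), 1e-6)

  indep <- cohort_config(n_participants = 200, rng_seed = 3,
                         rho_comp_adapt = 0)
  gt <- simulate_cohort(indep, tracks = FALSE)$ground_truth
  expect_lt(abs(cor(gt$g_whole, gt$plateau_pct)), 0.15)

  expect_error(cohort_config(rho_mid_whole = 1.2), "correlations")
})

test_that("default preset magnitudes bracket the observed response range", {
  gt <- simulate_cohort(cohort_preset("default", rng_seed = 8),
                        tracks = FALSE)$ground_truth
  expect_equal(nrow(gt), 22)
  # population means put compensation gains and plateaus in the 2-10% band
  expect_gt(mean(100 * gt$g_whole), 2)
  expect_lt(mean(100 * gt$g_whole), 10)
  expect_gt(mean(gt$plateau_pct), 2)
  expect_lt(mean(gt$plateau_pct), 10)
})

test_that("the realistic preset flags roughly the stated share of trials", {
  ds <- simulate_cohort(cohort_preset("realistic", n_participants = 4,
                                      rng_seed = 9, sessions = c(1L, 2L)))
  flagged <- 0
  heads <- 0
  for (el in ds$sessions) {
    h <- el$schedule$word == "head"
    heads <- heads + sum(h)
    flagged <- flagged + sum(h & el$quality == "excluded")
  }
  rate <- flagged / heads # 1140 head trials; binomial sd ~ 0.5 points
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.05)
})
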