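test_that("constant production yields a flat, zero adaptation record", {
  ds <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 1, rng_seed = 3, sessions = c(2L, 4L),
    mean = list(adapt_rate = 0, g_whole = 0)
  ))
  rec <- adaptation_trajectory(ds, "P01", 200)
  expect_true(all(abs(rec$trajectory$norm_hz) < 1e-9))
  expect_equal(rec$adaptation_pct, 0, tolerance = 1e-9)
  expect_equal(nrow(rec$smoothed), 24) # floor(120 / 5)
  expect_true(all(abs(rec$smoothed$norm_hz) < 1e-9))
})

test_that("the late-hold statistic recovers the learning plateau exactly", {
  # beta = 0.1, r = 0.5: plateau -40 Hz under +200 Hz, i.e. 20% adaptation,
  # converged to machine precision long before the late hold trials
  ds <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 1, rng_seed = 4, sessions = 2L,
    mean = list(adapt_rate = 0.1, adapt_retention = 0.5, g_whole = 0)
  ))
  rec <- adaptation_trajectory(ds, "P01", 200)
  expect_equal(rec$adaptation_pct, 20, tolerance = 1e-9)
  expect_equal(rec$baseline_ref_hz,
               ds$ground_truth$f1_baseline[1] + 30 * mean(exp(-(0:24) * 3 / 80)),
               tolerance = 1e-9)
  expect_error(adaptation_trajectory(ds, "P01", -200), "-200")
})

test_that("identical adapters give degenerate group summaries", {
  # fast-converging learning (same 8.5% plateau) so the statistic has hit
  # the plateau exactly regardless of where the catch trials fell
  ds <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 3, rng_seed = 6, sessions = c(2L, 4L),
    mean = list(g_whole = 0, adapt_rate = 0.0425, adapt_retention = 0.5)
  ))
  at <- adaptation_table(ds)
  expect_equal(nrow(at$table), 6)
  expect_equal(at$summary$sem, c(0, 0), tolerance = 1e-9)
  expect_equal(at$summary$mean, c(8.5, 8.5), tolerance = 1e-9)

  # zero learning: all responses zero, t = 0, p = 1
  ds0 <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 2, rng_seed = 6, sessions = c(2L, 4L),
    mean = list(adapt_rate = 0, g_whole = 0)
  ))
  s0 <- adaptation_table(ds0)$summary
  expect_equal(s0$t, c(0, 0))
  expect_equal(s0$p, c(1, 1))
})

test_that("the outlier rule removes extreme adapters once", {
  tbl <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:22),
    direction = 200,
    adaptation_pct = c(seq(7.5, 8.5, length.out = 21), 80)
  )
  res <- exclude_outlier_participants(tbl)
  expect_equal(res$removed$participant_id, "P22")
  expect_equal(length(res$kept), 21)

  # single-pass policy: a second pass over the kept set removes no one
  again <- exclude_outlier_participants(
    tbl[tbl$participant_id %in% res$kept, ]
  )
  expect_equal(nrow(again$removed), 0)

  # an identical cohort has zero dispersion and keeps everyone
  same <- tibble::tibble(participant_id = sprintf("P%02d", 1:5),
                         direction = 200, adaptation_pct = 8)
  expect_equal(nrow(exclude_outlier_participants(same)$removed), 0)
  expect_error(exclude_outlier_participants(same[1:2, ]), "three")
})

test_that("responder selection requires both positive responses", {
  comp <- tibble::tibble(
    participant_id = c("P01", "P02", "P03", "P01"),
    pert_kind = c(rep("whole_utterance", 3), "mid_utterance"),
    pert_hz = 200,
    peak_compensation_pct = c(5, 4, -1, -9)
  )
  adapt <- tibble::tibble(
    participant_id = c("P01", "P02", "P03"),
    direction = 200,
    adaptation_pct = c(8, -2, 6)
  )
  expect_equal(select_positive_responders(comp, adapt, 200), "P01")
  adapt$adaptation_pct <- c(8, 2, 6)
  expect_equal(select_positive_responders(comp, adapt, 200), c("P01", "P02"))
})

test_that("dynamics O window is consistent with the adaptation statistic", {
  ds <- small_cohort(n = 3, seed = 17, sessions = c(2L, 4L))
  ids <- ds$participants$participant_id
  for (d in c(200, -200)) {
    dyn <- phase_dynamics(ds, ids, d)
    late_o <- dyn$windows[dyn$windows$phase == "late_adapt" &
                            dyn$windows$window == "O", ]
    for (pid in ids) {
      rec <- adaptation_trajectory(ds, pid, d)
      expect_equal(late_o$pct[late_o$participant_id == pid],
                   rec$adaptation_pct, tolerance = 1e-9)
    }
  }
})

test_that("noise-free dynamics are zero at baseline and show the feedback buildup", {
  g <- 0.06
  ds <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 2, rng_seed = 8, sessions = c(2L, 4L),
    mean = list(g_whole = g, comp_latency_ms = 250, comp_tau_ms = 120)
  ))
  dyn <- phase_dynamics(ds, c("P01", "P02"), 200)
  base <- dyn$windows[dyn$windows$phase == "late_baseline", ]
  expect_true(all(abs(base$pct) < 1e-9))

  late <- dyn$windows[dyn$windows$phase == "late_adapt", ]
  m_minus_o <- late$pct[late$window == "M"] - late$pct[late$window == "O"]
  t_m <- seq(600, 798, by = 3)
  expected <- 100 * g * mean(1 - exp(-(t_m - 250) / 120))
  expect_equal(m_minus_o, rep(expected, 2), tolerance = 1e-6)

  expect_error(phase_dynamics(ds, character(0), 200), "empty")
})
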