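cfg <- schedule_config(rng_seed = 42, counterbalance_group = "plus_first")

test_that("unpredictable sessions reproduce the design counts", {
  sched <- build_unpredictable_sessions(cfg, "P01")
  expect_equal(nrow(sched), 495)
  expect_equal(unname(table(sched$session)), rep(165L, 3),
               ignore_attr = TRUE)
  expect_equal(sum(sched$phase == "familiarization"), 15)
  expect_equal(sched$phase[sched$session == 1][1:15],
               rep("familiarization", 15))

  pool <- sched[sched$phase == "unpredictable", ]
  expect_equal(nrow(pool), 480)
  pert <- pool[pool$pert_kind != "none", ]
  expect_equal(nrow(pert), 432)
  expect_equal(sum(pert$word == "head"), 360)
  expect_equal(sum(pert$word == "hid"), 72)
  unpert <- pool[pool$pert_kind == "none", ]
  expect_equal(nrow(unpert), 48)
  expect_equal(sum(unpert$word == "head"), 30)
  expect_equal(sum(unpert$word == "hid"), 18)

  conds <- unique(pert[, c("pert_kind", "pert_hz")])
  expect_equal(nrow(conds), 8)
  balance <- table(pert$pert_kind, pert$pert_hz, pert$word)
  expect_true(all(balance[, , "head"] == 45))
  expect_true(all(balance[, , "hid"] == 9))
})

test_that("schedules are pure functions of seed, participant and group", {
  a <- build_unpredictable_sessions(cfg, "P01")
  b <- build_unpredictable_sessions(cfg, "P01")
  expect_identical(a, b)
  expect_false(identical(
    a, build_unpredictable_sessions(schedule_config(rng_seed = 43), "P01")
  ))
  expect_false(identical(a, build_unpredictable_sessions(cfg, "P02")))
  expect_identical(build_adaptation_session(cfg, "P03", 2),
                   build_adaptation_session(cfg, "P03", 2))
})

test_that("mid-utterance jitter stays in bounds and follows the uniform law", {
  onsets <- unlist(lapply(1:48, function(i) {
    s <- build_unpredictable_sessions(schedule_config(rng_seed = i), "P01")
    s$pert_onset_ms[s$pert_kind == "mid_utterance"]
  }))
  expect_gt(length(onsets), 1e4)
  expect_true(all(onsets >= 200 & onsets <= 500))
  ks <- suppressWarnings(stats::ks.test(onsets, "punif", 200, 500))
  expect_gt(ks$p.value, 0.01)
})

test_that("adaptation sessions have the phase structure and counterbalance", {
  s2 <- build_adaptation_session(cfg, "P01", 2)
  expect_equal(nrow(s2), 165)
  expect_equal(unname(table(s2$phase)[c("baseline", "hold", "washout")]),
               c(42L, 81L, 42L), ignore_attr = TRUE)
  expect_equal(sum(s2$word == "head"), 120)
  hold <- s2[s2$phase == "hold", ]
  expect_true(all(hold$pert_kind == "whole_utterance"))
  expect_true(all(hold$pert_hz == 200)) # plus_first, session 2
  expect_true(all(hold$pert_onset_ms == 0))
  expect_true(all(s2$pert_kind[s2$phase != "hold"] == "none"))

  s4 <- build_adaptation_session(cfg, "P01", 4)
  expect_true(all(s4$pert_hz[s4$phase == "hold"] == -200))

  minus <- schedule_config(rng_seed = 42, counterbalance_group = "minus_first")
  m4 <- build_adaptation_session(minus, "P01", 4)
  expect_true(all(m4$pert_hz[m4$phase == "hold"] == 200))
  expect_error(build_adaptation_session(cfg, "P01", 3), "session")
})

test_that("head-trial ordinals skip catch trials", {
  mini <- dplyr::bind_rows(
    trial_row(word = "head", trial_index = 1L),
    trial_row(word = "hid", trial_index = 2L),
    trial_row(word = "head", trial_index = 3L)
  )
  ords <- head_trial_ordinals(mini)
  expect_equal(ords$trial_index, c(1L, 3L))
  expect_equal(ords$head_ordinal, c(1L, 2L))

  full <- head_trial_ordinals(build_adaptation_session(cfg, "P01", 2))
  expect_equal(max(full$head_ordinal), 120)
  empty <- head_trial_ordinals(trial_row()[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("perturbation descriptors enforce their invariants", {
  expect_error(perturbation_spec("none", 50), "magnitude")
  expect_error(perturbation_spec("mid_utterance", 200, onset_delay_ms = 150),
               "200")
  expect_error(perturbation_spec("whole_utterance", 200, onset_delay_ms = 100),
               "voice onset")
  ok <- perturbation_spec("mid_utterance", -50, onset_delay_ms = 321)
  expect_equal(ok$pert_duration_ms, 400)
})

test_that("schedules round-trip through CSV", {
  sched <- build_schedule(cfg, "P07")
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedule(sched, path, rng_seed = 42)
  back <- read_schedule(path)
  expect_equal(as.data.frame(back[, names(sched)]), as.data.frame(sched),
               tolerance = 1e-12)
  expect_true(all(back$rng_seed == 42))
})
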