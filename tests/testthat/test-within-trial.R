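test_that("the unperturbed trend removes shared trajectories", {
  # identical constant trials: onset normalization leaves a zero trend
  sched <- dplyr::bind_rows(lapply(1:3, function(i) {
    trial_row(kind = "none", hz = 0, trial_index = i)
  }))
  el <- make_session_element(matrix(612, nrow = 200, ncol = 3), sched)
  ds <- manual_dataset(list(el))
  tr <- unperturbed_trend(ds, "P01")
  expect_true(all(tr$values == 0))
  expect_equal(tr$n_trials, 3L)

  # ramps of slope 1 and 3 Hz/frame average to a slope-2 trend
  f1 <- cbind(600 + (0:199) * 1, 580 + (0:199) * 3)
  el2 <- make_session_element(f1, sched[1:2, ])
  tr2 <- unperturbed_trend(manual_dataset(list(el2)), "P01")
  expect_equal(tr2$values, (0:199) * 2, tolerance = 1e-12)

  # noise-free simulated vowel-onset transient is recovered pointwise
  ds3 <- simulate_cohort(cohort_preset("noise_free", n_participants = 1,
                                       rng_seed = 2, sessions = 1L))
  tr3 <- unperturbed_trend(ds3, "P01")
  t_ms <- (seq_along(tr3$values) - 1) * 3
  expect_equal(tr3$values, 30 * exp(-t_ms / 80) - 30, tolerance = 1e-9)

  expect_error(
    unperturbed_trend(manual_dataset(list(make_session_element(
      matrix(600, 10, 1), trial_row(kind = "whole_utterance", hz = 200)
    ))), "P01"),
    "unperturbed"
  )
})

test_that("trial normalization zeroes trend-shaped and offset inputs", {
  trend <- cumsum(rnorm(400, 0, 2))
  trend <- trend - trend[1]
  out <- normalize_trial(trend + 603, trend, pert_onset_ms = 0)
  expect_true(all(abs(out$value) < 1e-9))

  out7 <- normalize_trial(trend + 7 + 603, trend, pert_onset_ms = 120)
  expect_true(all(abs(out7$value) < 1e-9))
})

test_that("an instantaneous response lands in the bin containing the step", {
  t_ms <- (0:666) * 3
  f1 <- ifelse(t_ms < 250, 600, 590) # g = 0.05, p = +200, L = 250
  out <- normalize_trial(f1, numeric(667), pert_onset_ms = 0)
  expect_true(all(out$value[out$bin <= 9] == 0))
  expect_true(all(out$value[out$bin >= 10] == -10))
})

test_that("the post-onset reference mean is zero for random trials", {
  withr::local_seed(314)
  worst <- 0
  for (i in 1:250) {
    n <- 500
    f1 <- 600 + cumsum(rnorm(n)) + rnorm(n, 0, 8)
    trend <- cumsum(rnorm(n, 0, 0.5))
    tp <- runif(1, 0, 500)
    out <- normalize_trial(f1, trend, tp)
    ref <- out[out$time_ms < 50, ]
    worst <- max(worst, abs(sum(ref$value * ref$n_frames) / sum(ref$n_frames)))
  }
  expect_lt(worst, 1e-9)
})

make_group_tc <- function(kind = "mid_utterance", target_hz = -200,
                          target = NULL, n_bins = 30, others = c(-1, 1)) {
  dplyr::bind_rows(lapply(c(-200, -50, 50, 200), function(hz) {
    mean_vals <- if (hz == target_hz && !is.null(target)) target else
      c(others, rep(0, n_bins - 2))
    tibble::tibble(
      pert_kind = kind, pert_hz = hz, bin = 0:(n_bins - 1),
      time_ms = (0:(n_bins - 1)) * 25, time_mid_ms = (0:(n_bins - 1)) * 25 + 12.5,
      mean = mean_vals, sem = 0, n_participants = 2
    )
  }))
}

test_that("onset latency finds sustained threshold crossings", {
  # series 0 until bin 10 (= 250 ms), then 5: pool mean 0, sd ~ 1
  target <- c(-1, 1, rep(0, 8), rep(5, 20))
  tc <- make_group_tc(target_hz = -200, target = target)
  expect_equal(onset_latency(tc, "mid_utterance", -200), 250)

  # compensatory direction matters: same series under +200 never crosses
  tc_pos <- make_group_tc(target_hz = 200, target = target)
  expect_true(is.na(onset_latency(tc_pos, "mid_utterance", 200)))

  # identically zero response with a nonzero-sd pool: no latency
  tc0 <- make_group_tc(target_hz = -200, target = rep(0, 30))
  expect_true(is.na(onset_latency(tc0, "mid_utterance", -200)))

  # a single-bin blip passes the literal rule but not the sustained one
  blip <- c(-1, 1, rep(0, 8), 5, rep(0, 19))
  tcb <- make_group_tc(target_hz = -200, target = blip)
  expect_equal(onset_latency(tcb, "mid_utterance", -200, persistence = 1), 250)
  expect_true(is.na(onset_latency(tcb, "mid_utterance", -200)))
})

test_that("latency detection on pure noise reports none almost always", {
  withr::local_seed(2718)
  none <- 0
  reps <- 80
  for (i in seq_len(reps)) {
    tc <- dplyr::bind_rows(lapply(c(-200, -50, 50, 200), function(hz) {
      tibble::tibble(
        pert_kind = "mid_utterance", pert_hz = hz, bin = 0:59,
        time_ms = (0:59) * 25, time_mid_ms = (0:59) * 25 + 12.5,
        mean = rnorm(60), sem = 0, n_participants = 22
      )
    }))
    if (is.na(onset_latency(tc, "mid_utterance", 200))) none <- none + 1
  }
  expect_gte(none / reps, 0.95)
})

test_that("peak compensation applies the compMult formula", {
  tc <- tibble::tibble(time_mid_ms = (0:29) * 25 + 12.5,
                       value = rep(-10, 30))
  pc <- peak_compensation(tc, peak_latency_ms = 400, pert_hz = 200)
  expect_equal(pc$pct, 5)
  expect_equal(pc$n_bins, 8)

  tc0 <- tibble::tibble(time_mid_ms = tc$time_mid_ms, value = 0)
  expect_equal(peak_compensation(tc0, 400, -50)$pct, 0)

  # antisymmetry: response x under p equals -x under -p
  withr::local_seed(7)
  x <- rnorm(30, 0, 4)
  for (p in c(50, 200)) {
    a <- peak_compensation(tibble::tibble(time_mid_ms = tc$time_mid_ms,
                                          value = x), 300, p)$pct
    b <- peak_compensation(tibble::tibble(time_mid_ms = tc$time_mid_ms,
                                          value = -x), 300, -p)$pct
    expect_equal(a, b, tolerance = 1e-12)
  }
  expect_error(peak_compensation(tc, 2000, 200), "window")
})

test_that("opposite responders average to zero with SEM a", {
  a <- 6
  sched_un <- dplyr::bind_rows(lapply(1:2, function(i) {
    trial_row(kind = "none", hz = 0, trial_index = i)
  }))
  sched_p <- trial_row(kind = "whole_utterance", hz = 200, trial_index = 3L)
  t_ms <- (0:399) * 3
  ds <- manual_dataset(list(
    make_session_element(
      cbind(600, 600, 600 + ifelse(t_ms >= 500, a, 0)),
      dplyr::bind_rows(sched_un, sched_p)
    ),
    make_session_element(
      cbind(600, 600, 600 + ifelse(t_ms >= 500, -a, 0)),
      dplyr::mutate(dplyr::bind_rows(sched_un, sched_p), participant_id = "P02")
    )
  ))
  ds$participants <- tibble::tibble(participant_id = c("P01", "P02"),
                                    group = "plus_first", age = 25)
  ca <- condition_average(ds)
  late <- ca$group[ca$group$time_ms >= 500, ]
  expect_true(all(abs(late$mean) < 1e-9))
  expect_equal(late$sem, rep(a, nrow(late)), tolerance = 1e-9)
})

test_that("identical instantaneous compensators yield exact percentages", {
  ds <- simulate_cohort(cohort_preset(
    "noise_free", n_participants = 3, rng_seed = 5, sessions = c(1L, 3L, 5L),
    mean = list(g_mid = 0.05, g_whole = 0.05, comp_latency_ms = 250,
                comp_tau_ms = 0)
  ))
  ct <- compensation_table(ds)
  expect_equal(ct$summary$mean, rep(5, 8), tolerance = 1e-9)
  expect_equal(ct$summary$sem, rep(0, 8), tolerance = 1e-9)
  expect_true(all(ct$summary$degenerate))
  expect_equal(ct$latency$onset_latency_ms, rep(250, 8))
})

test_that("production normalization agrees with the brute-force oracle", {
  withr::local_seed(99)
  for (i in 1:20) {
    n <- 600
    f1 <- 580 + cumsum(rnorm(n, 0, 1.5)) + rnorm(n, 0, 10)
    trend <- cumsum(rnorm(n, 0, 0.8))
    tp <- runif(1, 0, 500)
    oracle <- brute_normalize(f1, trend, tp)
    prod <- normalize_trial(f1, trend, tp)
    expect_equal(prod$bin, oracle$bin)
    expect_lt(max(abs(prod$value - oracle$value)), 1e-9)

    # and the vectorized batch engine agrees with both
    sched <- trial_row(kind = "mid_utterance", hz = 200, onset = tp)
    el <- make_session_element(matrix(f1, ncol = 1), sched)
    bn <- fpl:::binned_normalized(el, trend, 1L)
    got <- bn$values[seq_len(bn$max_complete_bin + 1), 1]
    expect_lt(max(abs(got - oracle$value)), 1e-9)
  }
})
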