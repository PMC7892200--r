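#' Parametric speech-motor model for one participant
#'
#' Describes a speaker as a feedback + feedforward controller of the first
#' formant (F1): a baseline F1 with a vowel-onset exponential transient, a
#' delayed first-order compensatory response opposing feedback perturbations
#' (separate gains for mid- and whole-utterance perturbations), a single-rate
#' trial-to-trial adaptation state (learning rate and retention), and
#' frame-level plus trial-level Gaussian noise.
#'
#' @param f1_baseline Baseline F1 of the prompted vowel in Hz.
#' @param trend_amplitude,trend_tau_ms Amplitude (Hz) and time constant (ms)
#'   of the vowel-onset transient `trend_amplitude * exp(-t / trend_tau_ms)`.
#' @param g_mid,g_whole Dimensionless compensation gains (fraction of the
#'   perturbation opposed) for mid- and whole-utterance perturbations.
#' @param comp_latency_ms Sensory-motor latency L before the compensatory
#'   response begins (ms); the response to the perturbation offset is delayed
#'   by the same amount.
#' @param comp_tau_ms First-order rise/decay time constant of the
#'   compensatory response (ms); 0 gives an instantaneous step.
#' @param adapt_rate Per-trial learning fraction (state change per Hz of
#'   perturbation per trial).
#' @param adapt_retention Per-trial retention of the adaptation state, in
#'   `[0, 1)`.
#' @param noise_frame_hz,noise_trial_hz Standard deviations of iid per-frame
#'   noise and of the per-trial offset (Hz).
#' @param age Age in years (analysis covariate only).
#' @param hid_offset_hz F1 offset applied to "hid" catch trials (their vowel
#'   has a lower F1; catch trials never enter analyses).
#' @return An object of class `participant_model`.
#' @export
participant_model <- function(f1_baseline = 600,
                              trend_amplitude = 30,
                              trend_tau_ms = 80,
                              g_mid = 0.03,
                              g_whole = 0.05,
                              comp_latency_ms = 275,
                              comp_tau_ms = 120,
                              adapt_rate = 0.00425,
                              adapt_retention = 0.95,
                              noise_frame_hz = 12,
                              noise_trial_hz = 18,
                              age = 22,
                              hid_offset_hz = -150) {
  m <- list(
    f1_baseline = f1_baseline, trend_amplitude = trend_amplitude,
    trend_tau_ms = trend_tau_ms, g_mid = g_mid, g_whole = g_whole,
    comp_latency_ms = comp_latency_ms, comp_tau_ms = comp_tau_ms,
    adapt_rate = adapt_rate, adapt_retention = adapt_retention,
    noise_frame_hz = noise_frame_hz, noise_trial_hz = noise_trial_hz,
    age = age, hid_offset_hz = hid_offset_hz
  )
  if (!all(vapply(m, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1)))) {
    abort("All participant_model parameters must be finite scalars.")
  }
  if (m$noise_frame_hz < 0 || m$noise_trial_hz < 0) {
    abort("Noise standard deviations must be non-negative.")
  }
  if (m$adapt_retention < 0 || m$adapt_retention >= 1) {
    abort("adapt_retention must lie in [0, 1).")
  }
  structure(m, class = "participant_model")
}

# Deterministic compensatory response c(t) to a perturbation of `pert_hz` Hz
# starting at `onset_ms` with duration `duration_ms` (Inf = whole utterance).
# The response begins at onset + L and rises as a first-order exponential
# toward -g * p; after the (delayed) perturbation offset it decays back to 0
# with the same time constant. Both the onset and the offset of the response
# lag the stimulus by the sensory latency L.
comp_response <- function(t_ms, pert_hz, gain, onset_ms, duration_ms,
                          latency_ms, tau_ms) {
  out <- numeric(length(t_ms))
  if (pert_hz == 0 || gain == 0) return(out)
  t_on <- onset_ms + latency_ms
  t_off <- if (is.finite(duration_ms)) onset_ms + duration_ms + latency_ms else Inf
  amp <- -gain * pert_hz
  rising <- t_ms >= t_on & t_ms < t_off
  after <- t_ms >= t_off
  if (tau_ms <= 0) {
    out[rising] <- amp
  } else {
    out[rising] <- amp * (1 - exp(-(t_ms[rising] - t_on) / tau_ms))
    if (any(after)) {
      c_end <- amp * (1 - exp(-(t_off - t_on) / tau_ms))
      out[after] <- c_end * exp(-(t_ms[after] - t_off) / tau_ms)
    }
  }
  out
}

#' Simulate one trial's F1 track
#'
#' The produced track is
#' `f1(t) = f1_baseline + trend_amplitude * exp(-t/trend_tau) + s + c(t) +
#' eps_trial + eps_frame(t)`, where `s` is the current adaptation state and
#' `c(t)` the delayed first-order compensatory response to the trial's
#' perturbation (see [participant_model()]). Frames are uniform; frame k has
#' time `(k - voice_onset_frame) * frame_interval_ms`, with voice onset at
#' frame 1.
#'
#' Randomness is taken from the current RNG stream; callers seed it.
#'
#' @param model A [participant_model()].
#' @param trial One schedule row (tibble with the perturbation columns).
#' @param adapt_state Current adaptation state s in Hz.
#' @param duration_ms Utterance duration (ms); at least 1000.
#' @param frame_interval_ms Frame interval (ms), default 3.
#' @return A `formant_track`: list with `participant_id`, `session`,
#'   `trial_index`, `frame_interval_ms`, `f1`, `voice_onset_frame`,
#'   `voice_offset_frame`, `quality_flag`.
#' @export
simulate_trial <- function(model, trial, adapt_state = 0,
                           duration_ms = 2000, frame_interval_ms = 3) {
  stopifnot(inherits(model, "participant_model"), is.finite(adapt_state))
  if (duration_ms < 1000) abort("Trials must last at least 1 s.")
  n <- n_frames_for(duration_ms, frame_interval_ms)
  t_ms <- (seq_len(n) - 1) * frame_interval_ms
  gain <- switch(trial$pert_kind,
    mid_utterance = model$g_mid,
    whole_utterance = model$g_whole,
    0
  )
  word_offset <- if (identical(trial$word, "hid")) model$hid_offset_hz else 0
  f1 <- model$f1_baseline + word_offset +
    model$trend_amplitude * exp(-t_ms / model$trend_tau_ms) +
    adapt_state +
    comp_response(t_ms, trial$pert_hz, gain,
                  trial$pert_onset_ms %||% 0, trial$pert_duration_ms %||% 0,
                  model$comp_latency_ms, model$comp_tau_ms) +
    rnorm(1, 0, model$noise_trial_hz) +
    rnorm(n, 0, model$noise_frame_hz)
  structure(
    list(
      participant_id = trial$participant_id %||% NA_character_,
      session = trial$session %||% NA_integer_,
      trial_index = trial$trial_index %||% NA_integer_,
      frame_interval_ms = frame_interval_ms,
      f1 = f1,
      voice_onset_frame = 1L,
      voice_offset_frame = n,
      quality_flag = "good"
    ),
    class = "formant_track"
  )
}

n_frames_for <- function(duration_ms, frame_interval_ms) {
  as.integer(floor((duration_ms - 1e-9) / frame_interval_ms)) + 1L
}

# Vectorized simulation of a whole session: returns the session element used
# throughout the package (schedule + frames-by-trials F1 matrix + markers).
simulate_session_tracks <- function(model, schedule, adapt_states = NULL,
                                    duration_ms = 2000, frame_interval_ms = 3,
                                    exclusion_rate = 0) {
  n_tr <- nrow(schedule)
  n <- n_frames_for(duration_ms, frame_interval_ms)
  t_ms <- (seq_len(n) - 1) * frame_interval_ms
  if (is.null(adapt_states)) adapt_states <- numeric(n_tr)
  stopifnot(length(adapt_states) == n_tr)

  base <- model$f1_baseline + model$trend_amplitude * exp(-t_ms / model$trend_tau_ms)
  f1 <- matrix(base, nrow = n, ncol = n_tr)
  for (j in seq_len(n_tr)) {
    if (schedule$pert_hz[j] != 0) {
      gain <- if (schedule$pert_kind[j] == "mid_utterance") model$g_mid else model$g_whole
      f1[, j] <- f1[, j] + comp_response(
        t_ms, schedule$pert_hz[j], gain,
        schedule$pert_onset_ms[j], schedule$pert_duration_ms[j],
        model$comp_latency_ms, model$comp_tau_ms
      )
    }
  }
  hid <- schedule$word == "hid"
  if (any(hid)) f1[, hid] <- f1[, hid] + model$hid_offset_hz
  f1 <- sweep(f1, 2, adapt_states + rnorm(n_tr, 0, model$noise_trial_hz), "+")
  if (model$noise_frame_hz > 0) {
    f1 <- f1 + matrix(rnorm(n * n_tr, 0, model$noise_frame_hz), n, n_tr)
  }
  quality <- rep("good", n_tr)
  if (exclusion_rate > 0) {
    flag <- schedule$word == "head" & runif(n_tr) < exclusion_rate
    quality[flag] <- "excluded"
  }
  list(
    participant_id = schedule$participant_id[1],
    session = schedule$session[1],
    frame_interval_ms = frame_interval_ms,
    schedule = schedule,
    f1 = f1,
    voice_onset_frame = rep(1L, n_tr),
    voice_offset_frame = rep(n, n_tr),
    quality = quality
  )
}

#' Simulate an adaptation session with an evolving feedforward state
#'
#' The adaptation state follows the single-rate learning rule
#' `s[k+1] = r * s[k] - beta * p[k]` with `s[1] = 0`, where `p[k]` is the
#' perturbation applied on trial k (0 in baseline and washout). Under a
#' constant perturbation the state converges to the plateau
#' `s_inf = -beta * p / (1 - r)`. Every trial is generated with the state
#' current at that trial.
#'
#' @param model A [participant_model()].
#' @param schedule A session schedule from [build_adaptation_session()].
#' @param duration_ms,frame_interval_ms Track geometry.
#' @param exclusion_rate Probability that a "head" trial is flagged
#'   `excluded` (exercises screening paths).
#' @return A list with `tracks` (session element: schedule, F1 matrix,
#'   markers, quality flags) and `states` (the per-trial true states s_k).
#' @export
simulate_adaptation_session <- function(model, schedule, duration_ms = 2000,
                                        frame_interval_ms = 3,
                                        exclusion_rate = 0) {
  stopifnot(inherits(model, "participant_model"))
  if (!all(schedule$phase %in% c("baseline", "hold", "washout"))) {
    abort("Expected an adaptation-session schedule (baseline/hold/washout phases).")
  }
  n_tr <- nrow(schedule)
  states <- numeric(n_tr)
  s <- 0
  for (k in seq_len(n_tr)) {
    states[k] <- s
    s <- model$adapt_retention * s - model$adapt_rate * schedule$pert_hz[k]
  }
  tracks <- simulate_session_tracks(model, schedule, states,
                                    duration_ms, frame_interval_ms,
                                    exclusion_rate)
  list(tracks = tracks, states = states)
}

#' Configuration for a synthetic cohort
#'
#' Population means and standard deviations for every [participant_model()]
#' field, plus two coupling knobs: `rho_mid_whole`, the across-participant
#' correlation of the mid- and whole-utterance compensation gains, and
#' `rho_comp_adapt`, the correlation of the whole-utterance gain with the
#' adaptation learning rate. The implied 3x3 correlation matrix (with
#' `cor(g_mid, adapt_rate) = rho_mid_whole * rho_comp_adapt`) must be
#' positive semi-definite.
#'
#' @param n_participants Cohort size.
#' @param rng_seed Cohort-level seed; per-participant streams are derived
#'   deterministically from it.
#' @param rho_mid_whole,rho_comp_adapt Coupling correlations in `[-1, 1]`.
#' @param mean,sd Named lists overriding population means / SDs for
#'   `participant_model` fields.
#' @param exclusion_rate Fraction of "head" trials randomly flagged excluded.
#' @param truncate_gains If `TRUE`, negative sampled gains are clipped to 0
#'   (the "compensator" preset behaviour).
#' @param sessions Which of the five sessions to generate (default all).
#' @param duration_ms,frame_interval_ms Track geometry.
#' @param schedule Arguments passed to [schedule_config()] apart from the
#'   seed and group (optional named list).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 22,
                          rng_seed = 1L,
                          rho_mid_whole = 0.6,
                          rho_comp_adapt = 0,
                          mean = list(),
                          sd = list(),
                          exclusion_rate = 0,
                          truncate_gains = FALSE,
                          sessions = 1:5,
                          duration_ms = 2000,
                          frame_interval_ms = 3,
                          schedule = list()) {
  if (abs(rho_mid_whole) > 1 || abs(rho_comp_adapt) > 1) {
    abort("Coupling correlations must lie in [-1, 1].")
  }
  pop_mean <- utils::modifyList(list(
    f1_baseline = 600, trend_amplitude = 30, trend_tau_ms = 80,
    g_mid = 0.03, g_whole = 0.05, comp_latency_ms = 275, comp_tau_ms = 120,
    adapt_rate = 0.00425, adapt_retention = 0.95,
    noise_frame_hz = 12, noise_trial_hz = 18, age = 24
  ), mean)
  # between-participant spreads follow the group SEMs this paradigm reports
  # at n = 22 (gain SDs of 3-4.5 points, adaptation plateaus of ~11 points),
  # which put a minority of speakers at or below zero response
  pop_sd <- utils::modifyList(list(
    f1_baseline = 50, trend_amplitude = 8, trend_tau_ms = 0,
    g_mid = 0.03, g_whole = 0.045, comp_latency_ms = 40, comp_tau_ms = 20,
    adapt_rate = 0.0055, adapt_retention = 0,
    noise_frame_hz = 0, noise_trial_hz = 0, age = 5
  ), sd)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho_mid_whole
  R[2, 3] <- R[3, 2] <- rho_comp_adapt
  R[1, 3] <- R[3, 1] <- rho_mid_whole * rho_comp_adapt
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("Implied gain/learning-rate correlation matrix is not positive semi-definite.")
  }
  structure(
    list(
      n_participants = as.integer(n_participants), rng_seed = as.integer(rng_seed),
      rho_mid_whole = rho_mid_whole, rho_comp_adapt = rho_comp_adapt,
      mean = pop_mean, sd = pop_sd, corr = R,
      exclusion_rate = exclusion_rate, truncate_gains = isTRUE(truncate_gains),
      sessions = as.integer(sessions), duration_ms = duration_ms,
      frame_interval_ms = frame_interval_ms, schedule = schedule
    ),
    class = "cohort_config"
  )
}

#' Named cohort presets
#'
#' `"default"`: the study conditions used throughout the package (n = 22,
#' moderate between-participant spread, realistic tracking noise).
#' `"noise_free"`: all noise terms and parameter spreads zero, for
#' closed-form checks. `"realistic"`: the default plus ~3% of "head" trials
#' randomly flagged excluded, to exercise screening. `"compensator"`: the
#' default with negative gains clipped at zero.
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [cohort_config()].
#' @return A `cohort_config`.
#' @export
cohort_preset <- function(name = c("default", "noise_free", "realistic", "compensator"),
                          ...) {
  name <- match.arg(name)
  args <- switch(name,
    default = list(),
    noise_free = list(
      sd = list(f1_baseline = 0, trend_amplitude = 0, trend_tau_ms = 0,
                g_mid = 0, g_whole = 0, comp_latency_ms = 0, comp_tau_ms = 0,
                adapt_rate = 0, adapt_retention = 0, age = 0),
      mean = list(noise_frame_hz = 0, noise_trial_hz = 0)
    ),
    realistic = list(exclusion_rate = 0.03),
    compensator = list(truncate_gains = TRUE)
  )
  do.call(cohort_config, utils::modifyList(args, list(...)))
}

# Draw the participant parameter table for a cohort config.
draw_participants <- function(config) {
  n <- config$n_participants
  mu <- config$mean
  sdv <- config$sd
  S <- diag(c(sdv$g_mid, sdv$g_whole, sdv$adapt_rate))
  Sigma <- S %*% config$corr %*% S
  g <- MASS::mvrnorm(n, mu = c(mu$g_mid, mu$g_whole, mu$adapt_rate),
                     Sigma = Sigma)
  g <- matrix(g, ncol = 3)
  if (config$truncate_gains) g[, 1:2][g[, 1:2] < 0] <- 0
  draw <- function(field, lo = -Inf, hi = Inf) {
    pmin(pmax(rnorm(n, mu[[field]], sdv[[field]]), lo), hi)
  }
  tibble::tibble(
    participant_id = sprintf("P%02d", seq_len(n)),
    group = rep(c("plus_first", "minus_first"), length.out = n),
    f1_baseline = draw("f1_baseline", lo = 200),
    trend_amplitude = draw("trend_amplitude"),
    trend_tau_ms = draw("trend_tau_ms", lo = 1),
    g_mid = g[, 1],
    g_whole = g[, 2],
    comp_latency_ms = draw("comp_latency_ms", lo = 0),
    comp_tau_ms = draw("comp_tau_ms", lo = 0),
    adapt_rate = g[, 3],
    adapt_retention = draw("adapt_retention", lo = 0, hi = 0.999),
    noise_frame_hz = draw("noise_frame_hz", lo = 0),
    noise_trial_hz = draw("noise_trial_hz", lo = 0),
    age = round(draw("age", lo = 18))
  )
}

participant_model_from_row <- function(row) {
  participant_model(
    f1_baseline = row$f1_baseline, trend_amplitude = row$trend_amplitude,
    trend_tau_ms = row$trend_tau_ms, g_mid = row$g_mid, g_whole = row$g_whole,
    comp_latency_ms = row$comp_latency_ms, comp_tau_ms = row$comp_tau_ms,
    adapt_rate = row$adapt_rate, adapt_retention = row$adapt_retention,
    noise_frame_hz = row$noise_frame_hz, noise_trial_hz = row$noise_trial_hz,
    age = row$age
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws correlated participant parameters, builds each participant's
#' five-session schedule (session order counterbalanced by alternating
#' groups), simulates every trial's F1 track, and returns an analysis-ready
#' dataset together with the ground-truth parameter table (including the
#' adaptation plateau `100 * beta / (1 - r)` in percent).
#'
#' @param config A [cohort_config()] or [cohort_preset()].
#' @param tracks If `FALSE`, only schedules and the ground-truth table are
#'   generated (fast path for parameter-level studies).
#' @return An object of class `fpl_dataset`: list with `participants`,
#'   `sessions` (named list of per participant-session track sets),
#'   `ground_truth`, and `provenance`.
#' @export
simulate_cohort <- function(config = cohort_preset("default"), tracks = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  params <- with_rng(derive_seed(config$rng_seed, "participants"),
                     draw_participants(config))
  truth <- params |>
    dplyr::mutate(
      plateau_hz_per_hz = -.data$adapt_rate / (1 - .data$adapt_retention),
      plateau_pct = 100 * .data$adapt_rate / (1 - .data$adapt_retention)
    )
  sessions <- list()
  if (tracks) {
    for (i in seq_len(nrow(params))) {
      row <- params[i, ]
      model <- participant_model_from_row(row)
      sc_args <- utils::modifyList(
        list(rng_seed = config$rng_seed, counterbalance_group = row$group),
        config$schedule
      )
      scfg <- do.call(schedule_config, sc_args)
      pid <- row$participant_id
      if (any(config$sessions %in% c(1L, 3L, 5L))) {
        unpred <- build_unpredictable_sessions(scfg, pid)
        for (s in intersect(config$sessions, c(1L, 3L, 5L))) {
          sched <- unpred[unpred$session == s, ]
          el <- with_rng(
            derive_seed(config$rng_seed, pid, "tracks", s),
            simulate_session_tracks(model, sched,
                                    duration_ms = config$duration_ms,
                                    frame_interval_ms = config$frame_interval_ms,
                                    exclusion_rate = config$exclusion_rate)
          )
          sessions[[paste(pid, s, sep = ".")]] <- el
        }
      }
      for (s in intersect(config$sessions, c(2L, 4L))) {
        sched <- build_adaptation_session(scfg, pid, s)
        sim <- with_rng(
          derive_seed(config$rng_seed, pid, "tracks", s),
          simulate_adaptation_session(model, sched,
                                      duration_ms = config$duration_ms,
                                      frame_interval_ms = config$frame_interval_ms,
                                      exclusion_rate = config$exclusion_rate)
        )
        el <- sim$tracks
        el$true_states <- sim$states
        sessions[[paste(pid, s, sep = ".")]] <- el
      }
    }
  }
  new_dataset(
    participants = params[, c("participant_id", "group", "age")],
    sessions = sessions,
    ground_truth = truth,
    provenance = list(
      rng_seed = config$rng_seed,
      config_hash = config_hash(unclass(config)),
      n_participants = config$n_participants,
      sessions = config$sessions
    )
  )
}
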