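# Shared fixtures and independent oracles, built in code at test time.

noise_free_model <- function(...) {
  participant_model(noise_frame_hz = 0, noise_trial_hz = 0, ...)
}

trial_row <- function(kind = "whole_utterance", hz = 200, onset = 0,
                      dur = if (kind == "mid_utterance") 400 else
                        if (kind == "none") NA_real_ else Inf,
                      word = "head", session = 1L, trial_index = 1L,
                      phase = "unpredictable", pid = "P01") {
  tibble::tibble(
    participant_id = pid, session = session, trial_index = trial_index,
    word = word, phase = phase, pert_kind = kind, pert_hz = hz,
    pert_onset_ms = if (kind == "none") NA_real_ else onset,
    pert_duration_ms = dur
  )
}

# Independent closed-form compensatory response: explicit piecewise scalar
# evaluation, no shared code with the simulator.
oracle_comp <- function(t_ms, p, g, t_p, dur, L, tau) {
  vapply(t_ms, function(t) {
    t_on <- t_p + L
    t_off <- t_p + dur + L
    if (t < t_on) return(0)
    if (t < t_off) return(-g * p * (1 - exp(-(t - t_on) / tau)))
    c_end <- -g * p * (1 - exp(-(t_off - t_on) / tau))
    c_end * exp(-(t - t_off) / tau)
  }, numeric(1))
}

# Brute-force single-pass reimplementation of the three normalization steps
# (explicit loops, no binning shortcuts); the oracle for pipeline equivalence.
brute_normalize <- function(f1, trend_values, pert_onset_ms, dt = 3,
                            bin_ms = 25, ref_ms = 50) {
  t_abs <- (seq_along(f1) - 1) * dt
  vals <- c()
  times <- c()
  for (k in seq_along(f1)) {
    if (t_abs[k] >= pert_onset_ms) {
      vals <- c(vals, f1[k] - trend_values[k])
      times <- c(times, t_abs[k] - pert_onset_ms)
    }
  }
  ref <- mean(vals[times < ref_ms])
  vals <- vals - ref
  out <- NULL
  b <- 0
  repeat {
    in_b <- times >= b * bin_ms & times < (b + 1) * bin_ms
    if (!any(in_b)) break
    out <- rbind(out, data.frame(bin = b, value = mean(vals[in_b])))
    b <- b + 1
  }
  keep <- out$bin <= floor((max(times) + dt) / bin_ms) - 1
  out[keep, ]
}

# Build a session element by hand from an F1 matrix and a schedule.
make_session_element <- function(f1, schedule, dt = 3, quality = NULL) {
  n <- nrow(f1)
  list(
    participant_id = schedule$participant_id[1],
    session = schedule$session[1],
    frame_interval_ms = dt,
    schedule = schedule,
    f1 = f1,
    voice_onset_frame = rep(1L, ncol(f1)),
    voice_offset_frame = rep(n, ncol(f1)),
    quality = quality %||% rep("good", ncol(f1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manual_dataset <- function(elements, ground_truth = NULL) {
  pids <- unique(vapply(elements, function(el) el$participant_id, character(1)))
  names(elements) <- vapply(elements, function(el) {
    paste(el$participant_id, el$session, sep = ".")
  }, character(1))
  new_dataset(
    participants = tibble::tibble(
      participant_id = pids, group = "plus_first", age = 25
    ),
    sessions = elements,
    ground_truth = ground_truth
  )
}

# Small simulated cohort for integration-style tests.
small_cohort <- function(n = 3, seed = 11, sessions = c(1L, 3L, 5L), ...) {
  screen_trials(simulate_cohort(
    cohort_preset("default", n_participants = n, rng_seed = seed,
                  sessions = sessions, ...)
  ))
}
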