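#' Configuration for deterministic trial-schedule generation
#'
#' Captures everything the schedule builders need: the seed, the
#' counterbalancing group deciding which perturbation direction is applied in
#' the first adaptation session, the jitter distribution for mid-utterance
#' perturbation onsets, and the per-condition trial allocation.
#'
#' The default allocation assigns each of the eight perturbed conditions
#' (mid/whole utterance crossed with -200, -50, +50, +200 Hz) 54 trials
#' (45 "head", 9 "hid"), plus 48 unperturbed trials (30 "head", 18 "hid"),
#' which reproduces the 432 perturbed / 48 unperturbed totals of the
#' five-session design.
#'
#' @param rng_seed Integer seed; identical (seed, group) yield byte-identical
#'   schedules.
#' @param counterbalance_group `"plus_first"` (+200 Hz hold perturbation in
#'   session 2, -200 Hz in session 4) or `"minus_first"` (the reverse).
#' @param jitter_range_ms Length-2 numeric, bounds of the continuous uniform
#'   onset-delay jitter for mid-utterance perturbations (ms from voice onset).
#' @param condition_allocation Data frame with columns `pert_kind`, `pert_hz`,
#'   `n_head`, `n_hid` describing perturbed-trial counts; `NULL` for the
#'   default equal allocation.
#' @param n_familiarization Number of familiarization trials opening session 1.
#' @param include_familiarization Logical; whether analysis functions should
#'   treat good "head" familiarization trials as analyzable (the default).
#' @return An object of class `schedule_config`.
#' @examples
#' cfg <- schedule_config(rng_seed = 7, counterbalance_group = "plus_first")
#' @export
schedule_config <- function(rng_seed = 1L,
                            counterbalance_group = c("plus_first", "minus_first"),
                            jitter_range_ms = c(200, 500),
                            condition_allocation = NULL,
                            n_familiarization = 15L,
                            include_familiarization = TRUE) {
  counterbalance_group <- match.arg(counterbalance_group)
  stopifnot(
    is.numeric(rng_seed), length(rng_seed) == 1, is.finite(rng_seed),
    length(jitter_range_ms) == 2, all(is.finite(jitter_range_ms)),
    jitter_range_ms[1] <= jitter_range_ms[2]
  )
  if (is.null(condition_allocation)) {
    condition_allocation <- default_condition_allocation()
  }
  needed <- c("pert_kind", "pert_hz", "n_head", "n_hid")
  if (!all(needed %in% names(condition_allocation))) {
    abort("`condition_allocation` needs columns pert_kind, pert_hz, n_head, n_hid.")
  }
  if (!all(condition_allocation$pert_kind %in% c("mid_utterance", "whole_utterance"))) {
    abort("Unknown perturbation kind in `condition_allocation`.")
  }
  if (any(condition_allocation$pert_hz == 0)) {
    abort("Perturbed conditions must have non-zero pert_hz.")
  }
  structure(
    list(
      rng_seed = as.integer(rng_seed),
      counterbalance_group = counterbalance_group,
      jitter_range_ms = as.numeric(jitter_range_ms),
      condition_allocation = tibble::as_tibble(condition_allocation),
      n_familiarization = as.integer(n_familiarization),
      include_familiarization = isTRUE(include_familiarization)
    ),
    class = "schedule_config"
  )
}

#' Default perturbed-condition allocation
#'
#' Equal allocation over the eight perturbed conditions: 54 trials each
#' (45 "head" + 9 "hid"), summing to the stated 360 "head" and 72 "hid"
#' perturbed trials.
#'
#' @return A tibble with one row per perturbed condition.
#' @export
default_condition_allocation <- function() {
  tidyr::expand_grid(
    pert_kind = c("mid_utterance", "whole_utterance"),
    pert_hz = c(-200, -50, 50, 200)
  ) |>
    dplyr::mutate(n_head = 45L, n_hid = 9L)
}

#' Construct a perturbation descriptor
#'
#' Validates the invariants tying kind, magnitude, onset delay and duration
#' together: unperturbed trials have zero magnitude; mid-utterance
#' perturbations last 400 ms and start 200-500 ms after voice onset;
#' whole-utterance perturbations start at voice onset and last for the whole
#' utterance (duration `Inf`).
#'
#' @param kind One of `"none"`, `"mid_utterance"`, `"whole_utterance"`.
#' @param magnitude_hz Signed perturbation in Hz (0 iff `kind == "none"`).
#' @param onset_delay_ms Delay from voice onset in ms.
#' @param duration_ms Duration in ms (`Inf` for whole-utterance).
#' @return A one-row tibble with columns `pert_kind`, `pert_hz`,
#'   `pert_onset_ms`, `pert_duration_ms`.
#' @export
perturbation_spec <- function(kind,
                              magnitude_hz = 0,
                              onset_delay_ms = if (kind == "mid_utterance") NA_real_ else 0,
                              duration_ms = switch(kind,
                                none = NA_real_,
                                mid_utterance = 400,
                                whole_utterance = Inf
                              )) {
  kind <- match.arg(kind, .pert_kinds)
  if ((kind == "none") != (magnitude_hz == 0)) {
    abort("kind = \"none\" if and only if magnitude is 0 Hz.")
  }
  if (kind == "mid_utterance") {
    if (!is.finite(onset_delay_ms) || onset_delay_ms < 200 || onset_delay_ms > 500) {
      abort("mid-utterance onset delay must lie in [200, 500] ms.")
    }
    if (!identical(as.numeric(duration_ms), 400)) {
      abort("mid-utterance perturbations last 400 ms.")
    }
  }
  if (kind == "whole_utterance" && !identical(as.numeric(onset_delay_ms), 0)) {
    abort("whole-utterance perturbations start at voice onset (delay 0).")
  }
  tibble::tibble(
    pert_kind = kind,
    pert_hz = as.numeric(magnitude_hz),
    pert_onset_ms = as.numeric(onset_delay_ms),
    pert_duration_ms = as.numeric(duration_ms)
  )
}

# Pool of unpredictable-session trial rows (one per scheduled trial, unshuffled).
unpredictable_trial_pool <- function(config) {
  alloc <- config$condition_allocation
  pert <- dplyr::bind_rows(
    alloc |> dplyr::reframe(
      word = rep("head", .data$n_head[1]),
      .by = c("pert_kind", "pert_hz")
    ),
    alloc |> dplyr::reframe(
      word = rep("hid", .data$n_hid[1]),
      .by = c("pert_kind", "pert_hz")
    )
  )
  unpert <- tibble::tibble(
    pert_kind = "none", pert_hz = 0,
    word = c(rep("head", 30), rep("hid", 18))
  )
  dplyr::bind_rows(pert, unpert)
}

finalize_pert_columns <- function(trials, config) {
  n_mid <- sum(trials$pert_kind == "mid_utterance")
  trials$pert_onset_ms <- dplyr::case_when(
    trials$pert_kind == "whole_utterance" ~ 0,
    TRUE ~ NA_real_
  )
  if (n_mid > 0) {
    trials$pert_onset_ms[trials$pert_kind == "mid_utterance"] <-
      runif(n_mid, config$jitter_range_ms[1], config$jitter_range_ms[2])
  }
  trials$pert_duration_ms <- dplyr::case_when(
    trials$pert_kind == "mid_utterance" ~ 400,
    trials$pert_kind == "whole_utterance" ~ Inf,
    TRUE ~ NA_real_
  )
  trials
}

#' Build the three unpredictable-perturbation sessions
#'
#' Generates the 495 trials of sessions 1, 3 and 5 (165 each). Session 1
#' opens with 15 familiarization trials sampled uniformly from the ten trial
#' types (eight perturbed conditions plus the two unperturbed word variants);
#' the remaining 480 trials hold exactly the configured perturbed/unperturbed
#' allocation (432 perturbed, 48 unperturbed by default) in an order that is
#' a pure function of (seed, participant, group).
#'
#' @param config A [schedule_config()].
#' @param participant_id Participant identifier (character scalar).
#' @return A tibble of trial specifications, one row per trial.
#' @examples
#' sched <- build_unpredictable_sessions(schedule_config(1), "P01")
#' nrow(sched) # 495
#' @export
build_unpredictable_sessions <- function(config, participant_id) {
  stopifnot(inherits(config, "schedule_config"))
  seed <- derive_seed(config$rng_seed, config$counterbalance_group,
                      participant_id, "unpredictable")
  with_rng(seed, {
    pool <- unpredictable_trial_pool(config)
    pool <- pool[sample.int(nrow(pool)), ]

    # Familiarization: uniform over the 10 trial types. Perturbed types are
    # prompted with the analysis word "head"; unperturbed types carry their
    # own word variant.
    types <- dplyr::bind_rows(
      dplyr::distinct(
        config$condition_allocation[, c("pert_kind", "pert_hz")]
      ) |> dplyr::mutate(word = "head"),
      tibble::tibble(pert_kind = "none", pert_hz = 0, word = c("head", "hid"))
    )
    fam <- types[sample.int(nrow(types), config$n_familiarization, replace = TRUE), ]

    n1 <- 165L - config$n_familiarization
    sessions <- list(
      `1` = dplyr::bind_rows(fam, pool[seq_len(n1), ]),
      `3` = pool[n1 + seq_len(165L), ],
      `5` = pool[n1 + 165L + seq_len(165L), ]
    )
    out <- dplyr::bind_rows(lapply(names(sessions), function(s) {
      trials <- sessions[[s]]
      trials$session <- as.integer(s)
      trials$trial_index <- seq_len(nrow(trials))
      trials$phase <- "unpredictable"
      if (s == "1") {
        trials$phase[seq_len(config$n_familiarization)] <- "familiarization"
      }
      trials
    }))
    out$participant_id <- participant_id
    out <- finalize_pert_columns(out, config)
    out[, .schedule_cols]
  })
}

#' Build one adaptation session (baseline / hold / washout)
#'
#' 165 trials: a 42-trial unperturbed baseline phase (30 "head", 12 "hid"),
#' an 81-trial hold phase (60 "head", 21 "hid") carrying the session's single
#' whole-utterance +/-200 Hz perturbation, and a 42-trial unperturbed washout
#' phase. Word order is randomized independently within each phase. The hold
#' direction follows the counterbalancing group: `"plus_first"` receives
#' +200 Hz in session 2 and -200 Hz in session 4.
#'
#' @inheritParams build_unpredictable_sessions
#' @param session Session index, 2 or 4.
#' @return A tibble of trial specifications.
#' @export
build_adaptation_session <- function(config, participant_id, session) {
  stopifnot(inherits(config, "schedule_config"))
  if (!session %in% c(2L, 4L)) {
    abort("Adaptation sessions are sessions 2 and 4.")
  }
  session <- as.integer(session)
  plus_first <- config$counterbalance_group == "plus_first"
  hold_hz <- if ((session == 2L) == plus_first) 200 else -200

  seed <- derive_seed(config$rng_seed, config$counterbalance_group,
                      participant_id, "adaptation", session)
  with_rng(seed, {
    phase_block <- function(phase, n_head, n_hid, hz) {
      words <- sample(c(rep("head", n_head), rep("hid", n_hid)))
      tibble::tibble(
        word = words,
        phase = phase,
        pert_kind = if (hz == 0) "none" else "whole_utterance",
        pert_hz = hz
      )
    }
    out <- dplyr::bind_rows(
      phase_block("baseline", 30L, 12L, 0),
      phase_block("hold", 60L, 21L, hold_hz),
      phase_block("washout", 30L, 12L, 0)
    )
    out$participant_id <- participant_id
    out$session <- session
    out$trial_index <- seq_len(nrow(out))
    out <- finalize_pert_columns(out, config)
    out[, .schedule_cols]
  })
}

#' Build the full five-session schedule for one participant
#'
#' @inheritParams build_unpredictable_sessions
#' @return A tibble with all 825 trials, ordered by session and trial index.
#' @export
build_schedule <- function(config, participant_id) {
  dplyr::bind_rows(
    build_unpredictable_sessions(config, participant_id),
    build_adaptation_session(config, participant_id, 2L),
    build_adaptation_session(config, participant_id, 4L)
  ) |>
    dplyr::arrange(.data$session, .data$trial_index)
}

#' Number the "head" trials of a schedule
#'
#' Analysis windows in adaptation sessions are indexed by "head"-trial
#' ordinal (e.g. "head trials 76-90"); catch ("hid") trials are skipped.
#'
#' @param schedule A single-session schedule tibble.
#' @return A tibble with columns `trial_index` and `head_ordinal`, one row
#'   per "head" trial, numbered 1..n in session order.
#' @examples
#' sched <- build_adaptation_session(schedule_config(1), "P01", 2)
#' max(head_trial_ordinals(sched)$head_ordinal) # 120
#' @export
head_trial_ordinals <- function(schedule) {
  if (nrow(schedule) == 0) {
    return(tibble::tibble(trial_index = integer(), head_ordinal = integer()))
  }
  schedule <- schedule[order(schedule$trial_index), ]
  heads <- schedule$word == "head"
  tibble::tibble(
    trial_index = schedule$trial_index[heads],
    head_ordinal = seq_len(sum(heads))
  )
}

#' Write / read a trial schedule as CSV
#'
#' UTF-8, header row, dot decimal separator; `pert_duration_ms` uses `Inf`
#' for whole-utterance perturbations and is empty for unperturbed trials.
#'
#' @param schedule A schedule tibble.
#' @param path Output CSV path.
#' @param rng_seed Seed recorded alongside each row for provenance.
#' @return `path`, invisibly (`read_schedule` returns the schedule tibble).
#' @export
write_schedule <- function(schedule, path, rng_seed = NA_integer_) {
  out <- schedule
  out$rng_seed <- as.integer(rng_seed)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sch <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session = readr::col_integer(),
      trial_index = readr::col_integer(),
      word = readr::col_character(),
      phase = readr::col_character(),
      pert_kind = readr::col_character(),
      pert_hz = readr::col_double(),
      pert_onset_ms = readr::col_double(),
      pert_duration_ms = readr::col_double(),
      rng_seed = readr::col_integer()
    ),
    progress = FALSE
  )
  bad <- setdiff(unique(sch$pert_kind), .pert_kinds)
  if (length(bad)) abort(paste0("Unknown perturbation kind in schedule: ", bad[1]))
  sch[, intersect(c(.schedule_cols, "rng_seed"), names(sch))]
}
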