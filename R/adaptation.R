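# Per-trial mean F1 over the half-open window [lo_ms, hi_ms) from voice
# onset. NA where a trial does not fully cover the window.
window_mean_by_trial <- function(el, lo_ms, hi_ms) {
  dt <- el$frame_interval_ms
  n_tr <- ncol(el$f1)
  out <- rep(NA_real_, n_tr)
  off0 <- as.integer(ceiling(lo_ms / dt - 1e-9))
  off1 <- as.integer(ceiling(hi_ms / dt - 1e-9)) - 1L
  for (j in seq_len(n_tr)) {
    k <- el$voice_onset_frame[j] + off0:off1
    if (k[1] < el$voice_onset_frame[j] || k[length(k)] > el$voice_offset_frame[j]) next
    out[j] <- mean(el$f1[k, j])
  }
  out
}

# The adaptation-session element whose hold-phase perturbation matches the
# requested direction.
adaptation_session_for <- function(dataset, participant, direction) {
  els <- participant_sessions(dataset, participant, c(2L, 4L))
  for (el in els) {
    hold_hz <- unique(el$schedule$pert_hz[el$schedule$phase == "hold"])
    if (length(hold_hz) == 1 && hold_hz == direction) return(el)
  }
  abort(paste0("No adaptation session with a ", direction,
               " Hz hold perturbation for participant ", participant, "."))
}

#' Across-trial sensorimotor adaptation trajectory for one participant
#'
#' Computes, for the adaptation session with the given hold direction: the
#' mean F1 over the first `early_ms` (default 75 ms, before any within-trial
#' feedback response can begin) of every "head" trial; the baseline
#' reference (mean of those early means over "head" trials 1-30); the
#' baseline-normalized trajectory; its smoothing over non-overlapping
#' `smooth_trials`-trial windows (a trailing remainder shorter than the
#' window is dropped); and the late-hold adaptation percentage from "head"
#' trials 76-90, converted with the same compMult convention as peak
#' compensation.
#'
#' @param dataset An `fpl_dataset`.
#' @param participant Participant id.
#' @param direction Signed hold perturbation in Hz (+200 or -200).
#' @param early_ms Early feedforward window length (ms from voice onset).
#' @param smooth_trials Smoothing window in "head" trials.
#' @param late_trials "Head"-trial ordinals defining the late hold phase.
#' @param baseline_trials Ordinals defining the baseline reference.
#' @param max_missing Maximum missing trials tolerated per 15-trial window.
#' @return An object of class `adaptation_record`: list with `trajectory`
#'   (tibble: `head_ordinal`, `trial_index`, `phase`, `early_hz`, `norm_hz`),
#'   `smoothed` (tibble: `window_index`, `head_ordinal_mid`, `norm_hz`),
#'   `baseline_ref_hz`, `adaptation_pct`, `direction`, `session`.
#' @export
adaptation_trajectory <- function(dataset, participant, direction,
                                  early_ms = 75, smooth_trials = 5,
                                  late_trials = 76:90,
                                  baseline_trials = 1:30,
                                  max_missing = 3) {
  el <- adaptation_session_for(dataset, participant, direction)
  ords <- head_trial_ordinals(el$schedule)
  n_head <- nrow(ords)
  early_all <- window_mean_by_trial(el, 0, early_ms)
  good <- el$quality == "good"
  col <- match(ords$trial_index, el$schedule$trial_index)
  early <- ifelse(good[col], early_all[col], NA_real_)

  base_avail <- sum(!is.na(early[baseline_trials]))
  if (base_avail < length(baseline_trials) - 2 * max_missing) {
    abort(paste0("Too few baseline 'head' trials for participant ",
                 participant, "."))
  }
  ref <- mean(early[baseline_trials], na.rm = TRUE)
  norm <- early - ref

  nwin <- floor(n_head / smooth_trials)
  win_id <- rep(seq_len(nwin), each = smooth_trials)
  smoothed <- tibble::tibble(
    window_index = seq_len(nwin),
    head_ordinal_mid = (seq_len(nwin) - 0.5) * smooth_trials + 0.5,
    norm_hz = as.vector(tapply(norm[seq_len(nwin * smooth_trials)], win_id,
                               mean, na.rm = TRUE))
  )
  late <- norm[late_trials]
  if (sum(!is.na(late)) < length(late_trials) - max_missing) {
    abort(paste0("Too many missing late-hold trials for participant ",
                 participant, "."))
  }
  structure(
    list(
      participant_id = participant,
      direction = direction,
      session = el$session,
      trajectory = tibble::tibble(
        head_ordinal = ords$head_ordinal,
        trial_index = ords$trial_index,
        phase = el$schedule$phase[col],
        early_hz = early,
        norm_hz = norm
      ),
      smoothed = smoothed,
      baseline_ref_hz = ref,
      adaptation_pct = percent_compensation(mean(late, na.rm = TRUE), direction)
    ),
    class = "adaptation_record"
  )
}

#' Cohort adaptation table and per-direction summary
#'
#' Computes every participant's late-hold adaptation percentage for each
#' perturbation direction, with the baseline F1 covariate (mean early-window
#' F1 over the baseline phase) and age, and summarises each direction with
#' mean, SEM and a two-tailed one-sample t-test against zero.
#'
#' @inheritParams adaptation_trajectory
#' @param participants Participants to analyse (default all).
#' @param directions Hold directions to analyse.
#' @return An object of class `fpl_adaptation`: list with `table`
#'   (participant x direction), `summary` (per direction), and `records`
#'   (the underlying [adaptation_trajectory()] objects).
#' @export
adaptation_table <- function(dataset, participants = NULL,
                             directions = c(-200, 200), ...) {
  participants <- participants %||% dataset$participants$participant_id
  records <- list()
  rows <- list()
  for (pid in participants) {
    for (d in directions) {
      rec <- adaptation_trajectory(dataset, pid, d, ...)
      records[[paste(pid, d)]] <- rec
      rows[[paste(pid, d)]] <- tibble::tibble(
        participant_id = pid,
        direction = d,
        adaptation_pct = rec$adaptation_pct,
        baseline_f1 = rec$baseline_ref_hz
      )
    }
  }
  table <- dplyr::bind_rows(rows) |>
    dplyr::left_join(dataset$participants[, c("participant_id", "age")],
                     by = "participant_id")
  summary <- table |>
    dplyr::reframe(tidy_ttest(one_sample_t(.data$adaptation_pct)),
                   .by = "direction")
  structure(list(table = table, summary = summary, records = records),
            class = "fpl_adaptation")
}

#' @export
print.fpl_adaptation <- function(x, ...) {
  cat("<fpl_adaptation>\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Exclude outlier participants by adaptation response
#'
#' Removes participants whose adaptation percentage lies more than
#' `n_sd` standard deviations (computed about the mean) from the cohort
#' median, separately per direction, in a single pass; the union of
#' per-direction removals is excluded.
#'
#' @param adaptation An `fpl_adaptation` or its `table` tibble (columns
#'   `participant_id`, `direction`, `adaptation_pct`).
#' @param n_sd Threshold in standard deviations (default 3).
#' @return A list with `kept` (participant ids), `removed` (tibble naming
#'   each removed participant with the offending value, cohort median and
#'   SD), and `n_sd`.
#' @export
exclude_outlier_participants <- function(adaptation, n_sd = 3) {
  tbl <- if (inherits(adaptation, "fpl_adaptation")) adaptation$table else
    tibble::as_tibble(adaptation)
  if (length(unique(tbl$participant_id)) < 3) {
    abort("Outlier screening needs at least three participants.")
  }
  flagged <- tbl |>
    dplyr::mutate(
      cohort_median = median(.data$adaptation_pct),
      cohort_sd = sd(.data$adaptation_pct),
      .by = "direction"
    ) |>
    dplyr::filter(
      .data$cohort_sd > 0,
      abs(.data$adaptation_pct - .data$cohort_median) > n_sd * .data$cohort_sd
    )
  removed_ids <- unique(flagged$participant_id)
  list(
    kept = setdiff(unique(tbl$participant_id), removed_ids),
    removed = flagged[, c("participant_id", "direction", "adaptation_pct",
                          "cohort_median", "cohort_sd")],
    n_sd = n_sd
  )
}

#' Select positive responders
#'
#' Participants who both positively compensated for the whole-utterance
#' unpredictable perturbation of the given direction and positively adapted
#' to the consistent perturbation of the same direction.
#'
#' @param compensation An `fpl_compensation` or its `table` tibble.
#' @param adaptation An `fpl_adaptation` or its `table` tibble.
#' @param direction Signed perturbation in Hz (+200 or -200).
#' @return Character vector of participant ids (sorted).
#' @export
select_positive_responders <- function(compensation, adaptation, direction) {
  ctab <- if (inherits(compensation, "fpl_compensation")) compensation$table else
    tibble::as_tibble(compensation)
  atab <- if (inherits(adaptation, "fpl_adaptation")) adaptation$table else
    tibble::as_tibble(adaptation)
  comp_pos <- ctab$participant_id[
    ctab$pert_kind == "whole_utterance" & ctab$pert_hz == direction &
      ctab$peak_compensation_pct > 0
  ]
  adapt_pos <- atab$participant_id[
    atab$direction == direction & atab$adaptation_pct > 0
  ]
  sort(intersect(comp_pos, adapt_pos))
}

#' Within-trial response dynamics across adaptation phases
#'
#' For each selected participant, averages the within-trial F1 time-course
#' (voice-onset aligned) over the "head" trials of each analysis phase --
#' late baseline (ordinals 16-30), early adaptation (31-45), late adaptation
#' (76-90) and late washout (106-120) -- and normalizes it by subtracting
#' the participant's mean time-course over "head" trials 1-30. Window means
#' at onset (`O`, 0-75 ms) and mid-utterance (`M`, 600-800 ms) are expressed
#' as percent compensation. A trial truncated before a window contributes to
#' the windows it covers and is dropped from the others.
#'
#' @param dataset An `fpl_dataset`.
#' @param participants Responder subset (non-empty).
#' @param direction Signed hold perturbation in Hz.
#' @param phases Named list of "head"-trial ordinal ranges.
#' @param windows Named list of half-open ms windows from voice onset.
#' @param baseline_trials Ordinals of the normalization reference.
#' @param max_missing Maximum missing trials per 15-trial phase window.
#' @param bin_ms Bin width for the output time-courses.
#' @return An object of class `fpl_dynamics`: list with `windows`
#'   (participant x phase x window percent compensation), `group_windows`
#'   (mean, SEM, t per phase x window), `timecourses` (participant binned
#'   normalized time-courses) and `group_timecourses`.
#' @export
phase_dynamics <- function(dataset, participants, direction,
                           phases = list(
                             late_baseline = 16:30,
                             early_adapt = 31:45,
                             late_adapt = 76:90,
                             late_washout = 106:120
                           ),
                           windows = list(O = c(0, 75), M = c(600, 800)),
                           baseline_trials = 1:30,
                           max_missing = 3,
                           bin_ms = 25) {
  if (length(participants) == 0) {
    abort("Responder subset is empty; no dynamics to compute.")
  }
  win_rows <- list()
  tc_rows <- list()
  for (pid in participants) {
    el <- adaptation_session_for(dataset, pid, direction)
    ords <- head_trial_ordinals(el$schedule)
    col <- match(ords$trial_index, el$schedule$trial_index)
    good <- el$quality[col] == "good"
    dt <- el$frame_interval_ms

    wmeans <- lapply(windows, function(w) {
      v <- window_mean_by_trial(el, w[1], w[2])[col]
      ifelse(good, v, NA_real_)
    })
    ref_w <- lapply(wmeans, function(v) mean(v[baseline_trials], na.rm = TRUE))

    n_fr <- nrow(el$f1)
    t_ms <- (seq_len(n_fr) - 1) * dt # simulated markers put onset at frame 1
    ref_cols <- col[baseline_trials][good[baseline_trials]]
    ref_tc <- rowMeans(el$f1[, ref_cols, drop = FALSE])

    for (ph in names(phases)) {
      sel_ord <- phases[[ph]]
      for (wn in names(windows)) {
        v <- wmeans[[wn]][sel_ord]
        if (sum(!is.na(v)) < length(sel_ord) - max_missing) {
          abort(paste0("Too many missing trials in phase ", ph,
                       " (window ", wn, ") for participant ", pid, "."))
        }
        win_rows[[length(win_rows) + 1L]] <- tibble::tibble(
          participant_id = pid, direction = direction, phase = ph,
          window = wn,
          pct = percent_compensation(mean(v, na.rm = TRUE) - ref_w[[wn]],
                                     direction)
        )
      }
      ph_cols <- col[sel_ord][good[sel_ord]]
      tc <- rowMeans(el$f1[, ph_cols, drop = FALSE]) - ref_tc
      bin <- floor(t_ms / bin_ms)
      agg <- rowsum(cbind(tc, 1), bin)
      bins <- as.integer(rownames(agg))
      tc_rows[[length(tc_rows) + 1L]] <- tibble::tibble(
        participant_id = pid, direction = direction, phase = ph,
        time_ms = bins * bin_ms,
        time_mid_ms = bins * bin_ms + bin_ms / 2,
        value = agg[, 1] / agg[, 2]
      )
    }
  }
  windows_tbl <- dplyr::bind_rows(win_rows)
  timecourses <- dplyr::bind_rows(tc_rows)
  group_windows <- windows_tbl |>
    dplyr::reframe(tidy_ttest(one_sample_t(.data$pct)),
                   .by = c("direction", "phase", "window"))
  group_timecourses <- timecourses |>
    dplyr::summarise(
      mean = mean(.data$value), sem = sem(.data$value),
      n = dplyr::n(),
      .by = c("direction", "phase", "time_ms", "time_mid_ms")
    )
  structure(
    list(
      direction = direction, participants = participants,
      windows = windows_tbl, group_windows = group_windows,
      timecourses = timecourses, group_timecourses = group_timecourses
    ),
    class = "fpl_dynamics"
  )
}
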