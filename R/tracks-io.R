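#' Construct an analysis dataset
#'
#' The central container: participant metadata, per participant-session track
#' sets (schedule, frames-by-trials F1 matrix, voice markers, quality flags),
#' an optional ground-truth table (for simulated cohorts), and provenance.
#'
#' @param participants Tibble with `participant_id`, `group`, `age`.
#' @param sessions Named list (`"<pid>.<session>"`) of session elements.
#' @param ground_truth Optional tibble of true generating parameters.
#' @param provenance List recording seed and configuration hash.
#' @return An object of class `fpl_dataset`.
#' @export
new_dataset <- function(participants, sessions, ground_truth = NULL,
                        provenance = list()) {
  structure(
    list(
      participants = tibble::as_tibble(participants),
      sessions = sessions,
      ground_truth = if (!is.null(ground_truth)) tibble::as_tibble(ground_truth),
      provenance = provenance
    ),
    class = "fpl_dataset"
  )
}

#' @export
print.fpl_dataset <- function(x, ...) {
  n_tr <- sum(vapply(x$sessions, function(el) nrow(el$schedule), integer(1)))
  cat(sprintf(
    "<fpl_dataset> %d participants, %d session track sets, %d trials\n",
    nrow(x$participants), length(x$sessions), n_tr
  ))
  invisible(x)
}

# All session elements for one participant, optionally restricted to sessions.
participant_sessions <- function(dataset, participant, sessions = NULL) {
  els <- Filter(function(el) el$participant_id == participant, dataset$sessions)
  if (!is.null(sessions)) {
    els <- Filter(function(el) el$session %in% sessions, els)
  }
  els
}

# Logical index of analyzable trials in a session element: good "head"
# trials, with familiarization trials included or not.
analyzable_idx <- function(el, include_familiarization = TRUE) {
  ok <- el$schedule$word == "head" & el$quality == "good"
  if (!include_familiarization) {
    ok <- ok & el$schedule$phase != "familiarization"
  }
  ok
}

# Times (ms relative to voice onset) of the frame rows for trial j of el.
track_times <- function(el, j) {
  (seq_len(nrow(el$f1)) - el$voice_onset_frame[j]) * el$frame_interval_ms
}

#' Write a dataset to plain-text files
#'
#' One TSV per participant-session with columns `trial_index`, `frame`,
#' `time_ms`, `f1_hz` (full-precision floats), a JSON sidecar with the frame
#' interval, voice markers, quality flags and the trial specifications, a
#' per-participant schedule CSV, plus cohort-level `participants.csv`,
#' `ground_truth.csv` and `provenance.json`.
#'
#' @param dataset An `fpl_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(dataset$participants, file.path(dir, "participants.csv"),
                   progress = FALSE)
  if (!is.null(dataset$ground_truth)) {
    readr::write_csv(dataset$ground_truth, file.path(dir, "ground_truth.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(dataset$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (key in names(dataset$sessions)) {
    el <- dataset$sessions[[key]]
    stub <- sprintf("%s_s%d", el$participant_id, el$session)
    n_fr <- nrow(el$f1)
    long <- tibble::tibble(
      trial_index = rep(el$schedule$trial_index, each = n_fr),
      frame = rep(seq_len(n_fr), ncol(el$f1)),
      time_ms = rep(seq_len(n_fr) - 1, ncol(el$f1)) * el$frame_interval_ms -
        rep((el$voice_onset_frame - 1) * el$frame_interval_ms, each = n_fr),
      f1_hz = sprintf("%.17g", as.vector(el$f1))
    )
    readr::write_tsv(long, file.path(dir, paste0("tracks_", stub, ".tsv")),
                     progress = FALSE)
    sched_json <- el$schedule
    # JSON has no Inf: the whole-utterance duration sentinel goes as a string
    sched_json$pert_duration_ms <- as.character(sched_json$pert_duration_ms)
    meta <- list(
      participant_id = el$participant_id,
      session = el$session,
      frame_interval_ms = el$frame_interval_ms,
      voice_onset_frame = el$voice_onset_frame,
      voice_offset_frame = el$voice_offset_frame,
      quality = el$quality,
      trials = sched_json,
      true_states = el$true_states
    )
    jsonlite::write_json(meta, file.path(dir, paste0("meta_", stub, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  for (pid in unique(dataset$participants$participant_id)) {
    els <- participant_sessions(dataset, pid)
    if (length(els)) {
      sched <- dplyr::bind_rows(lapply(els, function(el) el$schedule))
      write_schedule(sched, file.path(dir, paste0("schedule_", pid, ".csv")),
                     rng_seed = dataset$provenance$rng_seed %||% NA_integer_)
    }
  }
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#'
#' Validates the declared dialects: every track must join exactly one
#' scheduled trial, voice-onset markers must be present, and the frame grid
#' must be uniform at the declared interval.
#'
#' @param dir Directory containing the files.
#' @return An `fpl_dataset`.
#' @export
load_dataset <- function(dir) {
  participants <- readr::read_csv(
    file.path(dir, "participants.csv"),
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      age = readr::col_double()
    ), progress = FALSE
  )
  gt_path <- file.path(dir, "ground_truth.csv")
  ground_truth <- if (file.exists(gt_path)) {
    readr::read_csv(gt_path, show_col_types = FALSE, progress = FALSE)
  }
  prov_path <- file.path(dir, "provenance.json")
  provenance <- if (file.exists(prov_path)) {
    jsonlite::read_json(prov_path, simplifyVector = TRUE)
  } else list()

  sessions <- list()
  for (meta_file in sort(list.files(dir, "^meta_.*\\.json$", full.names = TRUE))) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    stub <- sub("^meta_(.*)\\.json$", "\\1", basename(meta_file))
    tracks_file <- file.path(dir, paste0("tracks_", stub, ".tsv"))
    if (!file.exists(tracks_file)) {
      abort(paste0("Missing track file for ", stub, "."))
    }
    long <- readr::read_tsv(
      tracks_file,
      col_types = readr::cols(
        trial_index = readr::col_integer(),
        frame = readr::col_integer(),
        time_ms = readr::col_double(),
        f1_hz = readr::col_character() # parsed below: exact strtod round-trip
      ), progress = FALSE
    )
    long$f1_hz <- as.numeric(long$f1_hz)
    sched <- tibble::as_tibble(meta$trials)
    sched$session <- as.integer(sched$session)
    sched$trial_index <- as.integer(sched$trial_index)
    sched$pert_duration_ms <- as.numeric(sched$pert_duration_ms)
    if (!"pert_onset_ms" %in% names(sched)) sched$pert_onset_ms <- NA_real_
    sched$pert_onset_ms <- as.numeric(sched$pert_onset_ms)
    orphan <- setdiff(unique(long$trial_index), sched$trial_index)
    if (length(orphan)) {
      abort(paste0("Track without a scheduled trial in ", stub, ": trial ",
                   orphan[1], "."))
    }
    n_tr <- nrow(sched)
    onset <- as.integer(meta$voice_onset_frame)
    if (length(onset) != n_tr || anyNA(onset)) {
      bad <- if (length(onset) == n_tr) sched$trial_index[which(is.na(onset))[1]] else NA
      abort(paste0("Missing voice_onset marker in ", stub,
                   if (!is.na(bad)) paste0(" (trial ", bad, ")"), "."))
    }
    counts <- table(long$trial_index)
    if (length(unique(counts)) != 1) {
      abort(paste0("Ragged frame counts in ", stub, "."))
    }
    n_fr <- as.integer(counts[1])
    long <- long[order(long$trial_index, long$frame), ]
    dt <- diff(long$time_ms[seq_len(min(n_fr, nrow(long)))])
    if (n_fr > 2 && max(abs(dt - meta$frame_interval_ms)) > 1e-9) {
      abort(paste0("Non-uniform frame grid in ", stub, "."))
    }
    f1 <- matrix(long$f1_hz, nrow = n_fr,
                 dimnames = NULL)
    # column order follows sorted trial_index; align to schedule order
    ord <- match(sched$trial_index, sort(unique(long$trial_index)))
    f1 <- f1[, ord, drop = FALSE]
    sessions[[paste(meta$participant_id, meta$session, sep = ".")]] <- list(
      participant_id = meta$participant_id,
      session = as.integer(meta$session),
      frame_interval_ms = meta$frame_interval_ms,
      schedule = sched,
      f1 = f1,
      voice_onset_frame = onset,
      voice_offset_frame = as.integer(meta$voice_offset_frame),
      quality = as.character(meta$quality),
      true_states = meta$true_states
    )
  }
  new_dataset(participants, sessions, ground_truth, provenance)
}

#' Screen trials for analyzability
#'
#' Applies the automatic exclusion rules: trials already flagged `excluded`,
#' trials with non-finite F1 between voice onset and offset, and trials with
#' missing voice markers are excluded. Screening is idempotent and purely
#' additive (a good trial is never un-excluded). Window-specific coverage
#' (a trial usable for an early analysis window but truncated before a late
#' one) is handled by the individual analyses, which check coverage per
#' window.
#'
#' @param dataset An `fpl_dataset`.
#' @return The dataset with updated quality flags and a `screening` element:
#'   a per-participant report of "head"-trial exclusion counts and
#'   percentages.
#' @export
screen_trials <- function(dataset) {
  for (key in names(dataset$sessions)) {
    el <- dataset$sessions[[key]]
    n_tr <- ncol(el$f1)
    excl <- el$quality != "good"
    for (j in seq_len(n_tr)) {
      if (excl[j]) next
      on <- el$voice_onset_frame[j]
      off <- el$voice_offset_frame[j]
      if (is.na(on) || is.na(off) || off < on) {
        excl[j] <- TRUE
      } else if (!all(is.finite(el$f1[on:off, j]))) {
        excl[j] <- TRUE
      }
    }
    el$quality[excl] <- "excluded"
    dataset$sessions[[key]] <- el
  }
  report <- dplyr::bind_rows(lapply(dataset$sessions, function(el) {
    heads <- el$schedule$word == "head"
    tibble::tibble(
      participant_id = el$participant_id,
      session = el$session,
      n_head = sum(heads),
      n_excluded = sum(heads & el$quality != "good")
    )
  })) |>
    dplyr::summarise(
      n_head = sum(.data$n_head),
      n_excluded = sum(.data$n_excluded),
      pct_excluded = 100 * sum(.data$n_excluded) / sum(.data$n_head),
      .by = "participant_id"
    )
  dataset$screening <- report
  dataset
}

#' Count analyzable trials in a dataset
#'
#' Analyzable trials are good "head" trials; catch ("hid") trials and
#' excluded trials never enter analyses.
#'
#' @param dataset An `fpl_dataset`.
#' @param include_familiarization Count good "head" familiarization trials?
#' @return Integer count.
#' @export
n_analyzable_trials <- function(dataset, include_familiarization = TRUE) {
  sum(vapply(
    dataset$sessions,
    function(el) sum(analyzable_idx(el, include_familiarization)),
    integer(1)
  ))
}
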