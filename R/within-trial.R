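#' Participant F1 trend from unperturbed trials
#'
#' The average F1 response across a participant's good unperturbed "head"
#' trials in the unpredictable sessions, after re-referencing each trial to
#' its value at voice onset (so the trend has F1(t = 0) = 0 Hz). Subtracting
#' this trend from every trial removes the participant's shared deterministic
#' trajectory (e.g. the vowel-onset transient).
#'
#' @param dataset An `fpl_dataset`.
#' @param participant Participant id.
#' @param sessions Sessions to pool (default the unpredictable sessions).
#' @param include_familiarization Include good unperturbed "head"
#'   familiarization trials.
#' @return An object of class `f1_trend`: list with `values` (Hz, indexed by
#'   frame offset from voice onset; defined on frames covered by at least one
#'   trial), `frame_interval_ms` and `n_trials`.
#' @export
unperturbed_trend <- function(dataset, participant, sessions = c(1L, 3L, 5L),
                              include_familiarization = TRUE) {
  els <- participant_sessions(dataset, participant, sessions)
  sums <- NULL
  counts <- NULL
  dt <- NULL
  n_used <- 0L
  for (el in els) {
    idx <- which(analyzable_idx(el, include_familiarization) &
                   el$schedule$pert_kind == "none")
    if (!length(idx)) next
    dt <- dt %||% el$frame_interval_ms
    for (j in idx) {
      on <- el$voice_onset_frame[j]
      off <- el$voice_offset_frame[j]
      y <- el$f1[on:off, j]
      y <- y - y[1]
      if (is.null(sums)) {
        sums <- numeric(0); counts <- numeric(0)
      }
      if (length(y) > length(sums)) {
        sums <- c(sums, numeric(length(y) - length(sums)))
        counts <- c(counts, numeric(length(y) - length(counts)))
      }
      sums[seq_along(y)] <- sums[seq_along(y)] + y
      counts[seq_along(y)] <- counts[seq_along(y)] + 1
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) {
    abort(paste0("No good unperturbed 'head' trials for participant ",
                 participant, "; cannot estimate the F1 trend."))
  }
  structure(
    list(values = sums / counts, frame_interval_ms = dt, n_trials = n_used),
    class = "f1_trend"
  )
}

#' Normalize one trial's F1 track
#'
#' The three linear normalization steps applied to every analyzable trial:
#' (1) subtract the participant's unperturbed F1 trend (both aligned at voice
#' onset); (2) re-align time zero to the perturbation onset and subtract the
#' mean of the first `ref_ms` (default 50 ms) of post-onset data, a window
#' before any compensatory response can begin; (3) average within
#' non-overlapping `bin_ms` (default 25 ms) bins anchored at the perturbation
#' onset, frames being assigned to bins by half-open membership of their
#' timestamps.
#'
#' @param f1 Numeric vector of F1 values (Hz) on the uniform frame grid.
#' @param trend An [unperturbed_trend()] result (or numeric vector of trend
#'   values indexed from voice onset).
#' @param pert_onset_ms Perturbation onset in ms after voice onset (0 for
#'   whole-utterance perturbations; use 0 to align unperturbed trials at
#'   voice onset).
#' @param frame_interval_ms Frame interval in ms.
#' @param voice_onset_frame,voice_offset_frame Voice markers (frame indices).
#' @param bin_ms,ref_ms Bin width and reference-window length in ms.
#' @return A tibble with one row per complete bin: `bin`, `time_ms` (bin
#'   start relative to perturbation onset), `time_mid_ms` (bin centre),
#'   `value` (normalized F1 deviation, Hz), `n_frames`.
#' @export
normalize_trial <- function(f1, trend, pert_onset_ms,
                            frame_interval_ms = 3,
                            voice_onset_frame = 1L,
                            voice_offset_frame = length(f1),
                            bin_ms = 25, ref_ms = 50) {
  tr <- if (inherits(trend, "f1_trend")) trend$values else trend
  t_ms <- (seq_along(f1) - voice_onset_frame) * frame_interval_ms
  keep <- t_ms >= pert_onset_ms & seq_along(f1) >= voice_onset_frame &
    seq_along(f1) <= voice_offset_frame
  if (!any(keep)) abort("Track does not cover the perturbation onset.")
  tr_idx <- (which(keep) - voice_onset_frame) + 1L
  if (max(tr_idx) > length(tr)) {
    abort("Trend does not cover the trial's frames.")
  }
  y <- f1[keep] - tr[tr_idx]
  t_rel <- t_ms[keep] - pert_onset_ms
  in_ref <- t_rel < ref_ms
  if (!any(in_ref)) {
    abort("Track does not cover the post-onset reference window.")
  }
  y <- y - mean(y[in_ref])
  bin <- floor(t_rel / bin_ms)
  agg <- rowsum(cbind(y, 1), bin)
  bins <- as.integer(rownames(agg))
  t_last <- max(t_rel)
  max_complete <- floor((t_last + frame_interval_ms) / bin_ms) - 1
  out <- tibble::tibble(
    bin = bins,
    time_ms = bins * bin_ms,
    time_mid_ms = bins * bin_ms + bin_ms / 2,
    value = agg[, 1] / agg[, 2],
    n_frames = as.integer(agg[, 2])
  )
  out[out$bin <= max_complete, ]
}

# Vectorized engine: binned, normalized values for the trials `idx` of one
# session element. Returns values/counts matrices (bins x trials; bin b in
# row b+1) plus each trial's last complete bin.
binned_normalized <- function(el, trend, idx, bin_ms = 25, ref_ms = 50) {
  tr <- if (inherits(trend, "f1_trend")) trend$values else trend
  dt <- el$frame_interval_ms
  n_fr <- nrow(el$f1)
  onset <- el$voice_onset_frame[idx]
  offset <- el$voice_offset_frame[idx]
  tp <- el$schedule$pert_onset_ms[idx]
  tp[is.na(tp)] <- 0
  k0 <- onset + as.integer(ceiling(tp / dt - 1e-9))
  k1 <- offset
  nkeep <- k1 - k0 + 1L
  if (any(nkeep * dt <= ref_ms)) {
    abort("A trial does not cover the post-onset reference window.")
  }
  col0 <- (idx - 1L) * n_fr
  flat <- sequence(nkeep, from = k0 + col0)
  frame_idx <- sequence(nkeep, from = k0)
  rel_frame <- frame_idx - rep(onset, nkeep) + 1L
  if (max(rel_frame) > length(tr)) {
    abort("Trend does not cover the trials' frames.")
  }
  y <- as.vector(el$f1)[flat] - tr[rel_frame]
  tid <- rep(seq_along(idx), nkeep)
  t_rel <- (rel_frame - 1L) * dt - rep(tp, nkeep)

  in_ref <- t_rel < ref_ms
  ref_sum <- rowsum(y[in_ref], tid[in_ref])
  ref_n <- rowsum(rep(1, sum(in_ref)), tid[in_ref])
  ref_mean <- as.vector(ref_sum / ref_n)[match(seq_along(idx),
                                               as.integer(rownames(ref_sum)))]
  y <- y - ref_mean[tid]

  bin <- as.integer(floor(t_rel / bin_ms))
  key <- (tid - 1L) * 100000L + bin
  agg <- rowsum(cbind(y, 1), key)
  ukey <- as.integer(rownames(agg))
  vb <- ukey %% 100000L
  vt <- ukey %/% 100000L + 1L
  nb <- max(vb) + 1L
  values <- matrix(NA_real_, nb, length(idx))
  counts <- matrix(0L, nb, length(idx))
  values[cbind(vb + 1L, vt)] <- agg[, 1] / agg[, 2]
  counts[cbind(vb + 1L, vt)] <- as.integer(agg[, 2])
  t_last <- (k1 - onset) * dt - tp
  list(
    values = values, counts = counts,
    max_complete_bin = as.integer(floor((t_last + dt) / bin_ms) - 1L),
    bin_ms = bin_ms
  )
}

#' Per-participant and group condition-averaged time-courses
#'
#' Normalizes every analyzable perturbed trial (see [normalize_trial()]),
#' groups trials by condition (perturbation kind x signed magnitude), and
#' averages within participants, then across participants (mean and SEM per
#' bin). Only bins complete for every contributing trial (and, at group
#' level, present for every participant) are kept.
#'
#' @param dataset An `fpl_dataset`.
#' @param sessions Unpredictable sessions to pool (default 1, 3, 5).
#' @param bin_ms,ref_ms Binning and reference-window parameters.
#' @param include_familiarization Include good "head" familiarization trials.
#' @return A list with `participant` (tibble: `participant_id`, `pert_kind`,
#'   `pert_hz`, `bin`, `time_ms`, `time_mid_ms`, `value`, `n_trials`) and
#'   `group` (tibble: condition, bin times, `mean`, `sem`, `n_participants`).
#' @export
condition_average <- function(dataset, sessions = c(1L, 3L, 5L),
                              bin_ms = 25, ref_ms = 50,
                              include_familiarization = TRUE) {
  per_part <- list()
  for (pid in dataset$participants$participant_id) {
    els <- participant_sessions(dataset, pid, sessions)
    if (!length(els)) next
    trend <- unperturbed_trend(dataset, pid, sessions, include_familiarization)
    cond_vals <- list()
    for (el in els) {
      idx <- which(analyzable_idx(el, include_familiarization) &
                     el$schedule$pert_kind != "none")
      if (!length(idx)) next
      bn <- binned_normalized(el, trend, idx, bin_ms, ref_ms)
      key <- paste(el$schedule$pert_kind[idx], el$schedule$pert_hz[idx])
      for (cond in unique(key)) {
        sel <- key == cond
        cond_vals[[cond]] <- c(cond_vals[[cond]], list(list(
          values = bn$values[, sel, drop = FALSE],
          max_bin = bn$max_complete_bin[sel]
        )))
      }
    }
    rows <- lapply(names(cond_vals), function(cond) {
      parts <- cond_vals[[cond]]
      max_bin <- min(unlist(lapply(parts, `[[`, "max_bin")))
      nb <- max_bin + 1L
      vals <- do.call(cbind, lapply(parts, function(p) {
        v <- p$values
        if (nrow(v) < nb) v <- rbind(v, matrix(NA_real_, nb - nrow(v), ncol(v)))
        v[seq_len(nb), , drop = FALSE]
      }))
      ck <- strsplit(cond, " ")[[1]]
      tibble::tibble(
        participant_id = pid,
        pert_kind = ck[1],
        pert_hz = as.numeric(ck[2]),
        bin = seq_len(nb) - 1L,
        time_ms = (seq_len(nb) - 1L) * bin_ms,
        time_mid_ms = (seq_len(nb) - 1L) * bin_ms + bin_ms / 2,
        value = rowMeans(vals, na.rm = TRUE),
        n_trials = rowSums(!is.na(vals))
      )
    })
    per_part[[pid]] <- dplyr::bind_rows(rows)
  }
  participant <- dplyr::bind_rows(per_part)
  if (nrow(participant) == 0) abort("No analyzable perturbed trials found.")
  n_parts <- length(unique(participant$participant_id))
  group <- participant |>
    dplyr::summarise(
      mean = mean(.data$value),
      sem = sem(.data$value),
      n_participants = dplyr::n(),
      .by = c("pert_kind", "pert_hz", "bin", "time_ms", "time_mid_ms")
    ) |>
    dplyr::filter(.data$n_participants == n_parts) |>
    dplyr::arrange(.data$pert_kind, .data$pert_hz, .data$bin)
  list(participant = participant, group = group)
}

#' Group onset-response latency
#'
#' Scans a condition's group-mean time-course forward from the perturbation
#' onset and returns the start time of the first bin (by default, first run
#' of `persistence` consecutive bins) whose value lies beyond two standard
#' deviations of the onset-pool mean in the compensatory direction. The pool
#' is all group-mean samples in the first `ref_ms` after perturbation onset
#' across the four magnitudes of the same perturbation kind.
#'
#' @param group_tc Group time-course tibble (from [condition_average()]).
#' @param kind Perturbation kind (`"mid_utterance"` or `"whole_utterance"`).
#' @param pert_hz Signed magnitude of the condition to scan.
#' @param ref_ms Pool window length (ms after perturbation onset).
#' @param n_sd Threshold in pool standard deviations.
#' @param persistence Number of consecutive supra-threshold bins required
#'   (1 reproduces a literal single-bin crossing rule).
#' @return Latency in ms (bin start), or `NA` if the response never crosses.
#' @export
onset_latency <- function(group_tc, kind, pert_hz, ref_ms = 50,
                          n_sd = 2, persistence = 4) {
  pool <- group_tc$mean[group_tc$pert_kind == kind & group_tc$time_ms < ref_ms]
  if (length(pool) < 2) abort("Onset pool has fewer than two samples.")
  series <- group_tc[group_tc$pert_kind == kind & group_tc$pert_hz == pert_hz, ]
  series <- series[order(series$bin), ]
  if (nrow(series) == 0) abort("No group time-course for that condition.")
  m <- mean(pool)
  s <- sd(pool)
  dirn <- comp_mult(pert_hz)
  # With a degenerate (zero-variance) pool, e.g. noise-free data, the
  # threshold collapses to any deviation in the compensatory direction;
  # a 1e-9 Hz floor keeps float jitter from registering as a crossing.
  threshold <- max(n_sd * s, 1e-9)
  if (all(abs(series$mean - m) <= 1e-9)) return(NA_real_)
  crossed <- dirn * (series$mean - m) > threshold
  if (persistence > 1) {
    run <- stats::filter(as.numeric(crossed), rep(1, persistence),
                         sides = 1)
    hit <- which(run == persistence)
    if (!length(hit)) return(NA_real_)
    series$time_ms[hit[1] - persistence + 1]
  } else {
    hit <- which(crossed)
    if (!length(hit)) return(NA_real_)
    series$time_ms[hit[1]]
  }
}

# Group peak-response latency for one condition: time (bin centre) of the
# extremum of the group-mean response in the compensatory direction, searched
# from the onset latency to the condition's search horizon (perturbation
# offset + 300 ms for transient perturbations; end of common coverage minus
# half the averaging window for whole-utterance ones, so the centred window
# always fits).
group_peak_latency <- function(group_tc, kind, pert_hz, latency_ms,
                               window_ms = 200, bin_ms = 25,
                               post_offset_ms = 300, pert_duration_ms = 400) {
  series <- group_tc[group_tc$pert_kind == kind & group_tc$pert_hz == pert_hz, ]
  series <- series[order(series$bin), ]
  lo <- if (is.na(latency_ms)) 0 else latency_ms
  hi <- if (kind == "mid_utterance") {
    pert_duration_ms + post_offset_ms
  } else {
    max(series$time_ms) + bin_ms - window_ms / 2
  }
  cand <- series[series$time_ms >= lo & series$time_mid_ms <= hi + bin_ms / 2, ]
  if (nrow(cand) == 0) cand <- series
  score <- comp_mult(pert_hz) * cand$mean
  ties <- which(score == max(score))
  # middle of an extremal run, so a plateau-shaped response centres the
  # averaging window inside the plateau
  cand$time_mid_ms[ties[ceiling(length(ties) / 2)]]
}

#' Peak percent compensation for one participant and condition
#'
#' Averages the participant's normalized time-course in a `window_ms`-wide
#' window centred on the group peak-response latency, then converts the mean
#' to percent compensation via
#' `response / |perturbation| * 100 * compMult` (compMult = -1 for positive,
#' +1 for negative perturbations).
#'
#' @param participant_tc Tibble with `time_mid_ms` and `value` for one
#'   participant x condition.
#' @param peak_latency_ms Group peak-response latency (ms, bin centre).
#' @param pert_hz Signed perturbation magnitude.
#' @param window_ms Averaging window width (default 200 ms).
#' @return A list with `pct` (percent compensation), `window_ms_used`
#'   (the half-open window actually averaged), and `n_bins`.
#' @export
peak_compensation <- function(participant_tc, peak_latency_ms, pert_hz,
                              window_ms = 200) {
  lo <- peak_latency_ms - window_ms / 2
  hi <- peak_latency_ms + window_ms / 2
  sel <- participant_tc$time_mid_ms >= lo & participant_tc$time_mid_ms < hi
  if (!any(sel)) {
    abort("Participant time-course does not cover the peak window.")
  }
  resp <- mean(participant_tc$value[sel])
  list(
    pct = percent_compensation(resp, pert_hz),
    window_ms_used = c(lo, hi),
    n_bins = sum(sel)
  )
}

#' Full within-trial compensation analysis
#'
#' Runs the complete pipeline for the unpredictable sessions: trend
#' subtraction, perturbation-onset alignment, binning, condition averaging,
#' group onset and peak latencies per condition, per-participant peak percent
#' compensation, and per-condition group summaries (mean, SEM, two-tailed
#' one-sample t against zero).
#'
#' @inheritParams condition_average
#' @param window_ms Peak averaging window width (ms).
#' @param latencies Optional precomputed latency tibble (as returned in
#'   `$latency`) whose peak latencies are reused, e.g. when recomputing
#'   per-session tables with the pooled latencies.
#' @param persistence Consecutive-bin requirement for [onset_latency()].
#' @return An object of class `fpl_compensation`: list with `table` (one row
#'   per participant x condition: `peak_compensation_pct`, `baseline_f1`,
#'   `age`), `summary` (per-condition mean, SEM, t, df, p), `latency`
#'   (per-condition onset and peak latencies), `group` and `participant`
#'   time-courses, and the parameters used.
#' @export
compensation_table <- function(dataset, sessions = c(1L, 3L, 5L),
                               bin_ms = 25, ref_ms = 50, window_ms = 200,
                               include_familiarization = TRUE,
                               latencies = NULL, persistence = 4) {
  tc <- condition_average(dataset, sessions, bin_ms, ref_ms,
                          include_familiarization)
  conds <- dplyr::distinct(tc$group[, c("pert_kind", "pert_hz")])
  if (is.null(latencies)) {
    latencies <- conds
    latencies$onset_latency_ms <- NA_real_
    latencies$peak_latency_ms <- NA_real_
    for (i in seq_len(nrow(conds))) {
      ol <- onset_latency(tc$group, conds$pert_kind[i], conds$pert_hz[i],
                          ref_ms, persistence = persistence)
      latencies$onset_latency_ms[i] <- ol
      latencies$peak_latency_ms[i] <- group_peak_latency(
        tc$group, conds$pert_kind[i], conds$pert_hz[i], ol,
        window_ms, bin_ms
      )
    }
  }
  base_f1 <- baseline_f1_by_condition(dataset, sessions,
                                      include_familiarization)
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    kind <- conds$pert_kind[i]
    hz <- conds$pert_hz[i]
    pk <- latencies$peak_latency_ms[latencies$pert_kind == kind &
                                      latencies$pert_hz == hz]
    sub <- tc$participant[tc$participant$pert_kind == kind &
                            tc$participant$pert_hz == hz, ]
    for (pid in unique(sub$participant_id)) {
      pc <- peak_compensation(sub[sub$participant_id == pid, ], pk, hz,
                              window_ms)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, pert_kind = kind, pert_hz = hz,
        peak_compensation_pct = pc$pct
      )
    }
  }
  table <- dplyr::bind_rows(rows) |>
    dplyr::left_join(base_f1, by = c("participant_id", "pert_kind", "pert_hz")) |>
    dplyr::left_join(dataset$participants[, c("participant_id", "age")],
                     by = "participant_id")
  summary <- table |>
    dplyr::reframe(
      tidy_ttest(one_sample_t(.data$peak_compensation_pct)),
      .by = c("pert_kind", "pert_hz")
    )
  structure(
    list(
      table = table, summary = summary, latency = latencies,
      group = tc$group, participant = tc$participant,
      bin_ms = bin_ms, ref_ms = ref_ms, window_ms = window_ms,
      sessions = sessions
    ),
    class = "fpl_compensation"
  )
}

# Non-normalized F1 at perturbation onset, averaged over the analyzable
# trials of each participant x condition (nuisance covariate).
baseline_f1_by_condition <- function(dataset, sessions = c(1L, 3L, 5L),
                                     include_familiarization = TRUE) {
  rows <- list()
  for (el in dataset$sessions) {
    if (!el$session %in% sessions) next
    idx <- which(analyzable_idx(el, include_familiarization) &
                   el$schedule$pert_kind != "none")
    if (!length(idx)) next
    tp <- el$schedule$pert_onset_ms[idx]
    k <- el$voice_onset_frame[idx] +
      as.integer(ceiling(tp / el$frame_interval_ms - 1e-9))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = el$participant_id,
      pert_kind = el$schedule$pert_kind[idx],
      pert_hz = el$schedule$pert_hz[idx],
      f1_at_onset = el$f1[cbind(k, idx)]
    )
  }
  dplyr::bind_rows(rows) |>
    dplyr::summarise(baseline_f1 = mean(.data$f1_at_onset),
                     .by = c("participant_id", "pert_kind", "pert_hz"))
}

#' @export
print.fpl_compensation <- function(x, ...) {
  cat("<fpl_compensation>\n")
  cat(sprintf("  %d participants x %d conditions; bins of %g ms\n",
              length(unique(x$table$participant_id)),
              nrow(x$latency), x$bin_ms))
  print(dplyr::left_join(x$latency, x$summary,
                         by = c("pert_kind", "pert_hz")), n = Inf)
  invisible(x)
}
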