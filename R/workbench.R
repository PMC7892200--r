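#' Configuration for an end-to-end pipeline run
#'
#' A fully serializable description of one run: seed, cohort preset and
#' overrides, which sessions to simulate, stage toggles and output paths.
#' The configuration hash is recorded in every output's provenance block, so
#' a results bundle is a pure function of its `run_config`.
#'
#' @param seed Top-level seed; all stage RNG streams are derived from it.
#' @param n_participants Cohort size.
#' @param preset Cohort preset name (see [cohort_preset()]).
#' @param cohort Named list of [cohort_config()] overrides.
#' @param sessions Sessions to simulate.
#' @param bin_ms Bin width for within-trial analyses.
#' @param run_stats,run_dynamics Stage toggles.
#' @param out_dir If non-NULL, results are written there as plain-text files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_participants = 22, preset = "default",
                       cohort = list(), sessions = 1:5, bin_ms = 25,
                       run_stats = TRUE, run_dynamics = TRUE,
                       out_dir = NULL) {
  structure(
    list(
      seed = as.integer(seed), n_participants = n_participants,
      preset = preset, cohort = cohort, sessions = as.integer(sessions),
      bin_ms = bin_ms, run_stats = isTRUE(run_stats),
      run_dynamics = isTRUE(run_dynamics), out_dir = out_dir
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(force(expr), error = function(e) {
    abort(paste0("[stage ", name, "] ", conditionMessage(e)))
  })
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  message(sprintf("stage %-14s %6.1fs", name, elapsed))
  attr(res, "elapsed_s") <- elapsed
  res
}

#' Run the full analysis pipeline
#'
#' design -> simulate -> screen -> within-trial compensation -> adaptation
#' (with outlier screening) -> responder selection -> within-trial dynamics
#' -> inferential models -> optional file outputs. Identical configurations
#' produce identical bundles.
#'
#' @param config A [run_config()].
#' @return An object of class `fpl_results`: list with `dataset` (screened),
#'   `compensation`, `adaptation`, `outliers`, `responders`, `dynamics`,
#'   `stats`, and `provenance`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cc <- do.call(cohort_preset, c(
    list(name = config$preset, n_participants = config$n_participants,
         rng_seed = config$seed, sessions = config$sessions),
    config$cohort
  ))
  dataset <- stage("simulate", simulate_cohort(cc))
  dataset <- stage("screen", screen_trials(dataset))

  has_unpred <- any(config$sessions %in% c(1L, 3L, 5L))
  has_adapt <- any(config$sessions %in% c(2L, 4L))
  compensation <- if (has_unpred) {
    stage("compensation", compensation_table(dataset, bin_ms = config$bin_ms))
  }
  adaptation <- if (has_adapt) stage("adaptation", adaptation_table(dataset))
  outliers <- NULL
  if (!is.null(adaptation)) {
    outliers <- stage("outliers", exclude_outlier_participants(adaptation))
    if (length(outliers$removed$participant_id)) {
      keep <- outliers$kept
      adaptation$table <- adaptation$table[
        adaptation$table$participant_id %in% keep, ]
      adaptation$summary <- adaptation$table |>
        dplyr::reframe(tidy_ttest(one_sample_t(.data$adaptation_pct)),
                       .by = "direction")
      if (!is.null(compensation)) {
        compensation$table <- compensation$table[
          compensation$table$participant_id %in% keep, ]
        compensation$summary <- compensation$table |>
          dplyr::reframe(tidy_ttest(one_sample_t(.data$peak_compensation_pct)),
                         .by = c("pert_kind", "pert_hz"))
      }
    }
  }

  responders <- NULL
  dynamics <- NULL
  if (config$run_dynamics && !is.null(compensation) && !is.null(adaptation)) {
    responders <- stage("responders", lapply(
      setNames(c(200, -200), c("+200", "-200")),
      function(d) select_positive_responders(compensation, adaptation, d)
    ))
    dynamics <- stage("dynamics", {
      out <- list()
      for (d in c(200, -200)) {
        ids <- responders[[if (d > 0) "+200" else "-200"]]
        if (length(ids) >= 2) {
          out[[if (d > 0) "+200" else "-200"]] <-
            phase_dynamics(dataset, ids, d)
        } else {
          message("dynamics skipped for ", d, " Hz: fewer than two responders")
        }
      }
      out
    })
  }

  stats_res <- NULL
  if (config$run_stats && !is.null(compensation)) {
    stats_res <- stage("stats", {
      out <- list()
      ctab <- compensation$table
      wide <- tidyr::pivot_wider(
        ctab[, c("participant_id", "pert_kind", "pert_hz",
                 "peak_compensation_pct")],
        names_from = "pert_kind", values_from = "peak_compensation_pct"
      )
      out$mid_whole <- random_intercept_slope(
        wide, "whole_utterance", "mid_utterance"
      )
      pm <- dplyr::summarise(
        ctab,
        mid = mean(.data$peak_compensation_pct[.data$pert_kind == "mid_utterance"]),
        whole = mean(.data$peak_compensation_pct[.data$pert_kind == "whole_utterance"]),
        .by = "participant_id"
      )
      out$mid_whole_participant <- random_intercept_slope(pm, "whole", "mid")
      out$mid_whole_by_magnitude <- lapply(
        setNames(sort(unique(wide$pert_hz)), sort(unique(wide$pert_hz))),
        function(hz) random_intercept_slope(
          wide[wide$pert_hz == hz, ], "whole_utterance", "mid_utterance"
        )
      )
      cfac <- ctab
      cfac$magnitude <- abs(cfac$pert_hz)
      cfac$direction <- ifelse(cfac$pert_hz > 0, "positive", "negative")
      out$compensation_lme <- factorial_lme(
        cfac, "peak_compensation_pct",
        factors = c("magnitude", "direction", "pert_kind"),
        covariates = c("age", "baseline_f1")
      )
      if (!is.null(adaptation)) {
        joined <- dplyr::inner_join(
          adaptation$table[, c("participant_id", "direction", "adaptation_pct")],
          ctab[abs(ctab$pert_hz) == 200,
               c("participant_id", "pert_kind", "pert_hz",
                 "peak_compensation_pct")],
          by = c("participant_id", "direction" = "pert_hz")
        )
        out$comp_adapt <- lapply(
          setNames(c("mid_utterance", "whole_utterance"),
                   c("mid_utterance", "whole_utterance")),
          function(k) random_intercept_slope(
            joined[joined$pert_kind == k, ], "adaptation_pct",
            "peak_compensation_pct"
          )
        )
        afac <- adaptation$table
        afac$direction_f <- ifelse(afac$direction > 0, "positive", "negative")
        out$adaptation_lme <- factorial_lme(
          afac, "adaptation_pct", factors = "direction_f",
          covariates = c("age", "baseline_f1")
        )
      }
      if (!is.null(dynamics) && length(dynamics)) {
        out$dynamics_lme <- dynamics_lme(dynamics)
      }
      if (length(intersect(config$sessions, c(1L, 3L, 5L))) == 3) {
        out$session_order <- session_order_checks(dataset, compensation)
      }
      out
    })
  }

  bundle <- structure(
    list(
      dataset = dataset, compensation = compensation,
      adaptation = adaptation, outliers = outliers,
      responders = responders, dynamics = dynamics, stats = stats_res,
      provenance = list(
        seed = config$seed,
        config = unclass(config),
        config_hash = config_hash(unclass(config)),
        n_analyzable_trials = n_analyzable_trials(dataset)
      )
    ),
    class = "fpl_results"
  )
  if (!is.null(config$out_dir)) write_results(bundle, config$out_dir)
  bundle
}

#' @export
print.fpl_results <- function(x, ...) {
  cat("<fpl_results> seed", x$provenance$seed,
      "hash", x$provenance$config_hash, "\n")
  if (!is.null(x$compensation)) print(x$compensation)
  if (!is.null(x$adaptation)) print(x$adaptation)
  invisible(x)
}

# Plain-list (JSON-ready) view of a model result.
as_plain <- function(x) {
  if (inherits(x, c("fpl_lme", "fpl_ttest"))) return(unclass(x))
  if (inherits(x, "fpl_lme_anova")) {
    x <- unclass(x)
    x$anova <- as.data.frame(x$anova)
    x$fixed <- as.data.frame(x$fixed)
    return(x)
  }
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(x, as_plain))
  x
}

#' Write a results bundle as plain-text files
#'
#' CSV tables for compensation, latencies, adaptation and responders, TSV
#' time-courses, JSON for every model fit, and a provenance block.
#'
#' @param bundle An `fpl_results`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put_csv <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_csv(x, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  put_tsv <- function(x, name) {
    p <- file.path(dir, name)
    readr::write_tsv(x, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$compensation)) {
    put_csv(bundle$compensation$table, "compensation_table.csv")
    put_csv(bundle$compensation$summary, "compensation_summary.csv")
    put_csv(bundle$compensation$latency, "latency_table.csv")
    put_tsv(bundle$compensation$participant, "normalized_timecourses.tsv")
    put_tsv(bundle$compensation$group, "group_timecourses.tsv")
  }
  if (!is.null(bundle$adaptation)) {
    put_csv(bundle$adaptation$table, "adaptation_table.csv")
    put_csv(bundle$adaptation$summary, "adaptation_summary.csv")
    traj <- dplyr::bind_rows(lapply(bundle$adaptation$records, function(r) {
      dplyr::mutate(r$smoothed, participant_id = r$participant_id,
                    direction = r$direction)
    }))
    put_csv(traj, "adaptation_trajectories.csv")
  }
  if (!is.null(bundle$responders)) {
    put_csv(
      dplyr::bind_rows(lapply(names(bundle$responders), function(d) {
        tibble::tibble(direction = d,
                       participant_id = bundle$responders[[d]])
      })),
      "responders.csv"
    )
  }
  if (!is.null(bundle$dynamics) && length(bundle$dynamics)) {
    put_csv(dplyr::bind_rows(lapply(bundle$dynamics, `[[`, "windows")),
            "dynamics_windows.csv")
    put_tsv(dplyr::bind_rows(lapply(bundle$dynamics, `[[`, "group_timecourses")),
            "dynamics_timecourses.tsv")
  }
  if (!is.null(bundle$stats)) {
    p <- file.path(dir, "models.json")
    jsonlite::write_json(as_plain(bundle$stats), p, auto_unbox = TRUE,
                         digits = NA, null = "null", dataframe = "rows")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "provenance.json")
  jsonlite::write_json(bundle$provenance, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

#' Render the summary figures for a results bundle
#'
#' Writes six static figures: mid- and whole-utterance group time-courses,
#' peak-compensation violins, the mid-vs-whole and compensation-vs-adaptation
#' scatters with fitted slopes, the across-trial adaptation course, and the
#' within-trial dynamics phases. Figures missing their inputs (e.g. an empty
#' responder subset) are skipped with a message.
#'
#' @param bundle An `fpl_results`.
#' @param dir Output directory.
#' @param device File extension (`"pdf"` or `"png"`).
#' @return Character vector of files written.
#' @export
make_report <- function(bundle, dir, device = "pdf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  save_fig <- function(plot, name, width = 7, height = 5) {
    p <- file.path(dir, paste0(name, ".", device))
    ggplot2::ggsave(p, plot, width = width, height = height)
    files <<- c(files, p)
  }
  comp <- bundle$compensation
  if (!is.null(comp)) {
    for (k in unique(comp$group$pert_kind)) {
      g <- comp$group[comp$group$pert_kind == k, ]
      pl <- ggplot2::ggplot(
        g, ggplot2::aes(.data$time_mid_ms, .data$mean,
                        colour = factor(.data$pert_hz),
                        fill = factor(.data$pert_hz))
      ) +
        ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem),
                             alpha = 0.25, colour = NA) +
        ggplot2::geom_line() +
        ggplot2::labs(
          x = "time from perturbation onset (ms)",
          y = "normalized F1 (Hz)", colour = "perturbation (Hz)",
          fill = "perturbation (Hz)",
          title = paste("Group F1 response,", sub("_", "-", k))
        ) +
        ggplot2::theme_minimal()
      save_fig(pl, paste0("timecourses_", sub("_utterance", "", k)))
    }
    pl <- ggplot2::ggplot(
      comp$table,
      ggplot2::aes(factor(.data$pert_hz), .data$peak_compensation_pct)
    ) +
      ggplot2::geom_violin(fill = "grey85") +
      ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 0.9) +
      ggplot2::facet_wrap(~pert_kind) +
      ggplot2::labs(x = "perturbation (Hz)", y = "peak compensation (%)") +
      ggplot2::theme_minimal()
    save_fig(pl, "compensation_violins")
  }
  adapt <- bundle$adaptation
  if (!is.null(adapt)) {
    traj <- dplyr::bind_rows(lapply(adapt$records, function(r) {
      dplyr::mutate(r$smoothed, participant_id = r$participant_id,
                    direction = r$direction)
    })) |>
      dplyr::summarise(mean = mean(.data$norm_hz, na.rm = TRUE),
                       sem = sem(.data$norm_hz),
                       .by = c("direction", "window_index", "head_ordinal_mid"))
    pl <- ggplot2::ggplot(
      traj, ggplot2::aes(.data$head_ordinal_mid, .data$mean,
                         colour = factor(.data$direction))
    ) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem,
                                        fill = factor(.data$direction)),
                           alpha = 0.25, colour = NA) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.9) +
      ggplot2::labs(x = "'head' trial", y = "normalized early F1 (Hz)",
                    colour = "hold (Hz)", fill = "hold (Hz)") +
      ggplot2::theme_minimal()
    save_fig(pl, "adaptation_course")
  }
  if (!is.null(comp)) {
    wide <- tidyr::pivot_wider(
      comp$table[, c("participant_id", "pert_kind", "pert_hz",
                     "peak_compensation_pct")],
      names_from = "pert_kind", values_from = "peak_compensation_pct"
    )
    rel <- tibble::tibble(
      relationship = "whole ~ mid",
      x = wide$mid_utterance, y = wide$whole_utterance,
      pert_hz = wide$pert_hz
    )
    if (!is.null(adapt)) {
      joined <- dplyr::inner_join(
        adapt$table[, c("participant_id", "direction", "adaptation_pct")],
        comp$table[abs(comp$table$pert_hz) == 200,
                   c("participant_id", "pert_kind", "pert_hz",
                     "peak_compensation_pct")],
        by = c("participant_id", "direction" = "pert_hz")
      )
      rel <- dplyr::bind_rows(rel, tibble::tibble(
        relationship = paste0("adapt ~ ", sub("_utterance", "", joined$pert_kind)),
        x = joined$peak_compensation_pct, y = joined$adaptation_pct,
        pert_hz = joined$direction
      ))
    }
    pl <- ggplot2::ggplot(rel, ggplot2::aes(.data$x, .data$y,
                                            colour = factor(.data$pert_hz))) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(ggplot2::aes(group = 1), method = "lm",
                           formula = y ~ x, colour = "black") +
      ggplot2::facet_wrap(~relationship, scales = "free") +
      ggplot2::labs(x = "predictor response (%)", y = "response (%)",
                    colour = "perturbation (Hz)") +
      ggplot2::theme_minimal()
    save_fig(pl, "scatter_relationships", width = 9)
  }
  dyn <- bundle$dynamics
  if (!is.null(dyn) && length(dyn)) {
    tc <- dplyr::bind_rows(lapply(dyn, `[[`, "group_timecourses"))
    pl <- ggplot2::ggplot(
      tc, ggplot2::aes(.data$time_mid_ms, .data$mean, colour = .data$phase)
    ) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem,
                                        fill = .data$phase),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~direction, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "time from voice onset (ms)",
                    y = "baseline-normalized F1 (Hz)") +
      ggplot2::theme_minimal()
    save_fig(pl, "dynamics_phases", width = 9)
  } else {
    message("dynamics figure skipped: no responder time-courses available")
  }
  files
}
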