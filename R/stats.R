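#' One-sample two-tailed t-test against zero
#'
#' Standard one-sample t-test written out explicitly so degenerate inputs
#' are flagged rather than silently producing NaN: with zero variance the
#' statistic is reported as 0 (p = 1) when the mean equals `mu`, and as a
#' signed infinity (p = 0) otherwise, with `degenerate = TRUE`.
#'
#' @param values Numeric vector, length >= 2, finite.
#' @param mu Null value (default 0).
#' @return An object of class `fpl_ttest`: list with `n`, `mean`, `sem`,
#'   `t`, `df`, `p`, `degenerate`.
#' @export
one_sample_t <- function(values, mu = 0) {
  if (length(values) < 2) abort("one_sample_t needs at least two values.")
  if (!all(is.finite(values))) abort("one_sample_t needs finite values.")
  n <- length(values)
  m <- mean(values)
  se <- sd(values) / sqrt(n)
  if (se == 0) {
    t_stat <- if (m == mu) 0 else sign(m - mu) * Inf
    p <- if (m == mu) 1 else 0
    degenerate <- TRUE
  } else {
    t_stat <- (m - mu) / se
    p <- 2 * pt(-abs(t_stat), df = n - 1)
    degenerate <- FALSE
  }
  structure(
    list(n = n, mean = m, sem = se, t = t_stat, df = n - 1L, p = p,
         degenerate = degenerate),
    class = "fpl_ttest"
  )
}

#' @export
print.fpl_ttest <- function(x, ...) {
  cat(sprintf("one-sample t: mean = %.4g +/- %.4g (SEM), t(%d) = %.4g, p = %.4g%s\n",
              x$mean, x$sem, x$df, x$t, x$p,
              if (x$degenerate) " [degenerate variance]" else ""))
  invisible(x)
}

#' Flatten a t-test result to a one-row tibble
#'
#' @param x An `fpl_ttest`.
#' @return One-row tibble with `n`, `mean`, `sem`, `t`, `df`, `p`.
#' @export
tidy_ttest <- function(x) {
  stopifnot(inherits(x, "fpl_ttest"))
  tibble::tibble(n = x$n, mean = x$mean, sem = x$sem, t = x$t,
                 df = x$df, p = x$p, degenerate = x$degenerate)
}

#' Random-intercept regression with a fixed slope
#'
#' Fits `y ~ 1 + x + (1 | group)` by restricted maximum likelihood
#' (lme4/lmerTest, Satterthwaite degrees of freedom). With a single
#' observation per group the random intercept is unidentifiable and the
#' model reduces to ordinary least squares, which is fitted instead and
#' flagged in `method`. Singular fits are reported through the `singular`
#' flag, never as an exception.
#'
#' @param data Data frame.
#' @param y,x,group Column names (character scalars).
#' @return An object of class `fpl_lme`: list with `estimate` (slope), `se`,
#'   `t`, `df`, `p`, `intercept`, `ranef_var`, `resid_var`, `n_obs`,
#'   `n_groups`, `method` ("lmer" or "ols"), `singular`, `converged`,
#'   `formula`.
#' @export
random_intercept_slope <- function(data, y, x, group = "participant_id") {
  data <- as.data.frame(data)[, c(y, x, group)]
  data <- data[complete.cases(data), ]
  if (nrow(data) < 3) abort("Too few complete observations for regression.")
  n_groups <- length(unique(data[[group]]))
  if (n_groups < 2) abort("Need at least two groups.")
  if (var(data[[x]]) == 0) abort("Predictor has no variation.")
  formula_str <- paste0(y, " ~ 1 + ", x, " + (1 | ", group, ")")

  max_per_group <- max(table(data[[group]]))
  fit_ols <- function(note) {
    fit <- lm(stats::reformulate(x, y), data = data)
    cs <- coef(suppressWarnings(summary(fit)))
    structure(
      list(
        estimate = cs[x, "Estimate"], se = cs[x, "Std. Error"],
        t = cs[x, "t value"], df = fit$df.residual, p = cs[x, "Pr(>|t|)"],
        intercept = cs["(Intercept)", "Estimate"],
        ranef_var = 0, resid_var = suppressWarnings(summary(fit))$sigma^2,
        n_obs = nrow(data), n_groups = n_groups,
        method = "ols", singular = FALSE, converged = TRUE,
        note = note, formula = formula_str
      ),
      class = "fpl_lme"
    )
  }
  if (max_per_group == 1) {
    return(fit_ols("single observation per group: random intercept unidentifiable"))
  }
  qf <- quiet_fit(lmerTest::lmer(as.formula(formula_str), data = data,
                                 REML = TRUE))
  fit <- qf$fit
  if (inherits(fit, "error")) {
    res <- fit_ols(paste0("mixed fit failed (", conditionMessage(fit),
                          "); ordinary least squares reported"))
    res$converged <- FALSE
    return(res)
  }
  cs <- coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(
    list(
      estimate = cs[x, "Estimate"], se = cs[x, "Std. Error"],
      t = cs[x, "t value"], df = cs[x, "df"], p = cs[x, "Pr(>|t|)"],
      intercept = cs["(Intercept)", "Estimate"],
      ranef_var = vc$vcov[vc$grp == group],
      resid_var = vc$vcov[vc$grp == "Residual"],
      n_obs = nrow(data), n_groups = n_groups,
      method = "lmer", singular = lme4::isSingular(fit),
      converged = length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0 &&
        length(qf$warnings) == 0,
      note = NULL, formula = formula_str
    ),
    class = "fpl_lme"
  )
}

#' @export
print.fpl_lme <- function(x, ...) {
  cat(sprintf("%s [%s]\n  slope = %.4g (SE %.4g), t(%.1f) = %.4g, p = %.4g\n",
              x$formula, x$method, x$estimate, x$se, x$df, x$t, x$p))
  if (isTRUE(x$singular)) cat("  note: singular fit\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Fit quietly: errors are returned, warnings and messages (e.g. singular-fit
# notices) are collected for the convergence flag instead of surfacing.
quiet_fit <- function(expr) {
  warns <- character(0)
  fit <- withCallingHandlers(
    tryCatch(expr, error = function(e) e),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage")
  )
  list(fit = fit, warnings = warns)
}

# Type-III F tests for an lm fit with sum contrasts, by dropping each term's
# model-matrix columns (used when a mixed fit is unavailable, e.g. on
# noise-free data).
lm_type3 <- function(fit) {
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  y <- stats::model.response(stats::model.frame(fit))
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- fit$df.residual
  rows <- lapply(seq_along(terms_lab), function(i) {
    keep <- asgn != i
    fit0 <- stats::lm.fit(mm[, keep, drop = FALSE], y)
    rss0 <- sum(fit0$residuals^2)
    df1 <- sum(!keep)
    f <- if (df_res > 0 && rss_full > 0) {
      ((rss0 - rss_full) / df1) / (rss_full / df_res)
    } else NA_real_
    tibble::tibble(
      term = terms_lab[i], f = f, df1 = df1, df2 = df_res,
      p = if (is.finite(f)) stats::pf(f, df1, df_res, lower.tail = FALSE) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Factorial mixed model with covariates
#'
#' Fits `response ~ factor1 * factor2 * ... + covariates + (1 | group)` by
#' REML with sum-to-zero contrasts, and reports type-III F tests
#' (Satterthwaite denominator df) for every main effect and interaction,
#' plus the covariate effects. If the mixed fit is unavailable (e.g. zero
#' residual variance in noise-free data) an ordinary least-squares fit with
#' the same fixed structure is used and flagged.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param factors Character vector of factor column names (crossed with all
#'   interactions unless `interactions = FALSE`).
#' @param covariates Character vector of numeric covariate column names.
#' @param group Grouping column for the random intercept.
#' @param interactions Include all factor interactions?
#' @return An object of class `fpl_lme_anova`: list with `anova` (tibble:
#'   `term`, `f`, `df1`, `df2`, `p`), `fixed` (coefficient table),
#'   `method`, `singular`, `converged`, `formula`.
#' @export
factorial_lme <- function(data, response, factors, covariates = character(),
                          group = "participant_id", interactions = TRUE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(response, factors, covariates, group), names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    if (nlevels(data[[f]]) < 2) {
      abort(paste0("Factor ", f, " has fewer than two levels."))
    }
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  fixed <- paste(factors, collapse = if (interactions) " * " else " + ")
  if (length(covariates)) {
    fixed <- paste(fixed, "+", paste(covariates, collapse = " + "))
  }
  formula_str <- paste0(response, " ~ ", fixed, " + (1 | ", group, ")")
  qf <- quiet_fit(lmerTest::lmer(as.formula(formula_str), data = data,
                                 REML = TRUE))
  fit <- qf$fit
  if (inherits(fit, "error")) {
    lmfit <- lm(as.formula(paste0(response, " ~ ", fixed)), data = data)
    cs <- coef(suppressWarnings(summary(lmfit)))
    return(structure(
      list(
        anova = lm_type3(lmfit),
        fixed = tibble::tibble(
          term = rownames(cs), estimate = cs[, "Estimate"],
          se = cs[, "Std. Error"], t = cs[, "t value"], df = lmfit$df.residual,
          p = cs[, "Pr(>|t|)"]
        ),
        method = "ols", singular = FALSE, converged = FALSE,
        note = paste0("mixed fit failed (", conditionMessage(fit), ")"),
        formula = formula_str
      ),
      class = "fpl_lme_anova"
    ))
  }
  an <- suppressWarnings(suppressMessages(
    stats::anova(fit, type = 3, ddf = "Satterthwaite")
  ))
  cs <- coef(summary(fit))
  structure(
    list(
      anova = tibble::tibble(
        term = rownames(an), f = an$`F value`, df1 = an$NumDF, df2 = an$DenDF,
        p = an$`Pr(>F)`
      ),
      fixed = tibble::tibble(
        term = rownames(cs), estimate = cs[, "Estimate"],
        se = cs[, "Std. Error"], t = cs[, "t value"], df = cs[, "df"],
        p = cs[, "Pr(>|t|)"]
      ),
      method = "lmer", singular = lme4::isSingular(fit),
      converged = length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0 &&
        length(qf$warnings) == 0,
      note = NULL, formula = formula_str
    ),
    class = "fpl_lme_anova"
  )
}

#' @export
print.fpl_lme_anova <- function(x, ...) {
  cat(sprintf("%s [%s]\n", x$formula, x$method))
  print(x$anova, n = Inf)
  invisible(x)
}

#' Mixed model for within-trial dynamics windows
#'
#' Factorial mixed model of the percent-compensation window means over
#' within-trial time window (O vs M), adaptation analysis phase, and -- when
#' both directions are supplied -- perturbation direction, with participant
#' as a random factor. The baseline phase is excluded (no perturbation has
#' been applied there). Per-direction submodels (window x phase) are fitted
#' alongside the overall model.
#'
#' @param windows An `fpl_dynamics` object, a list of them, or a tibble with
#'   columns `participant_id`, `direction`, `phase`, `window`, `pct`.
#' @param exclude_phases Phases dropped before modelling.
#' @return A list with `overall` (an [factorial_lme()] result) and
#'   `per_direction` (named list of submodels).
#' @export
dynamics_lme <- function(windows, exclude_phases = "late_baseline") {
  tbl <- if (inherits(windows, "fpl_dynamics")) {
    windows$windows
  } else if (is.data.frame(windows)) {
    tibble::as_tibble(windows)
  } else {
    dplyr::bind_rows(lapply(windows, function(w) w$windows))
  }
  tbl <- tbl[!tbl$phase %in% exclude_phases, ]
  dirs <- unique(tbl$direction)
  factors <- c("window", "phase", if (length(dirs) > 1) "direction")
  overall <- factorial_lme(tbl, "pct", factors)
  per_direction <- lapply(setNames(dirs, paste0(ifelse(dirs > 0, "+", ""), dirs)),
                          function(d) {
    factorial_lme(tbl[tbl$direction == d, ], "pct", c("window", "phase"))
  })
  list(overall = overall, per_direction = per_direction)
}

#' Session-order checks for the unpredictable sessions
#'
#' Two carry-over analyses: (i) each trial's baseline F1 (mean over the
#' first 50 ms from voice onset), reduced to a per-participant, per-session
#' median, tested for a session effect with a repeated-measures ANOVA
#' (participant as the error stratum); (ii) peak percent compensation
#' recomputed separately per session (reusing the pooled group peak
#' latencies), modelled with session, magnitude, direction and perturbation
#' kind as main effects and participant as a random factor.
#'
#' @param dataset An `fpl_dataset`.
#' @param compensation Optional pooled [compensation_table()] result (fitted
#'   if missing) providing the latencies and binning parameters.
#' @param baseline_ms Baseline window length from voice onset (ms).
#' @return A list with `baseline_medians`, `baseline_anova` (term, F, dfs,
#'   p), `per_session_table`, and `session_lme`.
#' @export
session_order_checks <- function(dataset, compensation = NULL,
                                 baseline_ms = 50) {
  sessions_present <- sort(unique(vapply(dataset$sessions, function(el)
    el$session, integer(1))))
  unpred <- intersect(c(1L, 3L, 5L), sessions_present)
  if (length(unpred) < 2) abort("Need at least two unpredictable sessions.")
  if (is.null(compensation)) compensation <- compensation_table(dataset, unpred)

  rows <- list()
  for (el in dataset$sessions) {
    if (!el$session %in% unpred) next
    idx <- which(analyzable_idx(el))
    if (!length(idx)) next
    v <- window_mean_by_trial(el, 0, baseline_ms)[idx]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      participant_id = el$participant_id, session = el$session,
      baseline_f1 = v
    )
  }
  baseline_medians <- dplyr::bind_rows(rows) |>
    dplyr::summarise(median_f1 = median(.data$baseline_f1, na.rm = TRUE),
                     .by = c("participant_id", "session"))
  adf <- as.data.frame(baseline_medians)
  adf$session <- factor(adf$session)
  adf$participant_id <- factor(adf$participant_id)
  aofit <- aov(median_f1 ~ session + Error(participant_id), data = adf)
  within <- summary(aofit)[["Error: Within"]][[1]]
  baseline_anova <- tibble::tibble(
    term = "session",
    f = within["session", "F value"],
    df1 = within["session", "Df"],
    df2 = within["Residuals", "Df"],
    p = within["session", "Pr(>F)"]
  )

  per_session <- dplyr::bind_rows(lapply(unpred, function(s) {
    ct <- compensation_table(
      dataset, sessions = s,
      bin_ms = compensation$bin_ms, ref_ms = compensation$ref_ms,
      window_ms = compensation$window_ms,
      latencies = compensation$latency
    )
    dplyr::mutate(ct$table, session = s)
  }))
  per_session$magnitude <- abs(per_session$pert_hz)
  per_session$direction <- ifelse(per_session$pert_hz > 0, "positive", "negative")
  session_lme <- factorial_lme(
    per_session, "peak_compensation_pct",
    factors = c("session", "magnitude", "direction", "pert_kind"),
    interactions = FALSE
  )
  list(
    baseline_medians = baseline_medians,
    baseline_anova = baseline_anova,
    per_session_table = per_session,
    session_lme = session_lme
  )
}

#' Optional Benjamini-Hochberg adjustment of a p-value column
#'
#' The primary analyses report unadjusted p-values; this helper lets users
#' add a false-discovery-rate adjusted column to any result table.
#'
#' @param table A tibble with a p-value column.
#' @param p_col Name of that column.
#' @return The table with an added `p_adj` column.
#' @export
adjust_fdr <- function(table, p_col = "p") {
  table$p_adj <- stats::p.adjust(table[[p_col]], method = "BH")
  table
}
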