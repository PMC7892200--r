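test_that("one-sample t matches the textbook formula", {
  withr::local_seed(42)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -3, 3), sd = runif(1, 0.5, 4))
    got <- one_sample_t(x)
    se <- sd(x) / sqrt(length(x))
    t_ref <- mean(x) / se
    expect_equal(got$t, t_ref, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(t_ref), length(x) - 1), tolerance = 1e-12)
    expect_equal(got$df, length(x) - 1)
  }
  z <- one_sample_t(rep(0, 6))
  expect_equal(c(z$t, z$p), c(0, 1))
  expect_equal(one_sample_t(c(1, -1))$t, 0)
  d <- one_sample_t(rep(2.5, 4))
  expect_true(d$degenerate)
  expect_equal(c(d$p, d$t), c(0, Inf))
  expect_error(one_sample_t(3), "two values")
})

test_that("random-intercept slope is exact on deterministic data", {
  df <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:6), each = 4),
    x = rnorm(24)
  )
  df$y <- df$x # y = x exactly
  fit <- random_intercept_slope(df, "y", "x")
  expect_equal(fit$estimate, 1, tolerance = 1e-6)
  expect_lt(fit$resid_var, 1e-10)
  expect_equal(fit$n_groups, 6)
})

test_that("one observation per group reduces to least squares", {
  withr::local_seed(5)
  df <- data.frame(
    participant_id = sprintf("P%02d", 1:15),
    x = rnorm(15), y = rnorm(15)
  )
  fit <- random_intercept_slope(df, "y", "x")
  expect_equal(fit$method, "ols")
  slope_ref <- sum((df$x - mean(df$x)) * (df$y - mean(df$y))) /
    sum((df$x - mean(df$x))^2)
  expect_equal(fit$estimate, slope_ref, tolerance = 1e-12)
  expect_equal(fit$df, 13)
})

test_that("reported p-values are invariant to observation order", {
  withr::local_seed(8)
  df <- data.frame(
    participant_id = rep(sprintf("P%02d", 1:8), each = 3),
    x = rnorm(24)
  )
  df$y <- 0.5 * df$x + rep(rnorm(8), each = 3) + rnorm(24, 0, 0.4)
  a <- random_intercept_slope(df, "y", "x")
  b <- random_intercept_slope(df[sample(nrow(df)), ], "y", "x")
  expect_equal(a$estimate, b$estimate, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("factorial models recover known structure", {
  withr::local_seed(11)
  grid <- expand.grid(
    participant_id = sprintf("P%02d", 1:10),
    magnitude = c("50", "200"), direction = c("neg", "pos"),
    kind = c("mid", "whole"), stringsAsFactors = FALSE
  )
  # pure magnitude effect plus participant intercepts and noise
  intercepts <- rnorm(10, 0, 1)
  grid$y <- 2 * (grid$magnitude == "200") +
    intercepts[match(grid$participant_id, sprintf("P%02d", 1:10))] +
    rnorm(nrow(grid), 0, 0.3)
  fit <- factorial_lme(grid, "y", c("magnitude", "direction", "kind"))
  an <- fit$anova
  expect_lt(an$p[an$term == "magnitude"], 1e-6)
  expect_gt(an$p[an$term == "direction"], 0.01)
  expect_gt(an$p[an$term == "magnitude:direction:kind"], 0.01)

  # consistent relabelling of factor levels leaves the F tests unchanged
  relab <- grid
  relab$direction <- c(neg = "down", pos = "up")[relab$direction]
  fit2 <- factorial_lme(relab, "y", c("magnitude", "direction", "kind"))
  expect_equal(fit$anova$f, fit2$anova$f, tolerance = 1e-6)

  # constant response: every effect estimate is zero
  grid$y <- 3
  fit0 <- factorial_lme(grid, "y", c("magnitude", "direction", "kind"))
  eff <- fit0$fixed[fit0$fixed$term != "(Intercept)", ]
  expect_true(all(abs(eff$estimate) < 1e-9))
})

test_that("noise-free fixed effects are reproduced exactly", {
  grid <- expand.grid(
    participant_id = sprintf("P%02d", 1:6),
    magnitude = c("50", "200"), direction = c("neg", "pos"),
    stringsAsFactors = FALSE
  )
  grid$y <- 1.5 + 2 * (grid$magnitude == "200") - 0.7 * (grid$direction == "pos")
  fit <- factorial_lme(grid, "y", c("magnitude", "direction"))
  # reconstruct fitted values from the sum-contrast estimates
  mm_data <- grid
  for (f in c("magnitude", "direction")) {
    mm_data[[f]] <- factor(mm_data[[f]])
    stats::contrasts(mm_data[[f]]) <- stats::contr.sum(2)
  }
  X <- stats::model.matrix(~ magnitude * direction, mm_data)
  est <- fit$fixed$estimate[match(colnames(X), fit$fixed$term)]
  expect_equal(as.vector(X %*% est), grid$y, tolerance = 1e-6)
})

test_that("session-order checks detect an injected baseline shift", {
  ds <- small_cohort(n = 6, seed = 23)
  out <- session_order_checks(ds)
  expect_true(is.finite(out$baseline_anova$f))
  expect_true(out$baseline_anova$p >= 0 && out$baseline_anova$p <= 1)
  expect_equal(sort(unique(out$per_session_table$session)), c(1, 3, 5))
  expect_s3_class(out$session_lme, "fpl_lme_anova")

  shifted <- ds
  for (key in names(shifted$sessions)) {
    if (shifted$sessions[[key]]$session == 5L) {
      shifted$sessions[[key]]$f1 <- shifted$sessions[[key]]$f1 + 30
    }
  }
  out2 <- session_order_checks(shifted)
  expect_lt(out2$baseline_anova$p, 0.001)
  med5 <- out2$baseline_medians
  expect_gt(mean(med5$median_f1[med5$session == 5]) -
              mean(med5$median_f1[med5$session == 1]), 20)
})

test_that("FDR adjustment is available but opt-in", {
  tbl <- tibble::tibble(term = letters[1:4], p = c(0.01, 0.02, 0.04, 0.6))
  adj <- adjust_fdr(tbl)
  expect_equal(adj$p_adj, stats::p.adjust(tbl$p, "BH"))
  expect_false("p_adj" %in% names(tbl))
})
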