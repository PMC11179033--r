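# Residual covariation: daily averaging, exclusion rules, lag pairing,
# and the concurrent/lagged mixed models.

make_residual_series <- function(n_id = 6, n_day = 20, seed = 2) {
  set.seed(seed)
  res <- data.frame(participant_id = rep(sprintf("P%02d", 1:n_id),
                                         each = n_day),
                    day_index = rep(seq_len(n_day), n_id),
                    mood = rnorm(n_id * n_day),
                    dprime = rnorm(n_id * n_day, 0, 0.4),
                    steps = rnorm(n_id * n_day, 0, 10),
                    n_nback_today = 3L, in_learning_period = FALSE)
  class(res) <- c("residual_series", class(res))
  res
}

test_that("daily d-prime residuals are the within-day mean of session residuals", {
  dp <- fake_fit(data.frame(
    participant_id = "P01", day_index = c(1L, 1L, 1L, 2L),
    residual = c(0.2, -0.1, 0.2, 0.4)))
  md <- fake_fit(data.frame(participant_id = "P01", day_index = 1:2,
                            residual = c(0.05, -0.05)))
  res <- build_residuals(list(dprime = dp, mood = md))
  expect_equal(res$dprime, c(0.1, 0.4))
  expect_equal(res$n_nback_today, c(3L, 1L))
  expect_equal(res$mood, c(0.05, -0.05))
})

test_that("near-noiseless cohorts give near-zero conditional residuals with mean zero", {
  cfg <- simulation_config(
    n_participants = 6L, n_days = 12L, fraction_non_learners = 1,
    diurnal_linear = 0, diurnal_quadratic = 0,
    noise_sd_dprime = 0.01, ar_phi_dprime = 0, p_session_missing = 0)
  ds <- harmonize_onset(generate_cohort(cfg, seed = 9)$dataset)
  fit <- fit_trend(ds, trend_spec("dprime", degree = 0))
  res <- build_residuals(list(dprime = fit))
  expect_lt(max(abs(res$dprime)), 0.05)
  pm <- tapply(fit$residuals$residual, fit$residuals$participant_id, mean)
  expect_lt(max(abs(pm)), 0.02)
})

test_that("learning-period exclusion keeps the plateau day and spares non-learners", {
  res <- make_residual_series(n_id = 2, n_day = 15)
  curves <- data.frame(participant_id = c("P01", "P02"),
                       fit_adequate = c(TRUE, FALSE),
                       learning_day_90 = c(10L, NA))
  out <- exclude_learning_period(res, curves)
  p1 <- out$day_index[out$participant_id == "P01"]
  expect_equal(min(p1), 10L)             # days 1-9 removed, day 10 kept
  expect_equal(length(p1), 6L)           # hand count: days 10..15
  p2 <- out$day_index[out$participant_id == "P02"]
  expect_equal(p2, 1:15)                 # non-learner untouched
  expect_lte(nrow(out), nrow(res))       # exclusions never add rows
})

test_that("complete-day restriction keeps exactly the 3-session days", {
  res <- make_residual_series(n_id = 1, n_day = 6)
  res$n_nback_today <- c(3L, 2L, 3L, 0L, 1L, 3L)
  out <- restrict_complete_days(res)
  expect_equal(out$day_index, c(1L, 3L, 6L))
  full <- make_residual_series(n_id = 2, n_day = 5)
  expect_equal(nrow(restrict_complete_days(full)), nrow(full))
})

test_that("lag pairing uses consecutive days only and needs enough pairs", {
  res <- make_residual_series(n_id = 3, n_day = 20)
  # a participant with a single day contributes no lagged pairs
  single <- res[res$participant_id != "P03" | res$day_index == 5, ]
  class(single) <- class(res)
  out <- lagged_covariation(single, "steps", "prev_day")
  expect_equal(out$n_obs, 2 * 19)
  # gaps break pairs: keep odd days only -> no consecutive pairs at all
  odd <- res[res$day_index %% 2 == 1, ]
  class(odd) <- class(res)
  expect_error(lagged_covariation(odd, "steps", "prev_day"),
               "fewer than 10")
})

test_that("a response regressed on itself returns estimate 1 exactly", {
  res <- make_residual_series()
  res$mirror <- res$mood
  out <- concurrent_covariation(res, response = "mood",
                                predictors = "mirror")
  expect_equal(out$table$estimate[out$table$term == "mirror"], 1)
  expect_true("degenerate_exact_fit" %in% out$flags)
})

test_that("degenerate predictors are dropped with a warning", {
  res <- make_residual_series()
  res$flat <- 0
  expect_warning(
    out <- concurrent_covariation(res, predictors = c("steps", "flat")),
    "degenerate")
  expect_equal(out$predictors, "steps")
  expect_error(
    suppressWarnings(concurrent_covariation(res, predictors = "flat")),
    "no usable")
})

test_that("a planted same-day coupling is estimated with the right sign and size", {
  set.seed(77)
  res <- make_residual_series(n_id = 10, n_day = 30, seed = 77)
  beta <- -0.08
  res$mood <- beta * res$steps + rnorm(nrow(res), 0, 0.5)
  out <- concurrent_covariation(res, predictors = c("dprime", "steps"))
  est <- out$table[out$table$term == "steps", ]
  expect_lt(est$estimate, 0)
  expect_lt(abs(est$estimate - beta), 3 * est$std_error)
  expect_lt(est$p_value, 0.001)
  # unrelated predictor stays non-significant
  expect_gt(out$table$p_value[out$table$term == "dprime"], 0.01)
})
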