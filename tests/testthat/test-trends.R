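# Hierarchical trend models: transforms, ML fitting with AR residual
# structures, GLS agreement, selection by sequential LRT, intercept
# extraction, diagnostics.

test_that("outcome transforms and their inverses round-trip", {
  expect_equal(transform_outcome(10000, "sqrt"), 100)
  expect_equal(transform_outcome(c(1, 2, 3), "identity"), c(1, 2, 3))
  set.seed(1)
  x <- runif(50, 0.1, 100)
  for (tr in c("identity", "log", "sqrt")) {
    expect_equal(inverse_transform_outcome(transform_outcome(x, tr), tr), x)
  }
  expect_error(transform_outcome(c(1, -2, 3), "log"), "record\\(s\\): 2")
  expect_error(transform_outcome(c(-1, 2), "sqrt"), "record\\(s\\): 1")
})

test_that("a known linear slope is recovered from near-noiseless data", {
  cfg <- simulation_config(
    n_participants = 6L, n_days = 14L, fraction_non_learners = 1,
    diurnal_linear = 0, diurnal_quadratic = 0,
    trend_coefs = list(dprime = c(0.05, 0, 0), steps = c(0, 0, 0),
                       heart_rate = c(0, 0, 0)),
    noise_sd_dprime = 1e-4, ar_phi_dprime = 0,
    p_session_missing = 0)
  ds <- harmonize_onset(generate_cohort(cfg, seed = 5)$dataset)
  fit <- fit_trend(ds, trend_spec("dprime", degree = 1))
  expect_true(fit$converged)
  slope <- fit$coefficients$estimate[2]
  expect_equal(slope, 0.05, tolerance = 5e-3)
  # starting points equal the participants' intercepts (trend is on the
  # day index here, and day_index 1 maps to t ~ 0 within rounding)
  sp <- extract_intercepts(fit)
  truth <- generate_cohort(cfg, seed = 5)$truth$participants
  m <- merge(sp, truth, by = "participant_id")
  expect_gt(cor(m$starting_point, m$intercept), 0.99)
  # value at time zero sits within one day-step of the flat intercept
  expect_lt(max(abs(m$starting_point - m$intercept)), 0.15)
})

test_that("random-intercept fit with independent errors matches GLS with compound symmetry", {
  set.seed(21)
  n_id <- 10
  days <- 12
  df <- expand.grid(participant_id = sprintf("P%02d", 1:n_id),
                    day_index = 1:days)
  u <- rnorm(n_id, 0, 8)
  df$step_count <- round(3000 + 15 * df$day_index +
                           40 * u[as.integer(factor(df$participant_id))] +
                           rnorm(nrow(df), 0, 150))
  ds <- make_daily_dataset(df[, c("participant_id", "day_index",
                                  "step_count")])
  ds$dailies$mean_heart_rate <- 70
  fit <- fit_trend(ds, trend_spec("steps", degree = 1,
                                  transform = "identity",
                                  covariance = "none",
                                  random_effects = "intercept"))
  frame <- fit$frame
  gls_fit <- nlme::gls(y ~ t, data = frame,
                       correlation = nlme::corCompSymm(form = ~ 1 |
                                                         participant_id),
                       method = "ML")
  # same marginal model: fixed effects and maximized likelihood agree
  raw <- fit$coefficients$estimate
  expect_equal(unname(raw), unname(coef(gls_fit)), tolerance = 1e-4)
  expect_equal(fit$logLik, as.numeric(logLik(gls_fit)), tolerance = 1e-5)
})

test_that("reversing the time axis negates a linear trend's slope", {
  set.seed(31)
  df <- expand.grid(participant_id = sprintf("P%02d", 1:8), day_index = 1:15)
  df$step_count <- round(4000 + 25 * df$day_index + rnorm(nrow(df), 0, 100))
  ds <- make_daily_dataset(df)
  ds$dailies$mean_heart_rate <- 70
  rev_df <- df
  rev_df$day_index <- 16L - df$day_index
  ds_rev <- make_daily_dataset(rev_df)
  ds_rev$dailies$mean_heart_rate <- 70
  f1 <- fit_trend(ds, trend_spec("steps", degree = 1,
                                 transform = "identity"))
  f2 <- fit_trend(ds_rev, trend_spec("steps", degree = 1,
                                     transform = "identity"))
  expect_equal(f1$coefficients$estimate[2], -f2$coefficients$estimate[2],
               tolerance = 1e-3)
})

test_that("selection table carries exact LRT and information-criterion identities", {
  cfg <- tiny_config(ar_phi_steps = 0.3, noise_sd_steps = 10)
  ds <- harmonize_onset(generate_cohort(cfg, seed = 8)$dataset)
  ds$dailies <- flag_nonwear(ds$dailies)
  sel <- select_trend(ds, "steps", degrees = 0:2)
  tab <- sel$table
  expect_true(all(tab$converged))
  # chi-square equals twice the log-likelihood gain over the selection path
  cur <- tab$logLik[1]
  for (i in 2:nrow(tab)) {
    expect_equal(tab$chisq[i], 2 * (tab$logLik[i] - cur), tolerance = 1e-8)
    if (!is.na(tab$p[i]) && tab$p[i] < sel$alpha) cur <- tab$logLik[i]
  }
  # AIC/BIC follow their definitions and match stats::AIC on the model
  for (d in names(sel$fits)) {
    f <- sel$fits[[d]]
    expect_equal(f$AIC, 2 * f$n_params - 2 * f$logLik)
    expect_equal(f$BIC, f$n_params * log(f$n_obs) - 2 * f$logLik)
    expect_equal(f$AIC, AIC(f$model), tolerance = 1e-8)
  }
  # likelihood monotonicity of nested fixed effects
  expect_true(all(diff(tab$logLik) >= -1e-6))
})

test_that("daily AR(1) autocorrelation is recovered", {
  cfg <- simulation_config(ar_phi_steps = 0.5, step_weekday_linear = 0,
                           step_weekday_quadratic = 0, p_nonwear_day = 0)
  ds <- harmonize_onset(generate_cohort(cfg, seed = 12)$dataset)
  ds$dailies <- flag_nonwear(ds$dailies)
  fit <- fit_trend(ds, trend_spec("steps", degree = 0))
  expect_true(fit$converged)
  expect_lt(abs(fit$varcomp$phi - 0.5), 0.15)
  expect_true(fit$varcomp$phi >= 0 && fit$varcomp$phi < 1)
})

test_that("diagnostics flag degenerate residuals and detect heavy tails", {
  cfg <- tiny_config()
  ds <- harmonize_onset(generate_cohort(cfg, seed = 3)$dataset)
  ds$dailies <- flag_nonwear(ds$dailies)
  fit <- fit_trend(ds, trend_spec("steps", degree = 1))
  dg <- run_diagnostics(fit)
  expect_false(dg$degenerate)
  expect_true(is.numeric(dg$normality$p))
  degen <- fit
  degen$residuals$residual <- rep(0, nrow(degen$residuals))
  expect_true(run_diagnostics(degen)$degenerate)
  # heavy-tailed residuals are flagged as non-normal
  set.seed(4)
  heavy <- fit
  heavy$residuals$residual <- rt(nrow(heavy$residuals), df = 2)
  expect_lt(run_diagnostics(heavy)$normality$p, 1e-4)
})
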