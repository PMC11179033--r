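# Synthetic cohort generator: determinism, latent-model contracts, trial
# calibration, count conservation, and config validation.

test_that("generation is deterministic in (config, seed) and responsive to seed", {
  cfg <- tiny_config()
  s1 <- generate_cohort(cfg, seed = 42)
  s2 <- generate_cohort(cfg, seed = 42)
  expect_identical(s1, s2)
  s3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(s1$dataset$sessions$d_prime,
                         s3$dataset$sessions$d_prime))
})

test_that("noiseless learner follows the inverse practice curve exactly", {
  cfg <- simulation_config(
    n_participants = 1L, n_days = 10L,
    intercept_mean = 0, intercept_sd = 0,
    asymptote_mean = 2, asymptote_sd = 0,
    slope_mean = 4, slope_sd = 0, slope_asymptote_cor = 0,
    fraction_non_learners = 0,
    diurnal_linear = 0, diurnal_quadratic = 0,
    noise_sd_dprime = 0, noise_sd_mood = 0, noise_sd_steps = 0,
    noise_sd_hr = 0,
    p_session_missing = 0, p_mood_missing = 0, p_nonwear_day = 0)
  sim <- generate_cohort(cfg, seed = 7)
  s <- sim$dataset$sessions
  s <- s[order(s$session_timestamp), ]
  # latent at assessment k is a - b/k = 2 - 4/k
  expect_equal(s$d_prime[4], 1.0)
  expect_equal(s$d_prime[1], -2.0)
  expect_equal(s$d_prime[8], 2 - 4 / 8)
  # non-learner config: flat at the intercept
  cfg2 <- simulation_config(
    n_participants = 1L, n_days = 5L,
    intercept_mean = 1.3, intercept_sd = 0, fraction_non_learners = 1,
    diurnal_linear = 0, diurnal_quadratic = 0,
    noise_sd_dprime = 0, p_session_missing = 0)
  s2 <- generate_cohort(cfg2, seed = 7)$dataset$sessions
  expect_true(all(abs(s2$d_prime - 1.3) < 1e-12))
})

test_that("session trials have the documented target structure", {
  cfg <- simulation_config()
  for (seed in 1:5) {
    tr <- generate_session_trials(1.2, cfg, seed = seed)
    expect_equal(nrow(tr), 30L)
    expect_equal(sum(tr$is_target), 9L)
    expect_false(any(tr$is_target[1:2]))
    # upper bound: all targets answered, no false alarms, for every seed
    trb <- generate_session_trials(3.33, cfg, seed = seed)
    expect_identical(trb$responded, trb$is_target)
  }
  expect_error(generate_session_trials(3.5, cfg, seed = 1), "outside")
  # zero sensitivity: symmetric response probabilities
  pr <- cogema:::solve_response_probs(0, 9, 21)
  expect_equal(unname(pr["hit"]), unname(pr["fa"]))
})

test_that("scored simulated sessions match the latent d-prime in expectation", {
  # 10,000 sessions via the calibrated response model, scored by the
  # package scorer
  set.seed(314)
  pr <- cogema:::solve_response_probs(1.5, 9, 21)
  h <- rbinom(10000, 9, pr["hit"])
  f <- rbinom(10000, 21, pr["fa"])
  expect_lt(abs(mean(dprime_from_counts(h, f, 9, 21)) - 1.5), 0.05)
  # and through the full trial generator + session scorer
  cfg <- simulation_config()
  d <- vapply(1:400, function(s) {
    score_session(generate_session_trials(1.5, cfg, seed = s))$d_prime
  }, numeric(1))
  expect_lt(abs(mean(d) - 1.5), 0.08)
})

test_that("session counts honour the missingness rate and mood totals stay in range", {
  cfg <- simulation_config(p_session_missing = 0.2)
  sim <- generate_cohort(cfg, seed = 99)
  n_expected <- 30 * 42 * 3 * 0.8
  sd_bin <- sqrt(30 * 42 * 3 * 0.2 * 0.8)
  expect_lt(abs(nrow(sim$dataset$sessions) - n_expected), 4 * sd_bin)
  m <- sim$dataset$moods
  expect_true(all(m$total >= 3 & m$total <= 12))
  items <- m$item_interest + m$item_down + m$item_concentration
  expect_identical(items, m$total)
  expect_true(all(m[, c("item_interest", "item_down",
                        "item_concentration")] >= 1))
  expect_true(all(m[, c("item_interest", "item_down",
                        "item_concentration")] <= 4))
  # at most one mood response per participant-day (evening prompt
  # suppressed after an afternoon response)
  key <- paste(m$participant_id, as.Date(m$timestamp, tz = "UTC"))
  expect_false(anyDuplicated(key) > 0)
  # learner ledger: non-learners have zero slope
  tp <- sim$truth$participants
  expect_true(all(tp$slope[!tp$learner] == 0))
  expect_equal(sum(!tp$learner), 3L)  # 10% of 30
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(ar_phi_mood = 1), "ar_phi_mood")
  expect_error(simulation_config(n_target_trials = 29), "n_target_trials")
  expect_error(simulation_config(noise_sd_mood = -1), "noise_sd_mood")
  expect_error(simulation_config(p_mood_missing = 1.4), "p_mood_missing")
  expect_error(simulation_config(nonsense = 1), "nonsense")
})
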