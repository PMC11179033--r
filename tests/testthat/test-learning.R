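# Learning curves: smoothing, exact inverse-curve recovery, the 90%
# learning-rate closed form, day mapping, and exploratory correlations.

test_that("trailing moving average uses partial start windows and preserves slope", {
  expect_equal(smooth_series(c(1, 2, 3, 4)), c(1, 1.5, 2, 3))
  expect_equal(smooth_series(rep(2.5, 10)), rep(2.5, 10))
  # arithmetic ramp: trailing 3-average is the series shifted by one step,
  # so the slope is preserved in the full-window region
  ramp <- 2 + 0.5 * (1:20)
  sm <- smooth_series(ramp, 3)
  expect_equal(diff(sm[3:20]), rep(0.5, 17))
  expect_equal(sm[3:20], ramp[3:20] - 0.5)
  expect_error(smooth_series(numeric(0)), "empty")
})

test_that("baseline adjustment subtracts the starting point on the assessment axis", {
  sc <- data.frame(assessment_index = c(2L, 1L, 3L),
                   d_prime = c(1.5, 1.0, 2.0), day_index = c(1L, 1L, 2L))
  adj <- baseline_adjust(sc, 0.5)
  expect_equal(adj$X, 1:3)
  expect_equal(adj$Y, c(0.5, 1.0, 1.5))
  expect_equal(baseline_adjust(sc, 0)$Y, c(1.0, 1.5, 2.0))
})

test_that("noiseless inverse curves are recovered exactly, with the rate identity", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.3, 3)
    b <- runif(1, 0.3, 5)
    X <- 1:30
    adj <- data.frame(X = X, Y = a - b / X)
    cv <- fit_inverse_curve(adj)
    expect_equal(cv$a, a, tolerance = 1e-6)
    expect_equal(cv$b, b, tolerance = 1e-6)
    expect_true(cv$fit_adequate)
    rate <- learning_rate_90(cv$a, cv$b)
    # fitted curve evaluated at the 90% rate equals 0.9 * asymptote
    expect_equal(cv$a - cv$b / rate, 0.9 * cv$a, tolerance = 1e-9)
    # scale properties of the closed form 10*b/a
    expect_equal(learning_rate_90(a, 3 * b), 3 * rate, tolerance = 1e-6)
    expect_equal(learning_rate_90(2 * a, b), rate / 2, tolerance = 1e-6)
  }
  expect_equal(learning_rate_90(2, 4), 20)
})

test_that("independent oracle: the inverse fit equals closed-form linear least squares", {
  # Y = a - b * (1/X) is linear in (a, b); lm() on 1/X is the oracle
  set.seed(12)
  X <- 1:40
  Y <- 1.8 - 2.6 / X + rnorm(40, 0, 0.3)
  cv <- fit_inverse_curve(data.frame(X = X, Y = Y))
  or <- lm(Y ~ I(1 / X))
  expect_equal(cv$a, unname(coef(or)[1]), tolerance = 1e-6)
  expect_equal(cv$b, unname(-coef(or)[2]), tolerance = 1e-6)
  sm <- summary(or)$coefficients
  expect_equal(cv$se_a, unname(sm[1, 2]), tolerance = 1e-4)
  expect_equal(cv$se_b, unname(sm[2, 2]), tolerance = 1e-4)
  expect_equal(cv$p_b, unname(sm[2, 4]), tolerance = 1e-4)
})

test_that("flat series yield a nonsignificant slope and an inadequate fit", {
  adj <- data.frame(X = 1:25, Y = rep(1, 25))
  cv <- fit_inverse_curve(adj)
  expect_lt(abs(cv$b), 1e-6)
  expect_false(cv$fit_adequate)
  expect_true(is.na(learning_rate_90(NA_real_, 1)))
  short <- fit_inverse_curve(data.frame(X = 1:3, Y = c(1, 2, 3)))
  expect_false(short$fit_adequate)
  expect_match(short$reason, "too few")
})

test_that("the 90% learning day is the cumulative-assessment boundary", {
  # 3 assessments/day, no gaps: ceiling(rate 20) = assessment 20 -> day 7
  sc <- data.frame(assessment_index = 1:30, day_index = rep(1:10, each = 3))
  expect_equal(map_rate_to_day(20, sc), 7L)
  expect_equal(map_rate_to_day(0.5, sc), 1L)
  expect_true(is.na(map_rate_to_day(31, sc)))
  # with missing sessions the boundary shifts later
  sc2 <- sc[-(1:6), ]
  sc2$assessment_index <- seq_len(nrow(sc2))
  expect_equal(map_rate_to_day(20, sc2), 9L)
})

test_that("cohort-level curves recover generator truth given true starting points", {
  cfg <- simulation_config(fraction_non_learners = 0)
  sim <- generate_cohort(cfg, seed = 31)
  ds <- clean_dataset(sim$dataset)$dataset
  tp <- sim$truth$participants
  curves <- fit_learning_curves(
    ds, data.frame(participant_id = tp$participant_id,
                   starting_point = tp$intercept))
  m <- merge(curves, tp, by = "participant_id")
  expect_gt(cor(m$asymptote_a, m$asymptote), 0.9)
  expect_gt(sum(m$fit_adequate) / nrow(m), 0.8)
  expect_equal(m$stable_max, m$asymptote_a + m$starting_point)
  # smoothing biases the slope upward; the unsmoothed sensitivity fit
  # tracks the generating slope more closely
  expect_gt(cor(m$b_unsmoothed, m$slope), 0.7)
})

test_that("learning-parameter correlations switch method on normality and hit trivial cases", {
  set.seed(41)
  n <- 24
  curves <- data.frame(participant_id = sprintf("P%02d", 1:n),
                       asymptote_a = rnorm(n, 1, 0.3),
                       slope_b = rnorm(n, 2, 0.5),
                       fit_adequate = TRUE)
  # identical vectors correlate exactly 1
  summ <- data.frame(participant_id = curves$participant_id,
                     mirror = curves$asymptote_a)
  res <- correlate_learning_params(curves, summ, n_boot = 200)
  expect_equal(res$estimate[res$parameter == "asymptote_a"], 1)
  # heavily skewed variable forces the rank-based method
  summ2 <- data.frame(participant_id = curves$participant_id,
                      skewed = exp(rnorm(n, 0, 1.5)))
  res2 <- correlate_learning_params(curves, summ2, n_boot = 200)
  expect_true(all(res2$method == "spearman"))
  expect_true(all(res2$conf_low <= res2$estimate &
                    res2$estimate <= res2$conf_high))
  expect_error(correlate_learning_params(curves[1:3, ], summ),
               "at least 5")
})
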