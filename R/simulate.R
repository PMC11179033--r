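# Synthetic cohort generator: produces datasets with the statistical
# structure the downstream analyses assume (inverse-curve practice effects,
# diurnal/weekday structure, step-mood coupling, AR(1) noise, missingness),
# together with a ground-truth ledger for parameter-recovery studies.

#' Stationary AR(1) noise with a given marginal standard deviation
#' @noRd
ar1_noise <- function(n, phi, sd_marginal) {
  if (n == 0L) return(numeric(0))
  e <- rnorm(n)
  if (sd_marginal == 0) return(numeric(n))
  x <- numeric(n)
  x[1] <- e[1] * sd_marginal
  if (n > 1) {
    innov_sd <- sd_marginal * sqrt(1 - phi^2)
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i] * innov_sd
  }
  x
}

#' Expected bounded d-prime when hit/false-alarm placement is symmetric
#'
#' For response criteria placed symmetrically about the midpoint
#' (\eqn{z_h = \delta}, \eqn{z_f = -\delta}), computes the exact expectation
#' of the corrected, clamped d-prime over the binomial distribution of hit
#' and false-alarm counts.
#' @noRd
expected_dprime <- function(delta, n_targets, n_nontargets,
                            bound = DPRIME_BOUND) {
  ph <- pnorm(delta)
  pf <- pnorm(-delta)
  qh <- qnorm((0:n_targets + 0.5) / (n_targets + 1))
  qf <- qnorm((0:n_nontargets + 0.5) / (n_nontargets + 1))
  wh <- dbinom(0:n_targets, n_targets, ph)
  wf <- dbinom(0:n_nontargets, n_nontargets, pf)
  d <- clamp(outer(qh, qf, "-"), -bound, bound)
  as.numeric(t(wh) %*% d %*% wf)
}

#' Response probabilities that realise a latent d-prime in expectation
#'
#' Solves for the symmetric criterion offset \eqn{\delta} such that the
#' expected corrected-and-clamped d-prime of a simulated session equals
#' `latent_dprime`; returns the hit and false-alarm probabilities
#' \eqn{(\Phi(\delta), \Phi(-\delta))}. At the scoring bounds the
#' probabilities degenerate to 1 and 0 (or 0 and 1).
#' @noRd
solve_response_probs <- function(latent_dprime, n_targets, n_nontargets,
                                 bound = DPRIME_BOUND) {
  if (abs(latent_dprime) > bound + 1e-12) {
    stop(sprintf("latent d-prime %.3f outside the attainable range [-%.2f, %.2f]",
                 latent_dprime, bound, bound), call. = FALSE)
  }
  s <- sign(latent_dprime)
  al <- abs(latent_dprime)
  hi <- expected_dprime(10, n_targets, n_nontargets, bound)
  if (al >= hi - 1e-10) {
    # degenerate: respond to every target, never to a non-target
    ph <- 1
    pf <- 0
  } else {
    delta <- uniroot(function(d) {
      expected_dprime(d, n_targets, n_nontargets, bound) - al
    }, lower = 0, upper = 10, tol = 1e-10)$root
    ph <- pnorm(delta)
    pf <- pnorm(-delta)
  }
  if (s < 0) c(hit = pf, fa = ph) else c(hit = ph, fa = pf)
}

#' Generate the trial events of one simulated n-back session
#'
#' Emits `trials_per_session` trials with exactly `n_target_trials` 2-back
#' matches (never in the first two positions). Response probabilities on
#' target and non-target trials are placed symmetrically about the
#' criterion midpoint and calibrated so that the expected corrected,
#' clamped d-prime of the scored session equals `latent_dprime`. At the
#' upper scoring bound every target is answered and no false alarms occur,
#' for every seed.
#'
#' @param latent_dprime target expected d-prime, within \eqn{\pm 3.33}.
#' @param config a [simulation_config()].
#' @param seed integer seed (the function restores the caller's RNG state).
#' @return data frame: `trial_index`, `is_target`, `responded`.
#' @export
generate_session_trials <- function(latent_dprime, config = simulation_config(),
                                    seed = 1L) {
  validate_config(config)
  nt <- config$trials_per_session
  k <- config$n_target_trials
  if (nt < 3) stop("trials_per_session must be >= 3", call. = FALSE)
  pr <- solve_response_probs(latent_dprime, k, nt - k)
  with_seed(seed, {
    pos <- sort(sample(3:nt, k))
    is_target <- seq_len(nt) %in% pos
    responded <- logical(nt)
    if (pr["hit"] >= 1 && pr["fa"] <= 0) {
      responded <- is_target
    } else if (pr["hit"] <= 0 && pr["fa"] >= 1) {
      responded <- !is_target
    } else {
      responded[is_target] <- runif(k) < pr["hit"]
      responded[!is_target] <- runif(nt - k) < pr["fa"]
    }
    data.frame(trial_index = seq_len(nt), is_target = is_target,
               responded = responded)
  })
}

session_windows <- function(sessions_per_day) {
  if (sessions_per_day == 1L) {
    14.5
  } else {
    seq(9, 20, length.out = sessions_per_day)
  }
}

poly_day <- function(coefs, day) {
  coefs[1] * day + coefs[2] * day^2 + coefs[3] * day^3
}

split_mood_items <- function(total) {
  t <- total - 3L
  vapply(0:2, function(i) 1L + pmin(3L, pmax(0L, t - 3L * i)), integer(length(total)))
}

#' Generate a synthetic study cohort with ground truth
#'
#' Simulates the full observation model: latent cognition at a participant's
#' k-th completed assessment equals \eqn{intercept + a - b/k} for learners
#' (\eqn{intercept} alone for non-learners) plus polynomial day trends,
#' quadratic time-of-day structure, and AR(1) noise, clamped to the scoring
#' bounds; mood totals follow a participant baseline plus a linear day
#' trend, coupling to same-day and previous-day step fluctuations and
#' same-day cognitive fluctuations, and AR(1) noise, discretised to the
#' 3-12 questionnaire range; steps (square-root scale) and heart rate (log
#' scale) carry quadratic weekday structure; non-wear days corrupt the
#' observed activity record (steps below 100, heart rate missing); session
#' and mood nonresponse are Bernoulli per prompt, with the evening mood
#' prompt suppressed whenever the afternoon response exists. Output is
#' byte-identical for identical `(config, seed)`.
#'
#' @param config a [simulation_config()].
#' @param seed integer; defaults to `config$seed`.
#' @param include_trials also generate trial-level events for every
#'   completed session (slower; the session stream's `d_prime` remains the
#'   clamped latent value, while scored trials reproduce it in expectation).
#' @return list with elements `dataset` (a raw [study_dataset()]; study-day
#'   fields are assigned later by [harmonize_onset()]) and `truth`
#'   (class `"cogema_truth"`: per-participant parameters and the global
#'   coupling/trend coefficients).
#' @export
generate_cohort <- function(config = simulation_config(), seed = config$seed,
                            include_trials = FALSE) {
  validate_config(config)
  with_seed(seed, {
    n <- config$n_participants
    ids <- sprintf("P%02d", seq_len(n))
    start0 <- as.Date(config$start_date)
    starts <- start0 + (seq_len(n) - 1L) %% 7L  # staggered enrolment
    # participant-level latent parameters
    S <- rnorm(n, config$intercept_mean, config$intercept_sd)
    rho <- config$slope_asymptote_cor
    a <- numeric(n)
    b <- numeric(n)
    for (i in seq_len(n)) {
      for (try in 1:1000) {
        z1 <- rnorm(1)
        z2 <- rnorm(1)
        ai <- config$asymptote_mean + config$asymptote_sd * z1
        bi <- config$slope_mean +
          config$slope_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
        if (ai > 0 && bi >= 0) break
      }
      a[i] <- ai
      b[i] <- bi
    }
    n_nl <- round(config$fraction_non_learners * n)
    nonlearner <- rep(FALSE, n)
    if (n_nl > 0) nonlearner[sample.int(n, n_nl)] <- TRUE
    a[nonlearner] <- 0
    b[nonlearner] <- 0
    mood_base <- rnorm(n, config$mood_baseline_mean, config$mood_baseline_sd)
    step_level <- pmax(rnorm(n, config$step_mean, config$step_sd), 500)
    hr_level <- pmax(rnorm(n, config$hr_mean, config$hr_sd), 40)

    centers <- session_windows(config$sessions_per_day)
    sess_list <- vector("list", n)
    mood_list <- vector("list", n)
    daily_list <- vector("list", n)
    trial_list <- if (include_trials) list() else NULL

    for (i in seq_len(n)) {
      days <- seq_len(config$n_days)
      dates <- starts[i] + days - 1L
      wd <- weekday_of(dates)

      # --- sessions ------------------------------------------------------
      grid <- expand.grid(s = seq_along(centers), day = days)
      grid <- grid[order(grid$day, grid$s), ]
      tod <- clamp(centers[grid$s] + rnorm(nrow(grid), 0, 0.75), 6, 23.75)
      completed <- runif(nrow(grid)) >= config$p_session_missing
      gc_day <- grid$day[completed]
      gc_tod <- tod[completed]
      kk <- seq_len(sum(completed))
      noise <- ar1_noise(length(kk), config$ar_phi_dprime,
                         config$noise_sd_dprime)
      practice <- if (nonlearner[i]) 0 else a[i] - b[i] / kk
      latent <- S[i] + practice +
        poly_day(config$trend_coefs$dprime, gc_day) +
        config$diurnal_linear * gc_tod +
        config$diurnal_quadratic * gc_tod^2 + noise
      dp <- clamp(latent, -DPRIME_BOUND, DPRIME_BOUND)
      ts <- as.POSIXct(paste(starts[i] + gc_day - 1L, "00:00:00"),
                       tz = "UTC") + round(gc_tod * 3600)
      sess_list[[i]] <- data.frame(
        participant_id = ids[i], session_timestamp = ts,
        hits = NA_integer_, false_alarms = NA_integer_,
        n_targets = config$n_target_trials,
        n_nontargets = config$trials_per_session - config$n_target_trials,
        d_prime = dp, stringsAsFactors = FALSE
      )
      # per-day mean cognitive fluctuation, for mood coupling
      dp_fluct <- rep(0, config$n_days)
      if (length(gc_day)) {
        agg <- tapply(noise, gc_day, mean)
        dp_fluct[as.integer(names(agg))] <- agg
      }
      if (include_trials && length(gc_day)) {
        for (j in seq_along(gc_day)) {
          tr <- generate_session_trials_local(dp[j], config)
          tr$participant_id <- ids[i]
          tr$session_timestamp <- ts[j]
          trial_list[[length(trial_list) + 1L]] <- tr
        }
      }

      # --- daily activity / heart rate ----------------------------------
      wk_step <- config$step_weekday_linear * wd +
        config$step_weekday_quadratic * wd^2
      mu_sqrt <- sqrt(step_level[i]) + wk_step +
        poly_day(config$trend_coefs$steps, days)
      s_noise <- ar1_noise(config$n_days, config$ar_phi_steps,
                           config$noise_sd_steps)
      sqrt_true <- pmax(mu_sqrt + s_noise, 0)
      true_steps <- round(sqrt_true^2)
      step_dev <- true_steps - pmax(mu_sqrt, 0)^2

      wk_hr <- config$hr_weekday_linear * wd +
        config$hr_weekday_quadratic * wd^2
      log_hr <- log(hr_level[i]) + wk_hr +
        poly_day(config$trend_coefs$heart_rate, days) +
        ar1_noise(config$n_days, config$ar_phi_hr, config$noise_sd_hr)
      hr_true <- exp(log_hr)

      nonwear <- runif(config$n_days) < config$p_nonwear_day
      obs_steps <- true_steps
      obs_steps[nonwear] <- sample(0:99, sum(nonwear), replace = TRUE)
      obs_hr <- round(hr_true, 1)
      obs_hr[nonwear] <- NA_real_
      daily_list[[i]] <- data.frame(
        participant_id = ids[i], date = dates,
        step_count = obs_steps, mean_heart_rate = obs_hr,
        stringsAsFactors = FALSE
      )

      # --- mood ----------------------------------------------------------
      resp_aft <- runif(config$n_days) >= config$p_mood_missing
      resp_eve <- !resp_aft & runif(config$n_days) >= config$p_mood_missing
      responded <- resp_aft | resp_eve
      m_tod <- ifelse(resp_aft,
                      clamp(rnorm(config$n_days, 15, 0.9), 12, 17.9),
                      clamp(rnorm(config$n_days, 19.5, 0.7), 18, 21.9))
      m_noise <- ar1_noise(sum(responded), config$ar_phi_mood,
                           config$noise_sd_mood)
      rd <- days[responded]
      lag_dev <- c(0, step_dev[-config$n_days])
      latent_mood <- mood_base[i] + config$mood_day_trend * (rd - 1) +
        config$coupling_dprime_mood * dp_fluct[rd] +
        config$coupling_step_mood_same_day * step_dev[rd] +
        config$coupling_step_mood_lag1 * lag_dev[rd] + m_noise
      total <- as.integer(round(clamp(latent_mood, 3, 12)))
      items <- split_mood_items(total)
      m_ts <- as.POSIXct(paste(starts[i] + rd - 1L, "00:00:00"),
                         tz = "UTC") + round(m_tod[responded] * 3600)
      mood_list[[i]] <- data.frame(
        participant_id = ids[i], timestamp = m_ts,
        item_interest = items[, 1], item_down = items[, 2],
        item_concentration = items[, 3], total = total,
        stringsAsFactors = FALSE
      )
    }

    sessions <- do.call(rbind, sess_list)
    moods <- do.call(rbind, mood_list)
    dailies <- do.call(rbind, daily_list)
    trials <- if (include_trials) do.call(rbind, trial_list) else NULL
    truth <- structure(list(
      participants = data.frame(
        participant_id = ids, start_date = starts,
        intercept = S, asymptote = a, slope = b, learner = !nonlearner,
        mood_baseline = mood_base, step_level = step_level,
        hr_level = hr_level, stringsAsFactors = FALSE
      ),
      couplings = list(
        step_mood_same_day = config$coupling_step_mood_same_day,
        step_mood_lag1 = config$coupling_step_mood_lag1,
        dprime_mood = config$coupling_dprime_mood
      ),
      trend = list(
        mood_day_trend = config$mood_day_trend,
        diurnal_linear = config$diurnal_linear,
        diurnal_quadratic = config$diurnal_quadratic,
        trend_coefs = config$trend_coefs
      ),
      config = config, seed = as.integer(seed)
    ), class = "cogema_truth")
    list(dataset = study_dataset(sessions, moods, dailies, trials = trials),
         truth = truth)
  })
}

# trial generation inside the cohort RNG stream (no seed reset)
generate_session_trials_local <- function(latent_dprime, config) {
  nt <- config$trials_per_session
  k <- config$n_target_trials
  pr <- solve_response_probs(latent_dprime, k, nt - k)
  pos <- sort(sample(3:nt, k))
  is_target <- seq_len(nt) %in% pos
  responded <- logical(nt)
  if (pr["hit"] >= 1 && pr["fa"] <= 0) {
    responded <- is_target
  } else if (pr["hit"] <= 0 && pr["fa"] >= 1) {
    responded <- !is_target
  } else {
    responded[is_target] <- runif(k) < pr["hit"]
    responded[!is_target] <- runif(nt - k) < pr["fa"]
  }
  data.frame(trial_index = seq_len(nt), is_target = is_target,
             responded = responded)
}
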