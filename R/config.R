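#' Simulation configuration for synthetic EMA cohorts
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' describe the study design the package targets: 30 participants monitored
#' for 42 days, 2-back sessions prompted three times daily (30 trials, 9
#' two-back targets drawn from a pool of 227 symbols), a three-item mood
#' questionnaire answered at most once per day (afternoon, with an evening
#' fallback prompt), and passive daily step counts and mean heart rate.
#'
#' Latent cognition follows an inverse practice curve on the participant's
#' completed-assessment index \eqn{k}: \eqn{intercept + a - b/k} for learners
#' and \eqn{intercept} alone for non-learners, plus quadratic time-of-day
#' structure and AR(1) noise. Mood totals carry a subtle linear day trend and
#' same-day / previous-day coupling to step-count fluctuations plus coupling
#' to same-day cognitive fluctuations. Steps (square-root scale) and heart
#' rate (log scale) carry quadratic day-of-week structure.
#'
#' @param ... named overrides of any default field (unknown names error).
#' @return A list with class `"cogema_config"`, validated.
#' @details Default magnitudes mirror the published cohort: stable maximal
#'   d-prime near 1.94, 90% learning rates near 22 assessments, a
#'   slope-asymptote correlation of 0.70, roughly 2% non-wear days, and
#'   negative step-to-mood coupling (higher activity, lower i.e. better
#'   mood totals) of a size matching the within-person coupling
#'   correlations implied by published test statistics.
#'   `trend_coefs` holds optional
#'   polynomial day-trend coefficients per outcome (used mainly in
#'   simulation studies of trend selection); the practice effect can be
#'   switched off by setting `fraction_non_learners = 1`.
#' @examples
#' cfg <- simulation_config(n_participants = 4, n_days = 7)
#' cfg$n_days
#' @export
simulation_config <- function(...) {
  cfg <- list(
    # design
    n_participants = 30L,
    n_days = 42L,
    sessions_per_day = 3L,
    trials_per_session = 30L,
    n_target_trials = 9L,
    symbol_pool_size = 227L,
    start_date = "2023-05-01",   # cohort enrolment anchor (staggered per id)
    # learning-curve population
    intercept_mean = 1.0, intercept_sd = 0.4,
    asymptote_mean = 0.95, asymptote_sd = 0.35,
    slope_mean = 2.1, slope_sd = 0.7,
    slope_asymptote_cor = 0.70,
    fraction_non_learners = 0.1,
    # diurnal structure on d-prime (per hour, per hour^2; raw clock hours)
    diurnal_linear = -0.02, diurnal_quadratic = 0.001,
    # mood
    mood_baseline_mean = 6, mood_baseline_sd = 1.5,
    mood_day_trend = -0.01,
    # activity / heart rate (weekday terms on transformed scales, raw 1-7
    # weekday coding)
    step_mean = 6000, step_sd = 2000,
    step_weekday_linear = 3.52, step_weekday_quadratic = -0.64,
    hr_mean = 75, hr_sd = 8,
    hr_weekday_linear = 0.01, hr_weekday_quadratic = -0.002,
    # couplings (score units per raw step; score units per d-prime unit).
    # The step couplings are anchored on the within-person coupling
    # correlation implied by published test statistics (|rho| ~ 0.15-0.2)
    # rather than a raw per-step coefficient, which is only meaningful
    # relative to a particular residual step variance.
    coupling_step_mood_same_day = -1e-4,
    coupling_step_mood_lag1 = -1e-4,
    coupling_dprime_mood = -0.06,
    # noise (marginal SDs on the analysis scale of each outcome) and serial
    # correlation of the noise
    noise_sd_dprime = 0.4, noise_sd_mood = 1.0,
    noise_sd_steps = 12, noise_sd_hr = 0.04,
    ar_phi_dprime = 0.3, ar_phi_mood = 0.3,
    ar_phi_steps = 0.0, ar_phi_hr = 0.3,
    # missingness
    p_nonwear_day = 0.02,
    p_session_missing = 0.15,
    p_mood_missing = 0.25,
    # optional polynomial day trends per outcome (length-3 vectors: linear,
    # quadratic, cubic coefficients on the study-day index)
    trend_coefs = list(
      dprime = c(0, 0, 0), steps = c(0, 0, 0), heart_rate = c(0, 0, 0)
    ),
    seed = 20230501L
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) {
      stop_field(bad[1], "unknown configuration field")
    }
    cfg[names(over)] <- over
  }
  class(cfg) <- "cogema_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every field's type and range; errors name the offending field.
#'
#' @param config a `"cogema_config"` list.
#' @return `config`, invisibly, if valid.
#' @export
validate_config <- function(config) {
  chk_count <- function(field, min = 1L) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < min ||
        v != round(v)) {
      stop_field(field, sprintf("must be an integer >= %d", min))
    }
  }
  chk_num <- function(field, lo = -Inf, hi = Inf) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < lo || v > hi) {
      stop_field(field, sprintf("must be a number in [%s, %s]", lo, hi))
    }
  }
  for (f in c("n_participants", "n_days", "sessions_per_day",
              "trials_per_session", "n_target_trials", "symbol_pool_size")) {
    chk_count(f)
  }
  if (config$trials_per_session < 3) {
    stop_field("trials_per_session", "a 2-back session needs >= 3 trials")
  }
  if (config$n_target_trials > config$trials_per_session - 2) {
    stop_field("n_target_trials",
               "cannot exceed trials_per_session - 2 (trials 1-2 are never 2-back targets)")
  }
  for (f in c("fraction_non_learners", "p_nonwear_day", "p_session_missing",
              "p_mood_missing")) {
    chk_num(f, 0, 1)
  }
  for (f in c("intercept_sd", "asymptote_sd", "slope_sd", "mood_baseline_sd",
              "step_sd", "hr_sd", "noise_sd_dprime", "noise_sd_mood",
              "noise_sd_steps", "noise_sd_hr")) {
    chk_num(f, 0)
  }
  for (f in c("ar_phi_dprime", "ar_phi_mood", "ar_phi_steps", "ar_phi_hr")) {
    v <- config[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
      stop_field(f, "autoregressive coefficient must lie in [0, 1)")
    }
  }
  chk_num("slope_asymptote_cor", -1, 1)
  chk_num("asymptote_mean", lo = .Machine$double.eps)
  chk_num("slope_mean", 0)
  chk_num("step_mean", 0)
  chk_num("hr_mean", 0)
  if (is.na(as.Date(config$start_date, optional = TRUE))) {
    stop_field("start_date", "must parse as a date (YYYY-MM-DD)")
  }
  tc <- config$trend_coefs
  if (!is.list(tc) ||
      !all(c("dprime", "steps", "heart_rate") %in% names(tc)) ||
      !all(vapply(tc, function(x) is.numeric(x) && length(x) == 3L, TRUE))) {
    stop_field("trend_coefs",
               "must be a list with numeric length-3 entries dprime/steps/heart_rate")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1L ||
      is.na(config$seed)) {
    stop_field("seed", "must be a single integer")
  }
  invisible(config)
}

#' Read a simulation or pipeline configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return a validated `"cogema_config"` object.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("config must be a .yaml or .json file", call. = FALSE)
  )
  if (!is.null(raw$trend_coefs)) {
    raw$trend_coefs <- lapply(raw$trend_coefs, as.numeric)
  }
  do.call(simulation_config, raw)
}

#' @export
print.cogema_config <- function(x, ...) {
  cat("<cogema simulation config>\n")
  cat(sprintf("  %d participants x %d days, %d sessions/day (%d trials, %d targets)\n",
              x$n_participants, x$n_days, x$sessions_per_day,
              x$trials_per_session, x$n_target_trials))
  cat(sprintf("  learning: intercept %.2f (%.2f), asymptote %.2f (%.2f), slope %.2f (%.2f), %d%% non-learners\n",
              x$intercept_mean, x$intercept_sd, x$asymptote_mean,
              x$asymptote_sd, x$slope_mean, x$slope_sd,
              round(100 * x$fraction_non_learners)))
  cat(sprintf("  missingness: sessions %.2f, mood %.2f, non-wear %.2f; seed %d\n",
              x$p_session_missing, x$p_mood_missing, x$p_nonwear_day,
              as.integer(x$seed)))
  invisible(x)
}
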