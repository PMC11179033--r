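# Hierarchical change-over-time models: polynomial fixed effects of time,
# participant-level random intercept and slope, and autoregressive residual
# correlation (continuous-time AR(1) for irregularly sampled streams, daily
# AR(1) for daily summaries), estimated by maximum likelihood via nlme::lme
# and compared by sequential likelihood-ratio tests.

#' Specify a change-over-time model
#'
#' @param outcome `"dprime"`, `"mood"`, `"steps"`, or `"heart_rate"`.
#' @param degree polynomial degree of time: 0 (intercept-only) to 3.
#' @param transform analysis-scale transform; defaults per outcome
#'   (identity, identity, sqrt, log).
#' @param covariance `"car1_continuous_time"` (irregular sampling;
#'   \eqn{corr = \phi^{|t_i - t_j|}} on continuous days),
#'   `"ar1_daily"` (\eqn{\phi^{|lag|}} on the day index), or `"none"`
#'   (independent residuals, mainly for validation against generalized
#'   least squares). Defaults per outcome.
#' @param random_effects `"intercept_slope"` (default: participant-level
#'   random intercept and random slope on time) or `"intercept"`.
#' @return list with class `"trend_spec"`.
#' @export
trend_spec <- function(outcome = c("dprime", "mood", "steps", "heart_rate"),
                       degree = 1,
                       transform = NULL,
                       covariance = NULL,
                       random_effects = c("intercept_slope", "intercept")) {
  outcome <- match.arg(outcome)
  random_effects <- match.arg(random_effects)
  if (!degree %in% 0:3) stop("degree must be 0, 1, 2, or 3", call. = FALSE)
  transform <- transform %||% default_transform(outcome)
  transform <- match.arg(transform, c("identity", "log", "sqrt"))
  covariance <- covariance %||% default_covariance(outcome)
  covariance <- match.arg(covariance,
                          c("car1_continuous_time", "ar1_daily", "none"))
  structure(list(outcome = outcome, degree = as.integer(degree),
                 transform = transform, covariance = covariance,
                 random_effects = random_effects),
            class = "trend_spec")
}

#' Build the analysis frame of one outcome
#'
#' Continuous streams (d-prime, mood) use fractional days since onset from
#' the timestamps; daily streams use the integer day index. Only active
#' (non-excluded, wearing) records enter.
#' @noRd
outcome_frame <- function(dataset, outcome, transform) {
  if (is.null(dataset$onset)) {
    stop("dataset not harmonized; run harmonize_onset() first", call. = FALSE)
  }
  if (outcome == "dprime") {
    df <- active_records(dataset, "sessions")
    out <- data.frame(
      participant_id = df$participant_id,
      y = transform_outcome(df$d_prime, transform),
      t = df$day_index - 1 + df$time_of_day / 24,
      day_index = df$day_index,
      time_of_day = df$time_of_day,
      assessment_index = df$assessment_index,
      weekday = weekday_of(as.Date(df$session_timestamp, tz = "UTC")),
      stringsAsFactors = FALSE
    )
  } else if (outcome == "mood") {
    df <- active_records(dataset, "moods")
    out <- data.frame(
      participant_id = df$participant_id,
      y = transform_outcome(df$total, transform),
      t = df$day_index - 1 + df$time_of_day / 24,
      day_index = df$day_index,
      time_of_day = df$time_of_day,
      weekday = weekday_of(as.Date(df$timestamp, tz = "UTC")),
      stringsAsFactors = FALSE
    )
  } else {
    df <- active_records(dataset, "dailies")
    y <- if (outcome == "steps") df$step_count else df$mean_heart_rate
    keep <- !is.na(y)
    df <- df[keep, , drop = FALSE]
    out <- data.frame(
      participant_id = df$participant_id,
      y = transform_outcome(y[keep], transform),
      t = as.numeric(df$day_index),
      day_index = df$day_index,
      weekday = weekday_of(as.Date(df$date)),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!is.na(out$y), , drop = FALSE]
  out[order(out$participant_id, out$t), , drop = FALSE]
}

re_formula <- function(spec, diagonal = FALSE) {
  if (spec$random_effects == "intercept") {
    ~ 1 | participant_id
  } else if (diagonal) {
    list(participant_id = nlme::pdDiag(~ 1 + t_s))
  } else {
    ~ 1 + t_s | participant_id
  }
}

cor_struct <- function(spec) {
  switch(spec$covariance,
         car1_continuous_time = nlme::corCAR1(form = ~ t | participant_id),
         ar1_daily = nlme::corAR1(form = ~ day_index | participant_id),
         none = NULL)
}

count_params <- function(spec, diagonal = FALSE, extra_fixed = 0L) {
  p_fixed <- spec$degree + 1L + extra_fixed
  p_re <- if (spec$random_effects == "intercept") 1L else if (diagonal) 2L else 3L
  p_cor <- if (spec$covariance == "none") 0L else 1L
  p_fixed + p_re + p_cor + 1L  # + residual variance
}

# exact linear map from the orthogonal-basis fixed effects to raw monomial
# coefficients (value, per-day, per-day^2, ...) via a Vandermonde solve
raw_coef_table <- function(beta, vc, degree, poly_obj, t_range, n_obs,
                           term_names) {
  if (degree == 0) {
    A <- matrix(1, 1, 1)
  } else {
    g <- seq(t_range[1], t_range[2], length.out = degree + 1)
    Xg <- cbind(1, predict(poly_obj, g))
    V <- outer(g, 0:degree, `^`)
    A <- solve(V, Xg)
  }
  est <- as.numeric(A %*% beta)
  cov_raw <- A %*% vc %*% t(A)
  se <- sqrt(pmax(diag(cov_raw), 0))
  tval <- est / se
  df <- max(n_obs - length(beta), 1)
  data.frame(term = term_names, estimate = est, std_error = se,
             t_value = tval, p_value = 2 * pt(-abs(tval), df),
             stringsAsFactors = FALSE)
}

#' Fit a hierarchical trend model
#'
#' Maximises the marginal likelihood of a linear mixed model with polynomial
#' fixed effects of time (orthogonalised internally for numerical
#' stability; coefficients are reported back-transformed to the raw
#' day scale), participant-level random intercept and slope, and
#' within-participant residual correlation per the supplied specification.
#' On a singular random-effects covariance the model is refitted with a
#' diagonal covariance and flagged; on outright optimizer failure the fit is
#' returned with `converged = FALSE` rather than a silent wrong answer.
#'
#' @param dataset a harmonized (and normally cleaned) `study_dataset`.
#' @param spec a [trend_spec()].
#' @return object of class `"trend_fit"`: raw-scale `coefficients` table,
#'   `random_effects` per participant, `varcomp` (residual SD, random-effect
#'   SDs, autocorrelation phi), `logLik`, `AIC`, `BIC`, `residuals`
#'   (conditional, per observation), `converged`, `singular`.
#' @export
fit_trend <- function(dataset, spec) {
  frame <- outcome_frame(dataset, spec$outcome, spec$transform)
  if (nrow(frame) < 3 || length(unique(frame$participant_id)) < 2) {
    stop("need at least 3 observations from at least 2 participants",
         call. = FALSE)
  }
  frame$t_s <- frame$t / max(max(frame$t), 1)
  poly_obj <- NULL
  if (spec$degree > 0) {
    poly_obj <- poly(frame$t, spec$degree)
    ot <- as.data.frame(unclass(poly_obj))
    names(ot) <- paste0("ot", seq_len(spec$degree))
    frame <- cbind(frame, ot)
    fixed <- as.formula(paste("y ~", paste(names(ot), collapse = " + ")))
  } else {
    fixed <- y ~ 1
  }
  fit_lme(frame, fixed, spec, poly_obj = poly_obj, extra_terms = NULL)
}

# shared lme driver for trend and periodicity fits; extra_terms is a
# character vector of additional (already-centred) fixed-effect columns
fit_lme <- function(frame, fixed, spec, poly_obj, extra_terms,
                    term_meta = NULL) {
  corst <- cor_struct(spec)
  singular <- FALSE
  # restart grid: for each random-effects structure (full covariance,
  # diagonal, intercept-only) try the BFGS profile optimizer, then nlminb
  # with a raised iteration budget; the first success wins and any
  # simplification of the random structure is flagged as singular
  try_fit <- function(random, control) {
    tryCatch(
      nlme::lme(fixed, random = random, data = frame, correlation = corst,
                method = "ML", control = control),
      error = function(e) e
    )
  }
  structures <- if (spec$random_effects == "intercept_slope") {
    list(full = re_formula(spec),
         diagonal = re_formula(spec, diagonal = TRUE),
         intercept = ~ 1 | participant_id)
  } else {
    list(intercept = ~ 1 | participant_id)
  }
  # optimizer order by correlation structure: the BFGS profile optimizer
  # converges much faster than nlminb under continuous-time AR(1), while
  # nlminb is the faster and more robust choice for the daily structures.
  # Iteration budgets stay moderate: a fit that has not converged by then
  # is almost always singular, and the structure fallback below handles
  # it faster than further grinding would
  controls <- if (spec$covariance == "car1_continuous_time") {
    list(nlme::lmeControl(opt = "optim", maxIter = 100, msMaxIter = 200),
         nlme::lmeControl(maxIter = 100, msMaxIter = 100))
  } else {
    list(nlme::lmeControl(maxIter = 60, msMaxIter = 60),
         nlme::lmeControl(opt = "optim", maxIter = 60, msMaxIter = 120))
  }
  model <- NULL
  for (si in seq_along(structures)) {
    for (ctrl in controls) {
      m <- try_fit(structures[[si]], ctrl)
      if (!inherits(m, "error")) {
        model <- m
        break
      }
      model <- m
    }
    if (!inherits(model, "error")) {
      if (names(structures)[si] != "full" &&
          spec$random_effects == "intercept_slope") {
        singular <- TRUE
        if (names(structures)[si] == "intercept") {
          spec$random_effects <- "intercept"
        }
      }
      break
    }
  }
  if (inherits(model, "error")) {
    return(structure(list(spec = spec, converged = FALSE, singular = singular,
                          message = conditionMessage(model), frame = frame),
                     class = "trend_fit"))
  }
  beta <- nlme::fixef(model)
  vc <- vcov(model)
  n_obs <- nrow(frame)
  deg <- spec$degree
  term_names <- c("(value at day 0)",
                  if (deg >= 1) paste0("day^", seq_len(deg)))
  n_poly <- deg + 1L
  tab <- raw_coef_table(beta[seq_len(n_poly)],
                        vc[seq_len(n_poly), seq_len(n_poly), drop = FALSE],
                        deg, poly_obj, range(frame$t), n_obs, term_names)
  if (length(beta) > n_poly) {
    # periodic (centred) terms: back-transform to the raw axis scale
    extra_tab <- periodic_coef_table(beta, vc, n_poly, term_meta, n_obs)
    tab <- rbind(tab, extra_tab)
  }
  phi <- NA_real_
  if (!is.null(model$modelStruct$corStruct)) {
    phi <- as.numeric(coef(model$modelStruct$corStruct,
                           unconstrained = FALSE))
  }
  re <- nlme::ranef(model)
  vc_re <- nlme::VarCorr(model)
  k <- count_params(spec,
                    diagonal = singular,
                    extra_fixed = length(beta) - n_poly)
  ll <- as.numeric(logLik(model))
  res <- frame[, intersect(c("participant_id", "day_index", "t",
                             "time_of_day", "assessment_index"),
                           names(frame)), drop = FALSE]
  res$fitted <- as.numeric(fitted(model, level = 1))
  res$residual <- as.numeric(resid(model, level = 1))
  structure(list(
    spec = spec, model = model, coefficients = tab,
    random_effects = re, varcomp = list(
      sigma = model$sigma, phi = phi, random_sd = suppressWarnings(
        as.numeric(vc_re[seq_len(nrow(vc_re) - 1), "StdDev"]))
    ),
    logLik = ll, n_params = k, n_obs = n_obs,
    AIC = 2 * k - 2 * ll, BIC = k * log(n_obs) - 2 * ll,
    residuals = res, converged = TRUE, singular = singular,
    frame = frame, fixed = fixed, poly_obj = poly_obj,
    term_meta = term_meta
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit: %s, degree %d, %s, %s>\n", x$spec$outcome,
              x$spec$degree, x$spec$covariance, x$spec$transform))
  if (!x$converged) {
    cat("  DID NOT CONVERGE:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f, phi = %.3f%s\n",
              x$n_obs, x$logLik, x$AIC, x$BIC, x$varcomp$phi,
              if (x$singular) " (diagonal RE covariance)" else ""))
  print(x$coefficients, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between two nested trend fits
#' @noRd
lrt <- function(small, big) {
  chisq <- 2 * (big$logLik - small$logLik)
  df <- big$n_params - small$n_params
  # df can collapse when a fit fell back to a simpler random structure;
  # such pairs are not nested and yield no test
  p <- if (df <= 0) NA_real_ else pchisq(max(chisq, 0), df,
                                         lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

#' Fit and select the polynomial change-over-time model of an outcome
#'
#' Attempts intercept-only, linear, quadratic, and cubic trends of time and
#' selects by forward sequential likelihood-ratio testing: starting from the
#' intercept-only model, a higher degree replaces the current selection only
#' when the likelihood-ratio test against it has p below `alpha`; the
#' highest such degree wins. Degrees that fail to converge are skipped with
#' a log entry. AIC and BIC are reported but do not drive the decision.
#'
#' @param dataset harmonized `study_dataset`.
#' @param outcome outcome name.
#' @param alpha selection level (default 0.05).
#' @param degrees degrees to attempt (default 0:3).
#' @param ... passed to [trend_spec()] (e.g. `transform`).
#' @return object of class `"trend_selection"`: `fits` (by degree),
#'   `selected` (a `trend_fit`), `table` (comparison: logLik, AIC, BIC,
#'   chi-square vs the selection path, df, p).
#' @export
select_trend <- function(dataset, outcome, alpha = 0.05, degrees = 0:3, ...) {
  fits <- list()
  for (d in degrees) {
    fits[[as.character(d)]] <- fit_trend(dataset,
                                         trend_spec(outcome, degree = d, ...))
  }
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  skipped <- names(fits)[!conv]
  sel <- NULL
  rows <- list()
  for (d in names(fits)) {
    f <- fits[[d]]
    row <- data.frame(degree = as.integer(d),
                      converged = f$converged,
                      n_params = if (f$converged) f$n_params else NA_integer_,
                      logLik = if (f$converged) f$logLik else NA_real_,
                      AIC = if (f$converged) f$AIC else NA_real_,
                      BIC = if (f$converged) f$BIC else NA_real_,
                      chisq = NA_real_, df = NA_integer_, p = NA_real_,
                      selected = FALSE)
    if (f$converged) {
      if (is.null(sel)) {
        sel <- f
      } else {
        tst <- lrt(sel, f)
        row$chisq <- tst$chisq
        row$df <- tst$df
        row$p <- tst$p
        if (!is.na(tst$p) && tst$p < alpha) sel <- f
      }
    }
    rows[[d]] <- row
  }
  if (is.null(sel)) stop("no trend model converged for ", outcome,
                         call. = FALSE)
  table <- do.call(rbind, rows)
  table$selected <- table$degree == sel$spec$degree
  rownames(table) <- NULL
  structure(list(outcome = outcome, fits = fits, selected = sel,
                 table = table, alpha = alpha, skipped = skipped),
            class = "trend_selection")
}

#' @export
print.trend_selection <- function(x, ...) {
  cat(sprintf("<trend_selection: %s, selected degree %d>\n", x$outcome,
              x$selected$spec$degree))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Per-participant starting points from a trend fit
#'
#' The starting point is the conditional (fixed + random) model value at
#' time zero: the fixed polynomial evaluated at day 0 plus the
#' participant's predicted random intercept.
#'
#' @param fit a converged `trend_fit`.
#' @return data frame: `participant_id`, `starting_point`.
#' @export
extract_intercepts <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("cannot extract intercepts from a non-converged fit", call. = FALSE)
  }
  re <- fit$random_effects
  data.frame(participant_id = rownames(re),
             starting_point = fit$coefficients$estimate[1] +
               re[["(Intercept)"]],
             stringsAsFactors = FALSE)
}

#' Residual diagnostics for a trend fit
#'
#' Shapiro-Wilk normality of the conditional residuals (subsampled to 5000
#' when larger) and residual-spread summaries against fitted values and
#' time. Purely descriptive: results never gate the pipeline.
#'
#' @param fit converged `trend_fit`.
#' @return list: `normality` (statistic, p, n), `spread`, `degenerate` flag.
#' @export
run_diagnostics <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("diagnostics require a converged fit", call. = FALSE)
  }
  r <- fit$residuals$residual
  if (sd(r) < 1e-12) {
    return(list(normality = NULL, spread = NULL, degenerate = TRUE))
  }
  rs <- if (length(r) > 5000) r[round(seq(1, length(r), length.out = 5000))] else r
  sw <- shapiro.test(rs)
  spread <- list(
    vs_fitted = cor(abs(r), fit$residuals$fitted),
    vs_time = cor(abs(r), fit$residuals$t),
    quartiles = quantile(r, c(0.25, 0.5, 0.75))
  )
  list(normality = list(statistic = unname(sw$statistic),
                        p = sw$p.value, n = length(rs)),
       spread = spread, degenerate = FALSE)
}
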