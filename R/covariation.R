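# Concurrent and time-lagged covariation of within-person daily residual
# fluctuations: residuals from each outcome's final (trend + retained
# periodic terms) model, d-prime averaged within day for a common daily
# time scale, modelled with random intercepts and daily AR(1) errors.

#' Build the daily residual series
#'
#' Computes conditional residuals from each outcome's final model
#' (fluctuations around each participant's own fitted trajectory), averages
#' the d-prime residuals within day, and joins all outcomes on
#' participant-day. Step and heart-rate residuals stay on their transformed
#' (sqrt / log) analysis scales.
#'
#' @param fits named list of converged `trend_fit` objects, with entries
#'   among `dprime`, `mood`, `steps`, `heart_rate` (at least the response
#'   and one predictor).
#' @param curves optional `learning_curves` table used to flag each
#'   learner's learning period (days strictly before `learning_day_90`).
#' @return data frame of class `"residual_series"`: `participant_id`,
#'   `day_index`, one residual column per outcome, `n_nback_today`,
#'   `in_learning_period`.
#' @export
build_residuals <- function(fits, curves = NULL) {
  if (length(fits) == 0 || is.null(names(fits))) {
    stop("fits must be a named list of trend fits", call. = FALSE)
  }
  daily <- NULL
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (is.null(f)) next
    if (!isTRUE(f$converged)) {
      stop("fit for ", nm, " did not converge", call. = FALSE)
    }
    r <- f$residuals
    if (nm == "dprime") {
      agg <- aggregate(residual ~ participant_id + day_index, data = r,
                       FUN = mean)
      cnt <- aggregate(residual ~ participant_id + day_index, data = r,
                       FUN = length)
      names(cnt)[3] <- "n_nback_today"
      agg <- merge(agg, cnt, by = c("participant_id", "day_index"))
    } else {
      agg <- aggregate(residual ~ participant_id + day_index, data = r,
                       FUN = mean)
    }
    names(agg)[names(agg) == "residual"] <- nm
    daily <- if (is.null(daily)) agg else {
      merge(daily, agg, by = c("participant_id", "day_index"), all = TRUE)
    }
  }
  if (!"n_nback_today" %in% names(daily)) daily$n_nback_today <- 0L
  daily$n_nback_today[is.na(daily$n_nback_today)] <- 0L
  daily$in_learning_period <- FALSE
  if (!is.null(curves)) {
    for (i in seq_len(nrow(curves))) {
      if (isTRUE(curves$fit_adequate[i]) &&
          !is.na(curves$learning_day_90[i])) {
        sel <- daily$participant_id == curves$participant_id[i] &
          daily$day_index < curves$learning_day_90[i]
        daily$in_learning_period[sel] <- TRUE
      }
    }
  }
  daily <- daily[order(daily$participant_id, daily$day_index), , drop = FALSE]
  rownames(daily) <- NULL
  class(daily) <- c("residual_series", class(daily))
  daily
}

fit_covariation_lme <- function(data, response, predictors, label,
                                flags = character(0)) {
  keep <- complete.cases(data[, c(response, predictors), drop = FALSE])
  d <- data[keep, , drop = FALSE]
  usable <- character(0)
  for (p in predictors) {
    if (sd(d[[p]]) < 1e-12) {
      warning("predictor ", p, " has degenerate variance; dropped",
              call. = FALSE)
    } else {
      usable <- c(usable, p)
    }
  }
  if (length(usable) == 0) stop("no usable predictors", call. = FALSE)
  fml <- as.formula(paste(response, "~", paste(usable, collapse = " + ")))
  d$participant_id <- factor(d$participant_id)
  # degenerate sanity case: the response is an exact linear function of
  # the predictors (e.g. regressed on itself); the mixed-model likelihood
  # is unbounded there, so report the exact least-squares solution
  ols <- stats::lm(fml, data = d)
  if (suppressWarnings(summary(ols)$sigma) < 1e-10) {
    cf <- coef(ols)
    tab <- data.frame(term = names(cf), estimate = unname(cf),
                      std_error = 0, df = NA_real_, t_value = Inf,
                      p_value = 0, stringsAsFactors = FALSE)
    tab$t_value[tab$estimate == 0] <- 0
    return(structure(list(label = label, response = response,
                          predictors = usable, table = tab, n_obs = nrow(d),
                          n_participants = nlevels(d$participant_id),
                          covariance = "degenerate_exact_fit",
                          flags = c(flags, "degenerate_exact_fit"),
                          model = ols),
                     class = "covariation_result"))
  }
  model <- nlme::lme(fml, random = ~ 1 | participant_id, data = d,
                     correlation = nlme::corAR1(form = ~ day_index |
                                                  participant_id),
                     method = "ML",
                     control = nlme::lmeControl(maxIter = 100,
                                                msMaxIter = 100))
  tt <- summary(model)$tTable
  tab <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                    std_error = tt[, "Std.Error"], df = tt[, "DF"],
                    t_value = tt[, "t-value"], p_value = tt[, "p-value"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(label = label, response = response, predictors = usable,
                 table = tab, n_obs = nrow(d),
                 n_participants = nlevels(d$participant_id),
                 covariance = "ar1_daily_random_intercept",
                 flags = flags, model = model),
            class = "covariation_result")
}

#' @export
print.covariation_result <- function(x, ...) {
  cat(sprintf("<covariation: %s; %s ~ %s; n = %d obs / %d participants%s>\n",
              x$label, x$response, paste(x$predictors, collapse = " + "),
              x$n_obs, x$n_participants,
              if (length(x$flags)) paste0("; ", paste(x$flags, collapse = ", "))
              else ""))
  print(x$table, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Concurrent covariation of daily fluctuations with mood
#'
#' Mixed model of daily mood residuals on same-day residuals of the other
#' outcomes, with participant random intercepts and a first-order
#' autoregressive covariance over the day sequence.
#'
#' @param residuals a `residual_series`.
#' @param response residual column modelled (default `"mood"`).
#' @param predictors residual columns used as fixed effects.
#' @param flags character notes recorded on the result (e.g. which
#'   exclusions were active).
#' @return a `covariation_result` with the full coefficient table.
#' @export
concurrent_covariation <- function(residuals, response = "mood",
                                   predictors = c("dprime", "steps",
                                                  "heart_rate"),
                                   flags = character(0)) {
  n_id <- tapply(residuals$day_index, residuals$participant_id, length)
  if (sum(n_id >= 5, na.rm = TRUE) < 2) {
    stop("need at least 2 participants with at least 5 days of residuals",
         call. = FALSE)
  }
  fit_covariation_lme(residuals, response, predictors,
                      label = "concurrent", flags = flags)
}

#' Time-lagged covariation with mood
#'
#' Models the mood residual on day t against a predictor residual on the
#' previous (`prev_day`) or following (`next_day`) calendar day. Pairs are
#' formed only from consecutive days on which both values exist; the
#' covariance structure matches the concurrent model.
#'
#' @param residuals a `residual_series`.
#' @param predictor residual column to lag.
#' @param direction `"prev_day"` or `"next_day"`.
#' @param response response residual column (default `"mood"`).
#' @param flags notes recorded on the result.
#' @return a `covariation_result`.
#' @export
lagged_covariation <- function(residuals, predictor,
                               direction = c("prev_day", "next_day"),
                               response = "mood", flags = character(0)) {
  direction <- match.arg(direction)
  shift <- if (direction == "prev_day") 1L else -1L
  lagname <- paste0(predictor, "_", direction)
  lhs <- residuals[, c("participant_id", "day_index", response)]
  rhs <- residuals[, c("participant_id", "day_index", predictor)]
  rhs$day_index <- rhs$day_index + shift
  names(rhs)[3] <- lagname
  paired <- merge(lhs, rhs, by = c("participant_id", "day_index"))
  paired <- paired[complete.cases(paired), , drop = FALSE]
  if (nrow(paired) < 10) {
    stop("fewer than 10 valid lagged pairs", call. = FALSE)
  }
  fit_covariation_lme(paired, response, lagname,
                      label = paste0("lag_", direction), flags = flags)
}

#' Drop each learner's learning period from the residual series
#'
#' Learners lose all days strictly before their `learning_day_90` (the
#' plateau day itself is kept as the first post-learning day); participants
#' without a significant learning effect keep all their data.
#'
#' @param residuals a `residual_series` built with `curves` supplied.
#' @param curves `learning_curves` table (used when the flag column is
#'   absent).
#' @return the filtered `residual_series`.
#' @export
exclude_learning_period <- function(residuals, curves = NULL) {
  if (!"in_learning_period" %in% names(residuals) && is.null(curves)) {
    stop("residuals lack learning-period flags and no curves supplied",
         call. = FALSE)
  }
  if (!is.null(curves)) {
    residuals$in_learning_period <- FALSE
    for (i in seq_len(nrow(curves))) {
      if (isTRUE(curves$fit_adequate[i]) &&
          !is.na(curves$learning_day_90[i])) {
        sel <- residuals$participant_id == curves$participant_id[i] &
          residuals$day_index < curves$learning_day_90[i]
        residuals$in_learning_period[sel] <- TRUE
      }
    }
  }
  residuals[!residuals$in_learning_period, , drop = FALSE]
}

#' Restrict to days with the full quota of n-back assessments
#'
#' Sensitivity restriction against regression to the mean: keeps only
#' participant-days on which exactly `n_required` n-back sessions were
#' completed.
#'
#' @param residuals a `residual_series`.
#' @param n_required sessions per complete day (default 3).
#' @return the filtered `residual_series`.
#' @export
restrict_complete_days <- function(residuals, n_required = 3) {
  residuals[residuals$n_nback_today == n_required, , drop = FALSE]
}

#' Full covariation analysis sequence
#'
#' Reproducible pipeline: (1) concurrent model of mood on all predictor
#' residuals over the full period; (2) lagged models (previous and
#' following day) for predictors significant in the concurrent model;
#' (3) the same concurrent and lagged analyses after excluding each
#' learner's learning period; (4) when d-prime is significant in the
#' learning-excluded concurrent model, a rerun restricted to days with the
#' full assessment quota. Every fitted model's coefficient table is
#' archived.
#'
#' @param residuals a `residual_series` (with learning-period flags).
#' @param curves `learning_curves` table.
#' @param alpha significance level used to take predictors forward
#'   (default 0.05).
#' @param n_required sessions per complete day (default 3).
#' @param predictors candidate predictor columns.
#' @return list of `covariation_result`s: `concurrent`, `lagged`
#'   (named by predictor and direction), `concurrent_post_learning`,
#'   `lagged_post_learning`, `complete_days` (or NULL), plus
#'   `significant_predictors` per stage.
#' @export
covariation_pipeline <- function(residuals, curves, alpha = 0.05,
                                 n_required = 3,
                                 predictors = c("dprime", "steps",
                                                "heart_rate")) {
  predictors <- intersect(predictors, names(residuals))
  out <- list()
  conc <- concurrent_covariation(residuals, predictors = predictors)
  out$concurrent <- conc
  sig <- sig_predictors(conc, alpha)
  out$significant_predictors <- sig
  out$lagged <- list()
  for (p in sig) {
    for (dir in c("prev_day", "next_day")) {
      nm <- paste(p, dir, sep = "_")
      out$lagged[[nm]] <- tryCatch(
        lagged_covariation(residuals, p, dir),
        error = function(e) NULL)
    }
  }
  post <- exclude_learning_period(residuals, curves)
  conc2 <- concurrent_covariation(post, predictors = predictors,
                                  flags = "learning_period_excluded")
  out$concurrent_post_learning <- conc2
  sig2 <- sig_predictors(conc2, alpha)
  out$significant_predictors_post_learning <- sig2
  out$lagged_post_learning <- list()
  for (p in sig2) {
    for (dir in c("prev_day", "next_day")) {
      nm <- paste(p, dir, sep = "_")
      out$lagged_post_learning[[nm]] <- tryCatch(
        lagged_covariation(post, p, dir,
                           flags = "learning_period_excluded"),
        error = function(e) NULL)
    }
  }
  out$complete_days <- NULL
  if ("dprime" %in% sig2) {
    cd <- restrict_complete_days(post, n_required)
    out$complete_days <- tryCatch(
      concurrent_covariation(cd, predictors = predictors,
                             flags = c("learning_period_excluded",
                                       "complete_days_only")),
      error = function(e) NULL)
  }
  out
}

sig_predictors <- function(result, alpha) {
  tab <- result$table
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$term[tab$p_value < alpha]
}
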