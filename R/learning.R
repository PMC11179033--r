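# Individual n-back practice trajectories: baseline adjustment against the
# trend-model starting point, a 3-assessment trailing moving average, an
# inverse-curve fit Y = a - b/X per participant, the 90% learning rate
# 10*b/a, and the stable maximum a + starting point.

#' Baseline-adjust a participant's d-prime series
#'
#' @param scores session scores of one participant (active records), with
#'   `d_prime`, `assessment_index`, `day_index`.
#' @param starting_point the participant's starting point (see
#'   [extract_intercepts()]).
#' @return data frame: `X` (assessment index, 1-based), `Y`
#'   (baseline-adjusted d-prime), `day_index`.
#' @export
baseline_adjust <- function(scores, starting_point) {
  ord <- order(scores$assessment_index)
  data.frame(X = scores$assessment_index[ord],
             Y = scores$d_prime[ord] - starting_point,
             day_index = scores$day_index[ord])
}

#' Trailing moving average with partial start windows
#'
#' Averages each point with the `window - 1` preceding points of the same
#' series; the first `window - 1` points average all available preceding
#' points, preserving series length and using no future data.
#'
#' @param values numeric series in assessment order.
#' @param window window length (default 3, the typical number of
#'   assessments per day).
#' @return smoothed series, same length.
#' @examples
#' smooth_series(c(1, 2, 3, 4))  # 1, 1.5, 2, 3
#' @export
smooth_series <- function(values, window = 3) {
  if (length(values) == 0) stop("empty series", call. = FALSE)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  cs <- cumsum(values)
  n <- length(values)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window + 1L)
    out[i] <- (cs[i] - if (lo > 1) cs[lo - 1] else 0) / (i - lo + 1)
  }
  out
}

#' Fit an inverse learning curve to a baseline-adjusted series
#'
#' Nonlinear least squares for \eqn{Y = a - b/X} (bounded
#' Levenberg-Marquardt, \eqn{b \ge 0}), with standard errors from the
#' Jacobian, t statistics on n-2 degrees of freedom, and the adequacy rule
#' that both parameters must be significant at `p_threshold`. The series is
#' fitted exactly as supplied: apply [smooth_series()] beforehand to follow
#' the standard smooth-then-fit procedure (as [fit_learning_curves()]
#' does), or pass the raw adjusted series for a sensitivity fit. A
#' noiseless inverse-curve input is recovered exactly.
#'
#' @param adjusted data frame from [baseline_adjust()] (columns `X`, `Y`).
#' @param p_threshold two-sided adequacy level (default 0.05).
#' @param min_points minimum usable points (default 5).
#' @return list: `a`, `b`, `se_a`, `se_b`, `t_a`, `t_b`, `p_a`, `p_b`,
#'   `fit_adequate`, `n`, `reason` (when inadequate/failed).
#' @export
fit_inverse_curve <- function(adjusted, p_threshold = 0.05,
                              min_points = 5) {
  X <- adjusted$X
  Y <- adjusted$Y
  if (length(X) < min_points) {
    return(list(a = NA_real_, b = NA_real_, se_a = NA_real_, se_b = NA_real_,
                t_a = NA_real_, t_b = NA_real_, p_a = NA_real_, p_b = NA_real_,
                fit_adequate = FALSE, n = length(X),
                reason = "too few assessments"))
  }
  inverse_nls(X, Y, p_threshold)
}

inverse_nls <- function(X, Ys, p_threshold) {
  n <- length(X)
  a0 <- mean(tail(Ys, 5))
  b0 <- max(a0 - Ys[1], 0.1)
  dfr <- data.frame(X = X, Ys = Ys)
  fit <- tryCatch(
    minpack.lm::nlsLM(Ys ~ a - b / X, data = dfr,
                      start = list(a = a0, b = b0),
                      lower = c(a = -Inf, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(list(a = NA_real_, b = NA_real_, se_a = NA_real_, se_b = NA_real_,
                t_a = NA_real_, t_b = NA_real_, p_a = NA_real_,
                p_b = NA_real_, fit_adequate = FALSE, n = n,
                reason = paste("optimizer failure:", conditionMessage(fit))))
  }
  cf <- coef(fit)
  sm <- tryCatch(summary(fit), error = function(e) NULL)
  if (is.null(sm)) {
    se <- c(NA_real_, NA_real_)
  } else {
    se <- sm$coefficients[, "Std. Error"]
  }
  tt <- cf / se
  # a slope pinned at the zero bound has no learning signal: report p = 1
  if (cf["b"] <= 1e-10) tt["b"] <- 0
  pp <- 2 * pt(-abs(tt), df = max(n - 2, 1))
  adequate <- !anyNA(pp) && all(pp < p_threshold)
  list(a = unname(cf["a"]), b = unname(cf["b"]),
       se_a = unname(se[1]), se_b = unname(se[2]),
       t_a = unname(tt[1]), t_b = unname(tt[2]),
       p_a = unname(pp[1]), p_b = unname(pp[2]),
       fit_adequate = adequate, n = n,
       reason = if (adequate) NA_character_ else "parameter(s) not significant")
}

#' 90% learning rate of an adequate inverse curve
#'
#' The number of assessments needed to reach 90% of the asymptote beyond
#' the starting point: solving \eqn{a - b/X = 0.9a} gives \eqn{X = 10b/a}.
#'
#' @param a,b inverse-curve parameters (`a > 0`).
#' @return rate in assessments (real-valued).
#' @export
learning_rate_90 <- function(a, b) {
  if (is.na(a) || is.na(b) || a <= 0) {
    return(NA_real_)
  }
  10 * b / a
}

#' Study day on which a learning rate is reached
#'
#' The smallest study day whose cumulative count of completed assessments
#' reaches `ceiling(rate)`.
#'
#' @param rate learning rate in assessments.
#' @param scores the participant's active session scores (`day_index` in
#'   assessment order).
#' @return day index, or `NA` when the rate is never reached.
#' @export
map_rate_to_day <- function(rate, scores) {
  if (is.na(rate)) return(NA_integer_)
  need <- ceiling(rate)
  ord <- order(scores$assessment_index)
  di <- scores$day_index[ord]
  if (need < 1) return(di[1])
  if (need > length(di)) return(NA_integer_)
  as.integer(di[need])
}

#' Fit learning curves for a whole cohort
#'
#' Combines [baseline_adjust()], [smooth_series()], [fit_inverse_curve()],
#' [learning_rate_90()], and [map_rate_to_day()] per participant. The
#' stable maximum is the asymptote plus the starting point. Participants
#' with an inadequate fit (typically a nonsignificant slope: no clear
#' learning effect) keep `NA` rates and remain in the cohort for all
#' downstream analyses.
#'
#' @param dataset cleaned `study_dataset`.
#' @param starting_points data frame `participant_id`, `starting_point`
#'   (from [extract_intercepts()]).
#' @param window smoothing window (default 3).
#' @param p_threshold adequacy level (default 0.05).
#' @return data frame of class `"learning_curves"`, one row per
#'   participant: starting point, `asymptote_a`, `slope_b`, standard
#'   errors, t and p values, `fit_adequate`, `learning_rate_90`,
#'   `learning_day_90`, `stable_max`, `n_assessments`, and the
#'   unsmoothed-fit sensitivity estimates `a_unsmoothed`, `b_unsmoothed`.
#' @export
fit_learning_curves <- function(dataset, starting_points, window = 3,
                                p_threshold = 0.05) {
  s <- active_records(dataset, "sessions")
  out <- list()
  for (pid in starting_points$participant_id) {
    sp <- starting_points$starting_point[
      starting_points$participant_id == pid]
    sc <- s[s$participant_id == pid, , drop = FALSE]
    if (nrow(sc) == 0) next
    adj <- baseline_adjust(sc, sp)
    smoothed <- adj
    if (window > 1) smoothed$Y <- smooth_series(adj$Y, window)
    cv <- fit_inverse_curve(smoothed, p_threshold = p_threshold)
    raw_cv <- fit_inverse_curve(adj, p_threshold = p_threshold)
    rate <- if (cv$fit_adequate) learning_rate_90(cv$a, cv$b) else NA_real_
    day <- map_rate_to_day(rate, sc)
    out[[pid]] <- data.frame(
      participant_id = pid, starting_point = sp,
      asymptote_a = cv$a, slope_b = cv$b,
      se_a = cv$se_a, se_b = cv$se_b, t_a = cv$t_a, t_b = cv$t_b,
      p_a = cv$p_a, p_b = cv$p_b, fit_adequate = cv$fit_adequate,
      learning_rate_90 = rate, learning_day_90 = day,
      stable_max = cv$a + sp, n_assessments = cv$n,
      a_unsmoothed = raw_cv$a, b_unsmoothed = raw_cv$b,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("learning_curves", class(res))
  res
}

#' Correlate learning parameters with participant summaries
#'
#' Exploratory correlations of asymptotes and slopes (adequate fits only)
#' with per-participant summary measures (e.g. mean mood, mean daily
#' steps). Each variable pair is tested for normality (Shapiro-Wilk);
#' Pearson correlation with a Fisher-transform CI is used when both pass,
#' otherwise Spearman's rho with a bootstrap CI over participants.
#'
#' @param curves a `learning_curves` table.
#' @param summaries data frame: `participant_id` plus one column per
#'   summary measure.
#' @param alpha normality level (default 0.05).
#' @param n_boot bootstrap replicates for Spearman CIs (default 2000).
#' @return data frame: parameter, measure, method, estimate, conf_low,
#'   conf_high, p_value, n.
#' @export
correlate_learning_params <- function(curves, summaries, alpha = 0.05,
                                      n_boot = 2000) {
  ok <- curves[curves$fit_adequate, , drop = FALSE]
  merged <- merge(ok, summaries, by = "participant_id")
  if (nrow(merged) < 5) {
    stop("need at least 5 participants with adequate fits", call. = FALSE)
  }
  measures <- setdiff(names(summaries), "participant_id")
  rows <- list()
  for (par in c("asymptote_a", "slope_b")) {
    for (ms in measures) {
      x <- merged[[par]]
      y <- merged[[ms]]
      normal <- shapiro.test(x)$p.value >= alpha &&
        shapiro.test(y)$p.value >= alpha
      if (normal) {
        ct <- cor.test(x, y, method = "pearson")
        est <- unname(ct$estimate)
        ci <- as.numeric(ct$conf.int)
        meth <- "pearson"
        pv <- ct$p.value
      } else {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
        est <- unname(ct$estimate)
        pv <- ct$p.value
        bs <- vapply(seq_len(n_boot), function(i) {
          ix <- sample.int(length(x), replace = TRUE)
          suppressWarnings(cor(x[ix], y[ix], method = "spearman"))
        }, numeric(1))
        ci <- quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
        meth <- "spearman"
      }
      rows[[paste(par, ms)]] <- data.frame(
        parameter = par, measure = ms, method = meth, estimate = est,
        conf_low = ci[1], conf_high = ci[2], p_value = pv, n = length(x),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
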