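# Diurnal and day-of-week fixed effects appended to the selected trend
# models. Weekday enters as a numeric 1-7 code (Monday = 1) with linear and
# quadratic terms; time of day is continuous clock hours. Terms are centred
# before squaring to limit collinearity and back-transformed to the raw
# axis scale for reporting.

#' Weekday code of a date (Monday = 1 ... Sunday = 7)
#'
#' @param date a `Date` (or coercible) vector.
#' @return integer vector in 1..7.
#' @examples
#' weekday_of(as.Date("2023-05-01"))  # a Monday -> 1
#' @export
weekday_of <- function(date) {
  as.integer(format(as.Date(date), "%u"))
}

periodic_coef_table <- function(beta, vc, n_poly, term_meta, n_obs) {
  rows <- list()
  idx <- n_poly
  df <- max(n_obs - length(beta), 1)
  for (m in term_meta) {
    ix <- idx + seq_len(m$degree)
    idx <- idx + m$degree
    b <- beta[ix]
    V <- vc[ix, ix, drop = FALSE]
    if (m$degree == 2) {
      # b1*(x-c) + b2*(x-c)^2  ->  (b1 - 2c b2) x + b2 x^2 (+ const)
      A <- matrix(c(1, -2 * m$center, 0, 1), 2, 2, byrow = TRUE)
      est <- as.numeric(A %*% b)
      cov_raw <- A %*% V %*% t(A)
      nm <- paste0(m$axis, c("", "^2"))
    } else {
      est <- as.numeric(b)
      cov_raw <- V
      nm <- m$axis
    }
    se <- sqrt(pmax(diag(cov_raw), 0))
    tval <- est / se
    rows[[length(rows) + 1L]] <- data.frame(
      term = nm, estimate = est, std_error = se, t_value = tval,
      p_value = 2 * pt(-abs(tval), df), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Append diurnal or weekday fixed effects to a trend fit
#'
#' Adds centred linear (and, for `degree = 2`, quadratic) fixed effects of
#' the requested axis to a fitted trend model, refits by maximum
#' likelihood with the same random-effect and correlation structure, and
#' compares the augmented model to the base with a likelihood-ratio test.
#' The terms are retained (for downstream residualization) only when the
#' test improves fit at `alpha`.
#'
#' @param dataset harmonized `study_dataset` (the frame is rebuilt from it).
#' @param base_fit a converged `trend_fit` (typically the selected trend,
#'   possibly already augmented with earlier periodic terms).
#' @param axis `"time_of_day"` (continuous hours; only for streams with
#'   within-day sampling) or `"weekday"` (numeric 1-7 code).
#' @param degree 1 (linear) or 2 (linear + quadratic; default).
#' @param alpha retention level (default 0.05).
#' @return list: `fit` (augmented `trend_fit`), `test` (chisq, df, p),
#'   `retained` (logical), `base_fit`.
#' @export
add_periodic_terms <- function(dataset, base_fit,
                               axis = c("time_of_day", "weekday"),
                               degree = 2, alpha = 0.05) {
  axis <- match.arg(axis)
  if (!degree %in% 1:2) stop("degree must be 1 or 2", call. = FALSE)
  if (!isTRUE(base_fit$converged)) {
    stop("base fit did not converge", call. = FALSE)
  }
  frame <- base_fit$frame
  if (axis == "time_of_day" && !"time_of_day" %in% names(frame)) {
    stop("time_of_day terms are inapplicable to a stream with one observation per day",
         call. = FALSE)
  }
  x <- if (axis == "time_of_day") frame$time_of_day else frame$weekday
  ctr <- mean(x)
  meta <- c(base_fit$term_meta,
            list(list(axis = axis, degree = degree, center = ctr)))
  pref <- paste0(if (axis == "time_of_day") "tod" else "wd", "_c")
  frame[[pref]] <- x - ctr
  new_terms <- pref
  if (degree == 2) {
    frame[[paste0(pref, "2")]] <- (x - ctr)^2
    new_terms <- c(new_terms, paste0(pref, "2"))
  }
  old_rhs <- attr(terms(base_fit$fixed), "term.labels")
  fixed <- as.formula(paste("y ~",
                            paste(c(old_rhs, new_terms), collapse = " + ")))
  if (length(old_rhs) == 0) fixed <- as.formula(
    paste("y ~", paste(new_terms, collapse = " + ")))
  fit <- fit_lme(frame, fixed, base_fit$spec, poly_obj = base_fit$poly_obj,
                 extra_terms = NULL, term_meta = meta)
  if (!isTRUE(fit$converged)) {
    return(list(fit = fit, test = NULL, retained = FALSE,
                base_fit = base_fit))
  }
  tst <- lrt(base_fit, fit)
  list(fit = fit, test = tst, retained = tst$p < alpha, base_fit = base_fit)
}

#' Diurnal and weekday analysis of one outcome
#'
#' Follows the staged order used for high-frequency streams: for d-prime
#' and mood, time-of-day terms are tested first and weekday terms are then
#' added on top of whichever model survived; for the daily streams (steps,
#' heart rate) only weekday terms apply. Non-retained blocks are dropped
#' from the final residualization model.
#'
#' @param dataset harmonized `study_dataset`.
#' @param base the base model: a `trend_selection` or converged
#'   `trend_fit`.
#' @param degree polynomial degree of each periodic block (default 2).
#' @param alpha retention level (default 0.05).
#' @return list: `final_fit` (trend fit including retained blocks only),
#'   `tests` (per-axis LRT summaries), `retained` (named logical).
#' @export
periodic_analysis <- function(dataset, base, degree = 2, alpha = 0.05) {
  base_fit <- if (inherits(base, "trend_selection")) base$selected else base
  outcome <- base_fit$spec$outcome
  tests <- list()
  retained <- c()
  current <- base_fit
  if (outcome %in% c("dprime", "mood")) {
    res_tod <- add_periodic_terms(dataset, current, "time_of_day",
                                  degree = degree, alpha = alpha)
    tests$time_of_day <- res_tod$test
    retained["time_of_day"] <- res_tod$retained
    if (res_tod$retained) current <- res_tod$fit
  }
  res_wd <- add_periodic_terms(dataset, current, "weekday",
                               degree = degree, alpha = alpha)
  tests$weekday <- res_wd$test
  retained["weekday"] <- res_wd$retained
  if (res_wd$retained) current <- res_wd$fit
  list(final_fit = current, tests = tests, retained = retained)
}
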