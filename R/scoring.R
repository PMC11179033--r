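#' Bounded d-prime from hit and false-alarm counts
#'
#' Signal-detection sensitivity with the log-linear extreme-rate correction:
#' 0.5 is added to each count and 1 to each denominator before taking
#' standard-normal quantiles, and the result is clamped to the task's
#' documented range of \eqn{\pm 3.33}. The correction keeps perfect and
#' all-wrong sessions finite; the clamp reproduces the printed bounds for
#' any session geometry.
#'
#' @param hits,false_alarms non-negative counts (vectorised).
#' @param n_targets,n_nontargets trial counts per session.
#' @param bound clamp magnitude (default 3.33).
#' @return numeric vector of d-prime scores in `[-bound, bound]`.
#' @examples
#' dprime_from_counts(9, 0, 9, 21)   # perfect session -> 3.33
#' dprime_from_counts(7, 2, 9, 21)
#' @export
dprime_from_counts <- function(hits, false_alarms, n_targets, n_nontargets,
                               bound = DPRIME_BOUND) {
  if (any(hits < 0) || any(false_alarms < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(hits > n_targets) || any(false_alarms > n_nontargets)) {
    stop("counts cannot exceed their trial totals", call. = FALSE)
  }
  h <- (hits + 0.5) / (n_targets + 1)
  f <- (false_alarms + 0.5) / (n_nontargets + 1)
  clamp(qnorm(h) - qnorm(f), -bound, bound)
}

validate_trials <- function(trials) {
  need <- c("trial_index", "is_target", "responded")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) {
    stop("empty trial list", call. = FALSE)
  }
  idx <- trials$trial_index
  if (anyDuplicated(idx)) {
    stop("duplicate trial indices within session", call. = FALSE)
  }
  if (!setequal(idx, seq_len(nrow(trials)))) {
    stop("trial indices must be contiguous from 1", call. = FALSE)
  }
  if (any(trials$is_target & idx < 3)) {
    stop("trials 1 and 2 of a 2-back session can never be targets",
         call. = FALSE)
  }
  invisible(trials)
}

#' Score one n-back session
#'
#' Counts hits (responses on 2-back target trials) and false alarms
#' (responses on non-target trials) and converts them to a bounded d-prime
#' via [dprime_from_counts()].
#'
#' @param trials data frame for a single session with columns `trial_index`
#'   (contiguous from 1), `is_target`, `responded`, and optionally
#'   `participant_id` and `session_timestamp`.
#' @return one-row data frame: participant_id, session_timestamp, hits,
#'   false_alarms, n_targets, n_nontargets, d_prime.
#' @export
score_session <- function(trials) {
  validate_trials(trials)
  tgt <- trials$is_target
  data.frame(
    participant_id = if ("participant_id" %in% names(trials)) {
      trials$participant_id[1]
    } else {
      NA_character_
    },
    session_timestamp = if ("session_timestamp" %in% names(trials)) {
      trials$session_timestamp[1]
    } else {
      as.POSIXct(NA)
    },
    hits = sum(trials$responded[tgt]),
    false_alarms = sum(trials$responded[!tgt]),
    n_targets = sum(tgt),
    n_nontargets = sum(!tgt),
    d_prime = dprime_from_counts(sum(trials$responded[tgt]),
                                 sum(trials$responded[!tgt]),
                                 sum(tgt), sum(!tgt)),
    stringsAsFactors = FALSE
  )
}

#' Score many sessions at once
#'
#' Vectorised wrapper around the same scoring rule; sessions are identified
#' by `participant_id` + `session_timestamp`. Each session is validated as
#' in [score_session()].
#'
#' @param trials long trial table covering one or more sessions.
#' @return data frame of session scores, one row per session.
#' @export
score_sessions <- function(trials) {
  key <- interaction(trials$participant_id, format(trials$session_timestamp),
                     drop = TRUE)
  out <- lapply(split(trials, key), score_session)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$participant_id, res$session_timestamp), , drop = FALSE]
}

#' Populate study-time fields on session scores
#'
#' Computes `day_index` (study day, 1-based from each participant's onset
#' date), `time_of_day` (fractional clock hours), and `assessment_index`
#' (1-based rank of the participant's completed sessions in timestamp
#' order; ties broken by input order). Sessions timestamped before the
#' participant's onset are flagged `excluded` with reason `"pre_onset"`
#' rather than dropped.
#'
#' @param scores session-score data frame with `participant_id` and
#'   `session_timestamp`.
#' @param onset data frame with columns `participant_id`, `onset_date`.
#' @return `scores` with `day_index`, `time_of_day`, `assessment_index`,
#'   `excluded`, `exclude_reason` columns populated.
#' @export
assign_time_fields <- function(scores, onset) {
  if (!all(c("participant_id", "onset_date") %in% names(onset))) {
    stop("onset table needs participant_id and onset_date", call. = FALSE)
  }
  m <- match(scores$participant_id, onset$participant_id)
  if (anyNA(m)) {
    stop("onset date missing for participant(s): ",
         paste(unique(scores$participant_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  od <- as.Date(onset$onset_date)[m]
  ts <- scores$session_timestamp
  dt <- as.Date(ts, tz = "UTC")
  scores$day_index <- as.integer(dt - od) + 1L
  lt <- as.POSIXlt(ts, tz = "UTC")
  scores$time_of_day <- lt$hour + lt$min / 60 + lt$sec / 3600
  if (!"excluded" %in% names(scores)) scores$excluded <- FALSE
  if (!"exclude_reason" %in% names(scores)) {
    scores$exclude_reason <- NA_character_
  }
  pre <- scores$day_index < 1L
  scores$excluded <- scores$excluded | pre
  scores$exclude_reason[pre] <- "pre_onset"
  scores$assessment_index <- NA_integer_
  for (pid in unique(scores$participant_id)) {
    sel <- which(scores$participant_id == pid & !scores$excluded)
    ord <- sel[order(scores$session_timestamp[sel], sel)]
    scores$assessment_index[ord] <- seq_along(ord)
  }
  scores
}
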