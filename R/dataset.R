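#' Construct a study dataset
#'
#' Bundles the four long-format streams of a high-frequency wearable study:
#' n-back session scores, mood questionnaire responses, daily activity and
#' heart-rate summaries, and (optionally) trial-level n-back events. All
#' cleaning operations flag records via `excluded`/`exclude_reason` rather
#' than deleting them, so record counts are conserved and every drop is
#' auditable.
#'
#' @param sessions data frame of session scores (see [score_session()]).
#' @param moods data frame of mood responses: `participant_id`, `timestamp`,
#'   `item_interest`, `item_down`, `item_concentration`, `total`.
#' @param dailies data frame of daily summaries: `participant_id`, `date`,
#'   `step_count`, `mean_heart_rate`.
#' @param trials optional trial-level data frame.
#' @param onset optional data frame `participant_id`, `onset_date` (set by
#'   [harmonize_onset()]).
#' @return list with class `"study_dataset"`.
#' @export
study_dataset <- function(sessions, moods, dailies, trials = NULL,
                          onset = NULL) {
  add_flags <- function(df) {
    if (!"excluded" %in% names(df)) df$excluded <- logical(nrow(df))
    if (!"exclude_reason" %in% names(df)) {
      df$exclude_reason <- rep(NA_character_, nrow(df))
    }
    df
  }
  for (df in list(sessions, moods, dailies)) {
    if (!"participant_id" %in% names(df)) {
      stop("every stream needs a participant_id column", call. = FALSE)
    }
  }
  sessions <- add_flags(sessions)
  moods <- add_flags(moods)
  dailies <- add_flags(dailies)
  structure(list(sessions = sessions, moods = moods, dailies = dailies,
                 trials = trials, onset = onset),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset>\n")
  n_id <- length(unique(c(x$sessions$participant_id,
                          x$moods$participant_id,
                          x$dailies$participant_id)))
  cat(sprintf("  participants: %d\n", n_id))
  cat(sprintf("  sessions: %d (%d excluded)\n", nrow(x$sessions),
              sum(x$sessions$excluded)))
  cat(sprintf("  mood responses: %d (%d excluded)\n", nrow(x$moods),
              sum(x$moods$excluded)))
  cat(sprintf("  daily summaries: %d (%d excluded)\n", nrow(x$dailies),
              sum(x$dailies$excluded)))
  if (!is.null(x$trials)) cat(sprintf("  trials: %d\n", nrow(x$trials)))
  if (!is.null(x$onset)) cat("  onset harmonized\n")
  invisible(x)
}

#' Active (non-excluded) records of one stream
#'
#' @param dataset a `study_dataset`.
#' @param stream one of `"sessions"`, `"moods"`, `"dailies"`.
#' @return the stream's data frame restricted to non-excluded rows.
#' @export
active_records <- function(dataset,
                           stream = c("sessions", "moods", "dailies")) {
  stream <- match.arg(stream)
  df <- dataset[[stream]]
  df[!df$excluded, , drop = FALSE]
}

TS_FMT <- "%Y-%m-%d %H:%M:%S"

fmt_ts <- function(x) format(x, TS_FMT, tz = "UTC")

parse_ts <- function(x, what) {
  out <- as.POSIXct(x, format = TS_FMT, tz = "UTC")
  if (anyNA(out) && !all(is.na(x))) {
    bad <- which(is.na(out) & !is.na(x))
    stop(sprintf("unparseable timestamp(s) in %s at row(s) %s", what,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Write a study dataset as long-format CSV files
#'
#' One file per stream (`sessions.csv`, `mood.csv`, `daily.csv`, and
#' `trials.csv` / `onset.csv` when present), ISO-8601 timestamps, UTF-8.
#' The round trip through [read_dataset()] is lossless.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- dataset$sessions
  s$session_timestamp <- fmt_ts(s$session_timestamp)
  write.csv(s, file.path(dir, "sessions.csv"), row.names = FALSE)
  m <- dataset$moods
  m$timestamp <- fmt_ts(m$timestamp)
  write.csv(m, file.path(dir, "mood.csv"), row.names = FALSE)
  d <- dataset$dailies
  d$date <- format(as.Date(d$date))
  write.csv(d, file.path(dir, "daily.csv"), row.names = FALSE)
  if (!is.null(dataset$trials)) {
    tr <- dataset$trials
    tr$session_timestamp <- fmt_ts(tr$session_timestamp)
    write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE)
  }
  if (!is.null(dataset$onset)) {
    o <- dataset$onset
    o$onset_date <- format(as.Date(o$onset_date))
    write.csv(o, file.path(dir, "onset.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a study dataset written by [write_dataset()]
#'
#' Validates schemas on the way in: required columns must exist, timestamps
#' must parse, mood items must lie in 1-4 with `total` equal to their sum,
#' d-prime must lie within the documented \eqn{\pm 3.33} bounds, and step
#' counts must be non-negative. Violations raise errors naming the
#' offending rows.
#'
#' @param dir directory containing the CSV files.
#' @return a `study_dataset`.
#' @export
read_dataset <- function(dir) {
  need_file <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", f, call. = FALSE)
    p
  }
  s <- read.csv(need_file("sessions.csv"), stringsAsFactors = FALSE)
  req <- c("participant_id", "session_timestamp", "d_prime")
  miss <- setdiff(req, names(s))
  if (length(miss)) {
    stop("sessions.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  s$session_timestamp <- parse_ts(s$session_timestamp, "sessions.csv")
  bad <- which(abs(s$d_prime) > DPRIME_BOUND + 1e-9)
  if (length(bad)) {
    stop(sprintf("d_prime outside [-%.2f, %.2f] in sessions.csv at row(s) %s",
                 DPRIME_BOUND, DPRIME_BOUND,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  m <- read.csv(need_file("mood.csv"), stringsAsFactors = FALSE)
  reqm <- c("participant_id", "timestamp", "item_interest", "item_down",
            "item_concentration", "total")
  miss <- setdiff(reqm, names(m))
  if (length(miss)) {
    stop("mood.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  m$timestamp <- parse_ts(m$timestamp, "mood.csv")
  items <- m[, c("item_interest", "item_down", "item_concentration")]
  bad <- which(apply(items, 1, function(r) any(r < 1 | r > 4 | r != round(r))))
  if (length(bad)) {
    stop("mood item outside the 1-4 scale in mood.csv at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(rowSums(items) != m$total)
  if (length(bad)) {
    stop("mood total does not equal the item sum in mood.csv at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  d <- read.csv(need_file("daily.csv"), stringsAsFactors = FALSE)
  reqd <- c("participant_id", "date", "step_count", "mean_heart_rate")
  miss <- setdiff(reqd, names(d))
  if (length(miss)) {
    stop("daily.csv lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("unparseable date in daily.csv", call. = FALSE)
  bad <- which(!is.na(d$step_count) & d$step_count < 0)
  if (length(bad)) {
    stop("negative step count in daily.csv at row(s) ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  tr <- NULL
  if (file.exists(file.path(dir, "trials.csv"))) {
    tr <- read.csv(file.path(dir, "trials.csv"), stringsAsFactors = FALSE)
    tr$session_timestamp <- parse_ts(tr$session_timestamp, "trials.csv")
    tr$is_target <- as.logical(tr$is_target)
    tr$responded <- as.logical(tr$responded)
  }
  on <- NULL
  if (file.exists(file.path(dir, "onset.csv"))) {
    on <- read.csv(file.path(dir, "onset.csv"), stringsAsFactors = FALSE)
    on$onset_date <- as.Date(on$onset_date)
  }
  for (nm in c("excluded")) {
    if ("excluded" %in% names(s)) s$excluded <- as.logical(s$excluded)
    if ("excluded" %in% names(m)) m$excluded <- as.logical(m$excluded)
    if ("excluded" %in% names(d)) d$excluded <- as.logical(d$excluded)
  }
  study_dataset(s, m, d, trials = tr, onset = on)
}

#' Aggregate the session stream to daily mean d-prime
#'
#' Replaces the session stream with one pseudo-session per participant-day
#' holding that day's mean d-prime, timestamped at noon. Useful for
#' day-scale summaries and for replicated simulation studies where the
#' session-level continuous-time fit is unnecessarily expensive; the
#' participant-level structure (random intercepts, day trends) is
#' preserved. Requires a harmonized dataset; assessment indices are
#' recomputed on the aggregated stream.
#'
#' @param dataset a harmonized `study_dataset`.
#' @return the dataset with aggregated sessions.
#' @export
aggregate_sessions_daily <- function(dataset) {
  s <- active_records(dataset, "sessions")
  agg <- aggregate(d_prime ~ participant_id + day_index, data = s,
                   FUN = mean)
  om <- match(agg$participant_id, dataset$onset$participant_id)
  dates <- dataset$onset$onset_date[om] + agg$day_index - 1L
  agg$session_timestamp <- as.POSIXct(paste(dates, "12:00:00"), tz = "UTC")
  agg$hits <- NA_integer_
  agg$false_alarms <- NA_integer_
  agg$n_targets <- NA_integer_
  agg$n_nontargets <- NA_integer_
  dataset$sessions <- assign_time_fields(
    agg[, c("participant_id", "session_timestamp", "hits", "false_alarms",
            "n_targets", "n_nontargets", "d_prime", "day_index")],
    dataset$onset)
  dataset
}

#' Write generator ground truth
#'
#' Per-participant latent parameters as CSV plus the global coupling and
#' trend coefficients as JSON.
#'
#' @param truth a `"cogema_truth"` object from [generate_cohort()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(truth$participants, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  jsonlite::write_json(truth[c("couplings", "trend")],
                       file.path(dir, "ground_truth_global.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
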