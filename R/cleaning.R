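# Data-harmonization and exclusion rules applied before any modelling:
# onset definition, non-wear day flagging, and sparse-hour exclusion.
# Every rule flags records (excluded + exclude_reason) instead of deleting
# them, so records_in = records_kept + records_flagged for each filter.

#' Harmonize study onset per participant
#'
#' Defines each participant's first study day as the first calendar day on
#' which they responded to any assessment prompt (cognitive session or mood
#' questionnaire). Passive-only records from earlier days are flagged
#' `pre_onset`; day indices are rebased so that the onset date is day 1, and
#' time-of-day / assessment-index fields are populated on all streams.
#' Participants with passive data only are excluded entirely (flagged
#' `no_active_data`) with a warning.
#'
#' @param dataset a raw `study_dataset`.
#' @return the dataset with `onset` set and `day_index`, `time_of_day`,
#'   `assessment_index` populated.
#' @export
harmonize_onset <- function(dataset) {
  s <- dataset$sessions
  m <- dataset$moods
  d <- dataset$dailies
  ids <- unique(c(s$participant_id, m$participant_id, d$participant_id))
  onset <- data.frame(participant_id = character(0),
                      onset_date = as.Date(character(0)))
  passive_only <- character(0)
  for (pid in ids) {
    cand <- c(
      as.Date(s$session_timestamp[s$participant_id == pid], tz = "UTC"),
      as.Date(m$timestamp[m$participant_id == pid], tz = "UTC")
    )
    if (length(cand) == 0) {
      passive_only <- c(passive_only, pid)
    } else {
      onset <- rbind(onset, data.frame(participant_id = pid,
                                       onset_date = min(cand)))
    }
  }
  if (length(passive_only)) {
    warning("participant(s) with passive data only excluded: ",
            paste(passive_only, collapse = ", "), call. = FALSE)
    sel <- d$participant_id %in% passive_only
    d$excluded[sel] <- TRUE
    d$exclude_reason[sel] <- "no_active_data"
  }
  s <- assign_time_fields(s, onset)
  # mood stream: same day/time rebasing
  mm <- match(m$participant_id, onset$participant_id)
  m$day_index <- as.integer(as.Date(m$timestamp, tz = "UTC") -
                              onset$onset_date[mm]) + 1L
  lt <- as.POSIXlt(m$timestamp, tz = "UTC")
  m$time_of_day <- lt$hour + lt$min / 60 + lt$sec / 3600
  # dailies: flag pre-onset passive days, rebase the rest
  dm <- match(d$participant_id, onset$participant_id)
  d$day_index <- as.integer(as.Date(d$date) - onset$onset_date[dm]) + 1L
  pre <- !is.na(d$day_index) & d$day_index < 1L
  d$excluded[pre] <- TRUE
  d$exclude_reason[pre] <- "pre_onset"
  dataset$sessions <- s
  dataset$moods <- m
  dataset$dailies <- d
  dataset$onset <- onset
  dataset
}

#' Flag non-wear days
#'
#' A day counts as non-wearing when fewer than `min_steps` steps were
#' recorded or no heart rate was recorded; exactly `min_steps` steps counts
#' as wearing (the rule is strictly "fewer than"). Flagged records are
#' retained with `wear = FALSE` so downstream modules can filter and drops
#' stay auditable.
#'
#' @param dailies daily-summary data frame (`step_count`,
#'   `mean_heart_rate`).
#' @param min_steps wear threshold in steps (default 100).
#' @return `dailies` with `wear` set and non-wear rows flagged excluded.
#' @export
flag_nonwear <- function(dailies, min_steps = 100) {
  if (any(!is.na(dailies$step_count) & dailies$step_count < 0)) {
    stop("negative step counts are invalid", call. = FALSE)
  }
  nw <- is.na(dailies$step_count) | dailies$step_count < min_steps |
    is.na(dailies$mean_heart_rate)
  dailies$wear <- !nw
  newly <- nw & !dailies$excluded
  dailies$excluded <- dailies$excluded | nw
  dailies$exclude_reason[newly] <- "non_wear"
  dailies
}

#' Exclude sparse clock-hour bins
#'
#' Pools response counts across participants and days into half-open
#' clock-hour bins `[h:00, h+1:00)` for the requested stream, and flags
#' every observation falling in a bin with fewer than `min_per_hour`
#' assessments overall. Returns the retained hour window alongside the
#' updated dataset.
#'
#' @param dataset a harmonized `study_dataset`.
#' @param stream `"dprime"` (session scores) or `"mood"`.
#' @param min_per_hour minimum pooled assessments per clock-hour bin
#'   (default 25).
#' @return list: `dataset` (records in sparse bins flagged
#'   `sparse_hour`), `dropped` (count newly flagged), `kept_hours`
#'   (integer clock hours retained).
#' @export
filter_sparse_hours <- function(dataset, stream = c("dprime", "mood"),
                                min_per_hour = 25) {
  stream <- match.arg(stream)
  df <- if (stream == "dprime") dataset$sessions else dataset$moods
  if (is.null(df$time_of_day)) {
    stop("time_of_day not populated; run harmonize_onset() first",
         call. = FALSE)
  }
  act <- !df$excluded
  if (!any(act)) stop("no active records in stream ", stream, call. = FALSE)
  hour <- floor(df$time_of_day)
  counts <- table(hour[act])
  kept_hours <- sort(as.integer(names(counts)[counts >= min_per_hour]))
  drop <- act & !(hour %in% kept_hours)
  df$excluded[drop] <- TRUE
  df$exclude_reason[drop] <- "sparse_hour"
  if (stream == "dprime") {
    # keep assessment indices aligned with the retained sessions
    dataset$sessions <- df
  } else {
    dataset$moods <- df
  }
  list(dataset = dataset, dropped = sum(drop), kept_hours = kept_hours)
}

#' Apply all cleaning rules and report drop counts
#'
#' Runs [harmonize_onset()], [flag_nonwear()] on the daily stream, and
#' [filter_sparse_hours()] on the d-prime and mood streams, and returns the
#' cleaned dataset together with a per-rule accounting of flagged records.
#'
#' @param dataset a raw `study_dataset`.
#' @param min_steps non-wear threshold (default 100 steps).
#' @param min_per_hour sparse-hour threshold (default 25 assessments).
#' @return list: `dataset`, `report` (named counts and retained hour
#'   windows).
#' @export
clean_dataset <- function(dataset, min_steps = 100, min_per_hour = 25) {
  n_in <- c(sessions = nrow(dataset$sessions), moods = nrow(dataset$moods),
            dailies = nrow(dataset$dailies))
  dataset <- harmonize_onset(dataset)
  pre_onset <- sum(dataset$dailies$exclude_reason %in% "pre_onset") +
    sum(dataset$sessions$exclude_reason %in% "pre_onset")
  dataset$dailies <- flag_nonwear(dataset$dailies, min_steps = min_steps)
  non_wear <- sum(dataset$dailies$exclude_reason %in% "non_wear")
  fs_d <- filter_sparse_hours(dataset, "dprime", min_per_hour)
  fs_m <- filter_sparse_hours(fs_d$dataset, "mood", min_per_hour)
  dataset <- fs_m$dataset
  # assessment indices recomputed over the surviving sessions
  dataset$sessions <- assign_time_fields(dataset$sessions, dataset$onset)
  report <- list(
    records_in = n_in,
    pre_onset_flagged = pre_onset,
    non_wear_flagged = non_wear,
    sparse_hour_dprime = fs_d$dropped,
    sparse_hour_mood = fs_m$dropped,
    kept_hours_dprime = fs_d$kept_hours,
    kept_hours_mood = fs_m$kept_hours,
    records_active = c(sessions = sum(!dataset$sessions$excluded),
                       moods = sum(!dataset$moods$excluded),
                       dailies = sum(!dataset$dailies$excluded))
  )
  list(dataset = dataset, report = report)
}
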