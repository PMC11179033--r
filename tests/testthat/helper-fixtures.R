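# Fixtures are built in code: small configs, hand-enumerable cleaning
# datasets, and an independent Gaussian-quantile d-prime oracle.

# independent scoring oracle: the same correction rule computed through
# pracma's inverse error function instead of qnorm
oracle_dprime <- function(hits, fa, n_targets, n_nontargets, bound = 3.33) {
  z <- function(p) sqrt(2) * pracma::erfinv(2 * p - 1)
  raw <- z((hits + 0.5) / (n_targets + 1)) - z((fa + 0.5) / (n_nontargets + 1))
  pmin(pmax(raw, -bound), bound)
}

# a small but analysable cohort
tiny_config <- function(...) {
  simulation_config(n_participants = 8L, n_days = 21L, ...)
}

make_trials <- function(responded_on_targets, responded_on_nontargets,
                        n = 30L, k = 9L) {
  pos <- seq(3L, by = 3L, length.out = k)  # legal target placement
  is_target <- seq_len(n) %in% pos
  responded <- logical(n)
  responded[is_target] <- rep_len(responded_on_targets, k)
  responded[!is_target] <- rep_len(responded_on_nontargets, n - k)
  data.frame(participant_id = "P01",
             session_timestamp = as.POSIXct("2023-05-01 09:00:00", tz = "UTC"),
             trial_index = seq_len(n), is_target = is_target,
             responded = responded)
}

# hand-built cleaning fixture:
#  - participant A: 2 passive-only days before the first response, then
#    sessions pooled so clock hours 6-23 hold >= 25 observations each and
#    hours 0-5 hold fewer, and mood pooled so hours 12-17 survive while
#    8-11 and 18-21 do not
#  - daily rows exercising the non-wear boundary cases
cleaning_fixture <- function(n_keep = 25L, n_drop = 10L) {
  start <- as.Date("2023-06-05")  # a Monday
  sess <- list()
  for (h in 0:23) {
    nd <- if (h >= 6) n_keep else n_drop
    sess[[as.character(h)]] <- data.frame(
      participant_id = "A",
      session_timestamp = as.POSIXct(paste(start + seq_len(nd) - 1,
                                           sprintf("%02d:30:00", h)),
                                     tz = "UTC"),
      hits = 5L, false_alarms = 2L, n_targets = 9L, n_nontargets = 21L,
      d_prime = 1.0)
  }
  sessions <- do.call(rbind, sess)
  mood <- list()
  for (h in 8:21) {
    nd <- if (h >= 12 && h <= 17) n_keep else n_drop
    mood[[as.character(h)]] <- data.frame(
      participant_id = "A",
      timestamp = as.POSIXct(paste(start + seq_len(nd) - 1,
                                   sprintf("%02d:15:00", h)), tz = "UTC"),
      item_interest = 2L, item_down = 2L, item_concentration = 2L,
      total = 6L)
  }
  moods <- do.call(rbind, mood)
  # dailies: two passive-only days before onset plus boundary rows
  dailies <- data.frame(
    participant_id = "A",
    date = c(start - 2, start - 1, start, start + 1, start + 2, start + 3),
    step_count = c(4000, 5000, 99, 100, 5000, 8000),
    mean_heart_rate = c(70, 71, 72, 73, NA, 75))
  list(dataset = study_dataset(sessions, moods, dailies),
       n_sessions = nrow(sessions), n_moods = nrow(moods),
       start = start,
       # hand enumeration
       expected = list(
         sparse_dprime_dropped = 6L * n_drop,
         sparse_mood_dropped = 8L * n_drop,
         kept_hours_dprime = 6:23,
         kept_hours_mood = 12:17,
         pre_onset_dailies = 2L,
         non_wear = 2L  # the 99-step day and the missing-HR day
       ))
}

# harmonized dataset built directly from a daily outcome table (steps/HR),
# for focused trend-model tests
make_daily_dataset <- function(daily, onset_date = as.Date("2023-06-05")) {
  ids <- as.character(unique(daily$participant_id))
  daily$participant_id <- as.character(daily$participant_id)
  daily$date <- onset_date + daily$day_index - 1L
  daily$excluded <- FALSE
  daily$exclude_reason <- NA_character_
  daily$wear <- TRUE
  # one anchor session per participant so onset is the first fixture day
  sessions <- data.frame(participant_id = ids,
                         session_timestamp = as.POSIXct(
                           paste(onset_date, "09:00:00"), tz = "UTC"),
                         hits = NA_integer_, false_alarms = NA_integer_,
                         n_targets = NA_integer_, n_nontargets = NA_integer_,
                         d_prime = 1.0)
  moods <- data.frame(participant_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      item_interest = integer(0), item_down = integer(0),
                      item_concentration = integer(0), total = integer(0))
  ds <- study_dataset(sessions, moods, daily)
  ds <- harmonize_onset(ds)
  ds$dailies$excluded <- FALSE   # keep all fixture days regardless of HR
  ds
}

# fabricated converged trend fits, for covariation unit tests
fake_fit <- function(residual_df) {
  structure(list(converged = TRUE, residuals = residual_df),
            class = "trend_fit")
}
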