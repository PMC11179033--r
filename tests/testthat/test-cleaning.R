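# Cleaning rules: onset harmonization, non-wear flagging, sparse-hour
# exclusion -- exact drop counts on a hand-enumerable fixture.

test_that("onset is the first responded day and earlier passive days are flagged", {
  fx <- cleaning_fixture()
  ds <- harmonize_onset(fx$dataset)
  expect_equal(ds$onset$onset_date, fx$start)
  pre <- ds$dailies$exclude_reason %in% "pre_onset"
  expect_equal(sum(pre), fx$expected$pre_onset_dailies)
  expect_equal(ds$dailies$day_index[ds$dailies$date == fx$start], 1L)
  # dataset whose first response falls on the first calendar day is
  # unchanged apart from indexing
  fx2 <- cleaning_fixture()
  fx2$dataset$dailies <- fx2$dataset$dailies[
    fx2$dataset$dailies$date >= fx2$start, ]
  ds2 <- harmonize_onset(fx2$dataset)
  expect_equal(sum(ds2$dailies$excluded), 0L)
  expect_equal(min(ds2$dailies$day_index), 1L)
})

test_that("participants with passive data only are excluded with a warning", {
  fx <- cleaning_fixture()
  extra <- data.frame(participant_id = "Z",
                      date = fx$start + 0:3, step_count = 5000,
                      mean_heart_rate = 70,
                      excluded = FALSE, exclude_reason = NA_character_)
  fx$dataset$dailies <- rbind(fx$dataset$dailies, extra)
  expect_warning(ds <- harmonize_onset(fx$dataset), "passive data only")
  z <- ds$dailies[ds$dailies$participant_id == "Z", ]
  expect_true(all(z$excluded))
  expect_true(all(z$exclude_reason == "no_active_data"))
})

test_that("non-wear boundaries follow the strict <100-steps / missing-HR rule", {
  d <- data.frame(participant_id = "A", date = as.Date("2023-06-05") + 0:2,
                  step_count = c(99, 100, 5000),
                  mean_heart_rate = c(70, 70, NA),
                  excluded = FALSE, exclude_reason = NA_character_)
  out <- flag_nonwear(d)
  expect_equal(out$wear, c(FALSE, TRUE, FALSE))
  expect_equal(out$exclude_reason, c("non_wear", NA, "non_wear"))
  d$step_count[1] <- -5
  expect_error(flag_nonwear(d), "negative")
})

test_that("sparse clock-hour bins are excluded at the n<25 boundary and windows match", {
  fx <- cleaning_fixture()
  ds <- harmonize_onset(fx$dataset)
  fs_d <- filter_sparse_hours(ds, "dprime", min_per_hour = 25)
  expect_equal(fs_d$kept_hours, fx$expected$kept_hours_dprime)
  expect_equal(fs_d$dropped, fx$expected$sparse_dprime_dropped)
  fs_m <- filter_sparse_hours(fs_d$dataset, "mood", min_per_hour = 25)
  expect_equal(fs_m$kept_hours, fx$expected$kept_hours_mood)
  expect_equal(fs_m$dropped, fx$expected$sparse_mood_dropped)
  # bin with 24 pooled observations dropped; 25 kept
  fx24 <- cleaning_fixture(n_keep = 24L)
  ds24 <- harmonize_onset(fx24$dataset)
  expect_equal(filter_sparse_hours(ds24, "dprime")$kept_hours, integer(0))
  # everything in one big-enough bin: nothing dropped
  one <- fx$dataset
  one$sessions <- one$sessions[
    format(one$sessions$session_timestamp, "%H") == "09", ]
  ds1 <- harmonize_onset(one)
  fs1 <- filter_sparse_hours(ds1, "dprime")
  expect_equal(fs1$dropped, 0L)
  expect_equal(fs1$kept_hours, 9L)
})

test_that("cleaning conserves records, is idempotent, and rules commute", {
  fx <- cleaning_fixture()
  cl <- clean_dataset(fx$dataset)
  rep <- cl$report
  # conservation: active + flagged = in, per stream
  expect_equal(sum(!cl$dataset$sessions$excluded) +
                 sum(cl$dataset$sessions$excluded),
               unname(rep$records_in["sessions"]))
  expect_equal(unname(rep$records_in["sessions"] -
                        rep$records_active["sessions"]),
               rep$sparse_hour_dprime)
  expect_equal(unname(rep$records_in["dailies"] -
                        rep$records_active["dailies"]),
               rep$pre_onset_flagged + rep$non_wear_flagged)
  # idempotence
  cl2 <- clean_dataset(cl$dataset)
  expect_equal(cl2$report$records_active, rep$records_active)
  expect_equal(cl2$report$kept_hours_dprime, rep$kept_hours_dprime)
  # commutation of non-wear flagging and sparse-hour filtering (disjoint
  # streams)
  ds <- harmonize_onset(fx$dataset)
  p1 <- ds
  p1$dailies <- flag_nonwear(p1$dailies)
  p1 <- filter_sparse_hours(p1, "dprime")$dataset
  p2 <- filter_sparse_hours(ds, "dprime")$dataset
  p2$dailies <- flag_nonwear(p2$dailies)
  expect_equal(p1$sessions, p2$sessions)
  expect_equal(p1$dailies, p2$dailies)
})
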