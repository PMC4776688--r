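test_that("long-gap flagging applies the strict 1.5x rule per signal", {
  hr <- flag_long_gaps(min_series(c(0, 20), c(70, 75)), 10)
  expect_equal(nrow(attr(hr, "gaps")), 1L)
  expect_equal(as.numeric(attr(hr, "gaps")$end - attr(hr, "gaps")$start,
                          units = "mins"), 20)

  even <- flag_long_gaps(min_series(seq(0, 120, 10), rep(70, 13)), 10)
  expect_equal(nrow(attr(even, "gaps")), 0L)

  act <- flag_long_gaps(min_series(c(0, 7, 14), c(.1, .2, .3), "activity"), 5)
  expect_equal(nrow(attr(act, "gaps")), 0L)  # 7 min < 7.5 min threshold

  exactly <- flag_long_gaps(min_series(c(0, 15), c(70, 75)), 10)
  expect_equal(nrow(attr(exactly, "gaps")), 0L)  # "exceeding" is strict

  unsorted <- min_series(c(0, 10), c(70, 75))
  unsorted$time <- rev(unsorted$time)
  expect_error(flag_long_gaps(unsorted, 10), "increasing")
})

test_that("HR floor filter removes strictly-below-20 values and counts artifacts", {
  s <- filter_hr_floor(min_series(c(0, 10, 20), c(72, 19, 80)))
  expect_equal(s$value, c(72, 80))
  expect_equal(attr(s, "artifact_count"), 1L)
  expect_equal(attr(s, "artifact_fraction"), 1 / 3)

  clean <- filter_hr_floor(min_series(c(0, 10), c(20, 72)))
  expect_equal(clean$value, c(20, 72))  # exactly 20 bpm is retained
  expect_equal(attr(clean, "artifact_count"), 0L)

  expect_error(filter_hr_floor(min_series(0, 0.5, "activity")), "HR")
})

test_that("zero-order hold matches the hand-traced example", {
  s <- flag_long_gaps(min_series(c(0, 12), c(70, 80)), 10)
  rs <- resample_zoh(s, 10)
  expect_equal(rs$values[1:3], c(70, 70, 80))
  expect_equal(rs$interval, 10)
})

test_that("resampling observations already on the grid is the identity", {
  v <- c(70, 72, 74, 71, 69)
  s <- flag_long_gaps(min_series(seq(0, 40, 10), v), 10)
  rs <- resample_zoh(s, 10)
  expect_equal(rs$values[1:5], v)
})

test_that("no values are held across a flagged gap", {
  # observation, then a 40-min gap: intervening slots must be missing
  s <- flag_long_gaps(min_series(c(0, 10, 50, 60), c(70, 71, 72, 73)), 10)
  rs <- resample_zoh(s, 10)
  expect_equal(rs$values[1:7], c(70, 71, NA, NA, NA, 72, 73))
})

test_that("linear down-sampling averages slot-aligned pairs and drops the remainder", {
  rs5 <- regular_series(c(2, 4, 6, 8, 10), 5, start = t_origin)
  rs10 <- downsample_linear(rs5, 10)
  expect_equal(rs10$values, c(3, 7))
  expect_equal(rs10$interval, 10)

  const <- downsample_linear(regular_series(rep(5, 6), 5, start = t_origin), 10)
  expect_equal(const$values, rep(5, 3))

  with_na <- downsample_linear(regular_series(c(2, NA, 6, 8), 5, start = t_origin), 10)
  expect_equal(with_na$values, c(NA, 7))

  expect_error(downsample_linear(regular_series(1:5, 7, start = t_origin), 10),
               "multiple")
})

test_that("best-day selection orders by missing fraction with earliest-day ties", {
  make_rs <- function(day_fracs) {
    per_day <- 144
    vals <- unlist(lapply(day_fracs, function(fr) {
      v <- rep(70, per_day)
      if (fr > 0) v[seq_len(round(fr * per_day))] <- NA
      v
    }))
    regular_series(vals, 10, start = t_origin)
  }
  sel <- select_best_days(make_rs(c(rep(0, 10), .2, .3, .4, .5)))
  expect_equal(sel$days, as.Date("2022-01-03") + 0:9)

  expect_error(select_best_days(make_rs(rep(0, 9))), "9 day")

  # two days tied at 0.05 competing for the last slot -> earlier kept
  sel2 <- select_best_days(make_rs(c(rep(0, 9), .05, .05, .2, .2, .2)))
  expect_true(as.Date("2022-01-12") %in% sel2$days)
  expect_false(as.Date("2022-01-13") %in% sel2$days)
  expect_equal(nrow(sel2$report), 14)
})

test_that("quality gate uses strict 10% comparisons", {
  expect_true(quality_gate(0.10, 0.10, 0.10)$accept)   # exactly 10% passes
  expect_false(quality_gate(0.101, 0, 0)$accept)
  expect_false(quality_gate(0, 0.2, 0)$accept)
  g <- quality_gate(0.15, 0, 0.12)
  expect_length(g$reasons, 2)
})

test_that("injected corruption is recovered by the preprocessing report", {
  rec <- small_subject(seed = 7, days = 12, artifact = 0.15)
  expect_equal(rec$meta$injected$artifact_fraction, 0.15, tolerance = 0.01)
  ps <- preprocess_subject(rec)
  expect_s3_class(ps, "rejected_subject")
  expect_match(ps$reason, "artifact")

  clean <- small_subject(seed = 8, days = 12)
  ps2 <- preprocess_subject(clean)
  expect_s3_class(ps2, "processed_subject")
  expect_equal(ps2$qc$artifact_fraction, 0)
  expect_length(ps2$days, 10)
  expect_equal(length(ps2$hr$values), 10 * 144)
  expect_equal(length(ps2$activity$values), 10 * 288)
  expect_equal(length(ps2$activity10$values), 10 * 144)
})

test_that("preprocessing a 9-day record rejects with a reason", {
  rec <- small_subject(seed = 9, days = 9)
  ps <- preprocess_subject(rec)
  expect_s3_class(ps, "rejected_subject")
  expect_match(ps$reason, "10 required")
})

test_that("injected HR dropouts always exceed the 15-min gap threshold", {
  rec <- small_subject(seed = 10, days = 12)
  acq <- acquisition_model(dropout_rate = 0.05, record_days = 12)
  cor <- inject_artifacts(rec, acq, seed = 1)
  expect_gt(cor$meta$injected$dropout_fraction_hr, 0.03)
  # every removed block leaves consecutive samples > 15 min apart
  d <- diff(as.numeric(cor$hr$time)) / 60
  n_long <- sum(d > 15)
  flagged <- attr(flag_long_gaps(sample_series(cor$hr$time, cor$hr$value, "hr"), 10), "gaps")
  expect_equal(nrow(flagged), n_long)
  expect_gt(n_long, 0)
})
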