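test_that("generation is byte-identical under the same seed", {
  a <- small_subject(seed = 3)
  b <- small_subject(seed = 3)
  expect_identical(a, b)
  c2 <- small_subject(seed = 4)
  expect_false(identical(a$hr$value, c2$hr$value))
})

test_that("uncorrupted recordings have no long gaps and no sub-20 HR values", {
  rec <- small_subject(seed = 21, days = 14)
  d_hr <- diff(as.numeric(rec$hr$time)) / 60
  d_act <- diff(as.numeric(rec$activity$time)) / 60
  expect_lte(max(d_hr), 15)        # 1.5 x 10 min
  expect_lte(max(d_act), 7.5)      # 1.5 x 5 min
  expect_gte(min(rec$hr$value), 20)
  expect_true(all(rec$activity$value >= 0 & rec$activity$value <= 1))
  span_days <- as.numeric(max(rec$hr$time) - min(rec$hr$time), units = "days")
  expect_gt(span_days, 13)
})

test_that("invalid profile fields fail naming the field", {
  expect_error(group_profile(hr_baseline = -1), "hr_baseline")
  expect_error(group_profile(hr_baseline = 70, act_day_level = 2), "act_day_level")
  expect_error(group_profile(hr_baseline = 70, mse_roughness = 1), "mse_roughness")
  expect_error(acquisition_model(dropout_rate = 1.2), "dropout_rate")
  expect_error(acquisition_model(record_days = 0), "record_days")
})

test_that("cohorts have the requested sizes, labels and derived seeds", {
  prof <- calibration_profiles()
  acq <- acquisition_model(record_days = 10)
  coh <- generate_cohort(12, 19, prof$case, prof$control, acq, seed = 7)
  expect_length(coh, 31)
  labels <- vapply(coh, `[[`, numeric(1), "label")
  expect_equal(sum(labels == 1), 12)
  expect_equal(sum(labels == 0), 19)
  expect_equal(unique(substr(vapply(coh[1:12], `[[`, character(1), "subject_id"), 1, 4)),
               "case")
  coh2 <- generate_cohort(12, 19, prof$case, prof$control, acq, seed = 7)
  expect_identical(coh, coh2)
  expect_error(generate_cohort(0, 5, prof$case, prof$control, acq, 1), "at least 1")
})

test_that("identical profiles make the two arms statistically exchangeable", {
  prof <- calibration_profiles()$control
  acq <- acquisition_model(record_days = 10)
  diffs <- vapply(1:60, function(s) {
    coh <- generate_cohort(1, 1, prof, prof, acq, seed = 1000 + s)
    mean(coh[[1]]$hr$value) - mean(coh[[2]]$hr$value)
  }, numeric(1))
  expect_gt(wilcox.test(diffs)$p.value, 0.01)
  # roughly half the seeds go either way
  expect_gt(mean(diffs > 0), 0.25)
  expect_lt(mean(diffs > 0), 0.75)
})

test_that("inject_artifacts is the identity at zero rates and bookkeeps otherwise", {
  rec <- small_subject(seed = 31)
  same <- inject_artifacts(rec, acquisition_model(record_days = 12), seed = 1)
  expect_identical(rec, same)

  acq <- acquisition_model(artifact_rate = 0.15, record_days = 12)
  cor <- inject_artifacts(rec, acq, seed = 2)
  expect_equal(cor$meta$injected$artifact_fraction, 0.15, tolerance = 0.005)
  expect_equal(mean(cor$hr$value < 20), 0.15, tolerance = 0.005)
})

test_that("group contrasts point the right way at the raw-series level", {
  prof <- calibration_profiles()
  acq <- acquisition_model(record_days = 10)
  res <- vapply(1:20, function(s) {
    coh <- generate_cohort(2, 2, prof$case, prof$control, acq, seed = 400 + s)
    hr_means <- vapply(coh, function(r) mean(r$hr$value), numeric(1))
    act_sds <- vapply(coh, function(r) sd(r$activity$value), numeric(1))
    c(hr = mean(hr_means[1:2]) - mean(hr_means[3:4]),
      act = mean(act_sds[1:2]) - mean(act_sds[3:4]))
  }, numeric(2))
  expect_gt(mean(res["hr", ]), 0)   # cases run higher HR
  expect_lt(mean(res["act", ]), 0)  # cases show less activity dispersion
})

test_that("cohort CSV round-trips through the long format", {
  prof <- calibration_profiles()
  acq <- acquisition_model(record_days = 10)
  coh <- generate_cohort(1, 1, prof$case, prof$control, acq, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$label, 1)
  expect_equal(back[[1]]$hr$value, coh[[1]]$hr$value, tolerance = 1e-8)
  expect_equal(as.numeric(back[[2]]$activity$time),
               as.numeric(coh[[2]]$activity$time), tolerance = 0.01)
  hdr <- names(read.csv(path, nrows = 1))
  expect_equal(hdr, c("subject_id", "group", "signal", "timestamp", "value"))
})
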