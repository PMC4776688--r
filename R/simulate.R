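## Synthetic cohort generator: paired HR / locomotor-activity recordings with
## circadian structure, activity-coupled heart rate, irregular sampling and
## injectable corruption.

.time_origin <- function() as.POSIXct("2022-01-03 00:00:00", tz = "UTC")

## irregular sample times (minutes from record start) over `days` days
irregular_times <- function(days, interval_mean, jitter_sd) {
  total <- days * 1440
  n_guess <- ceiling(total / interval_mean * 1.25) + 10L
  steps <- pmax(interval_mean / 4, rnorm(n_guess, interval_mean, jitter_sd))
  t <- cumsum(steps)
  t[t < total]
}

## rectified-sinusoid wake envelope; wake_start per day, 16-h wake window
wake_envelope <- function(t_min, wake_start) {
  day <- pmin(floor(t_min / 1440) + 1L, length(wake_start))
  hod <- (t_min / 60) %% 24
  ws <- wake_start[day]
  inside <- hod >= ws & hod <= ws + 16
  env <- ifelse(inside, sin(pi * (hod - ws) / 16), 0)
  list(env = env, wake = inside)
}

#' Generate one synthetic subject recording
#'
#' Produces irregularly timestamped HR and activity series spanning
#' `acq$record_days`. Activity follows a 24-h wake/sleep envelope (rectified
#' sinusoid with per-day phase jitter) with lognormal daytime movement
#' bursts and near-zero nocturnal values, clipped to \[0, 1\]. HR is
#' baseline + 24-h sinusoid + instantaneous activity coupling
#' (`hr_activity_gain` x concurrent activity) + AR(1) noise whose
#' autocorrelation is set by `mse_roughness`. Dropouts and sub-20-bpm HR
#' artifacts are then injected at the acquisition model's rates. The output
#' is byte-identical for identical arguments and seed.
#'
#' @param profile a [group_profile()].
#' @param acq an [acquisition_model()].
#' @param seed integer seed.
#' @param subject_id identifier string.
#' @param label 0 = control, 1 = case.
#' @return a `subject_record`: list with `subject_id`, `label`, `hr` and
#'   `activity` (data.frames `time`, `value`) and `meta` (subject-level
#'   draws and injected-corruption bookkeeping).
#' @export
generate_subject <- function(profile, acq, seed, subject_id = "s01", label = 0) {
  stopifnot(inherits(profile, "group_profile"), inherits(acq, "acquisition_model"))
  rec <- local_seed(seed, {
    days <- acq$record_days
    ## subject-level random effects; the dynamics parameters get modest
    ## fixed-CV jitter so the groups overlap instead of separating trivially
    baseline_i <- profile$hr_baseline + rnorm(1, 0, profile$hr_baseline_sd)
    day_level_i <- profile$act_day_level * exp(rnorm(1, 0, profile$act_level_sd))
    burst_rate_i <- profile$act_burst_rate * exp(rnorm(1, 0, profile$act_level_sd))
    burst_scale_i <- profile$act_burst_scale * exp(rnorm(1, 0, profile$act_level_sd))
    noise_sd_i <- profile$hr_noise_sd * exp(rnorm(1, 0, 0.15))
    amp_i <- profile$hr_circadian_amp * exp(rnorm(1, 0, 0.2))
    rho_i <- stats::plogis(stats::qlogis(min(max(profile$mse_roughness, 1e-3), 0.999)) +
                             rnorm(1, 0, 0.3))
    wake_start <- 7 + rnorm(days, 0, profile$sleep_onset_jitter_sd)

    ## locomotor activity (~5-min epochs)
    at <- irregular_times(days, acq$act_interval_mean, acq$interval_jitter_sd)
    na <- length(at)
    we <- wake_envelope(at, wake_start)
    dt_hr <- acq$act_interval_mean / 60
    burst <- rbinom(na, 1, min(1, burst_rate_i * dt_hr)) *
      rlnorm(na, log(pmax(burst_scale_i, 1e-6)), 0.6)
    act <- we$env * day_level_i * exp(rnorm(na, 0, 0.4)) +
      we$wake * burst + profile$act_night_level * rexp(na)
    act <- pmin(pmax(act, 0), 1)

    ## heart rate (~10-min epochs)
    ht <- irregular_times(days, acq$hr_interval_mean, acq$interval_jitter_sd)
    nh <- length(ht)
    circ <- amp_i * cos(2 * pi * ((ht / 60) %% 24 - 15) / 24)
    act_at_hr <- approx(at, act, xout = ht, rule = 2)$y
    innov_sd <- noise_sd_i * sqrt(1 - rho_i^2)
    noise <- as.numeric(stats::filter(rnorm(nh, 0, innov_sd), rho_i, method = "recursive"))
    hr <- pmax(baseline_i + circ + profile$hr_activity_gain * act_at_hr + noise, 25)

    origin <- .time_origin()
    list(subject_id = subject_id, label = label,
         hr = data.frame(time = origin + ht * 60, value = hr),
         activity = data.frame(time = origin + at * 60, value = act),
         meta = list(seed = seed, baseline = baseline_i, day_level = day_level_i,
                     injected = list(artifact_fraction = 0,
                                     dropout_fraction_hr = 0,
                                     dropout_fraction_act = 0)))
  })
  class(rec) <- "subject_record"
  if (acq$dropout_rate > 0 || acq$artifact_rate > 0) {
    rec <- inject_artifacts(rec, acq, seed = seed + 1L)
  }
  rec
}

#' Inject dropouts and HR artifacts into a recording
#'
#' Removes contiguous blocks of samples (both signals) until about
#' `dropout_rate` of each series is lost, and replaces about `artifact_rate`
#' of the HR samples with implausible values drawn below 20 bpm. The
#' injected fractions are recorded in `meta$injected` so downstream quality
#' reports can be checked against ground truth. With both rates zero the
#' record is returned unchanged.
#'
#' @param record a `subject_record`.
#' @param acq an [acquisition_model()] carrying the corruption rates.
#' @param seed integer seed.
#' @return the corrupted `subject_record`.
#' @export
inject_artifacts <- function(record, acq, seed) {
  if (acq$dropout_rate == 0 && acq$artifact_rate == 0) return(record)
  local_seed(seed, {
    drop_blocks <- function(df, rate, mean_block = 4) {
      n <- nrow(df)
      target <- round(rate * n)
      removed <- integer(0)
      while (length(removed) < target) {
        len <- 1L + stats::rgeom(1, 1 / mean_block)
        len <- min(len, target - length(removed))
        start <- sample.int(n - len + 1L, 1L)
        removed <- unique(c(removed, start:(start + len - 1L)))
      }
      list(df = df[-removed, , drop = FALSE], fraction = length(removed) / n)
    }
    inj <- record$meta$injected
    if (acq$artifact_rate > 0) {
      nh <- nrow(record$hr)
      k <- round(acq$artifact_rate * nh)
      idx <- sample.int(nh, k)
      record$hr$value[idx] <- runif(k, 5, 19.5)
      inj$artifact_fraction <- k / nh
    }
    if (acq$dropout_rate > 0) {
      dh <- drop_blocks(record$hr, acq$dropout_rate)
      record$hr <- dh$df
      inj$dropout_fraction_hr <- dh$fraction
      da <- drop_blocks(record$activity, acq$dropout_rate)
      record$activity <- da$df
      inj$dropout_fraction_act <- da$fraction
    }
    record$meta$injected <- inj
    record
  })
}

#' Generate a labelled synthetic cohort
#'
#' Per-subject seeds are derived deterministically from the master seed, so
#' any subject can be regenerated in isolation.
#'
#' @param n_cases,n_controls group sizes (each >= 1).
#' @param case_profile,control_profile [group_profile()]s.
#' @param acq an [acquisition_model()].
#' @param seed master integer seed.
#' @return list of `subject_record`s, cases first.
#' @export
generate_cohort <- function(n_cases, n_controls, case_profile, control_profile,
                            acq, seed) {
  if (n_cases < 1 || n_controls < 1) {
    stop("`n_cases` and `n_controls` must be at least 1", call. = FALSE)
  }
  n <- n_cases + n_controls
  seeds <- derive_seeds(seed, n)
  out <- vector("list", n)
  for (i in seq_len(n_cases)) {
    out[[i]] <- generate_subject(case_profile, acq, seeds[i],
                                 subject_id = sprintf("case%02d", i), label = 1)
  }
  for (j in seq_len(n_controls)) {
    out[[n_cases + j]] <- generate_subject(control_profile, acq, seeds[n_cases + j],
                                           subject_id = sprintf("ctrl%02d", j), label = 0)
  }
  out
}

## Long-format CSV interchange ------------------------------------------------

#' Write a cohort to long-format CSV
#'
#' One row per sample: `subject_id`, `group` (0/1), `signal` (`hr` /
#' `activity`), `timestamp` (ISO-8601 UTC), `value`.
#'
#' @param records list of `subject_record`s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  rows <- lapply(records, function(r) {
    rbind(
      data.frame(subject_id = r$subject_id, group = r$label, signal = "hr",
                 timestamp = format(r$hr$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                 value = r$hr$value),
      data.frame(subject_id = r$subject_id, group = r$label, signal = "activity",
                 timestamp = format(r$activity$time, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                 value = r$activity$value)
    )
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format cohort CSV
#'
#' Accepts the schema written by [write_cohort_csv()] (also the expected
#' schema for real recordings).
#'
#' @param path CSV file.
#' @return list of `subject_record`s.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "signal", "timestamp", "value")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  df$time <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  lapply(split(df, factor(df$subject_id, levels = unique(df$subject_id))), function(d) {
    d <- d[order(d$time), ]
    hr <- d[d$signal == "hr", ]
    act <- d[d$signal == "activity", ]
    structure(list(subject_id = d$subject_id[1], label = d$group[1],
                   hr = data.frame(time = hr$time, value = hr$value),
                   activity = data.frame(time = act$time, value = act$value),
                   meta = list()),
              class = "subject_record")
  })
}
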