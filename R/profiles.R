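#' Group-level generator profile
#'
#' Parameters of the synthetic recording generator for one group. Amplitudes
#' and rates must be nonnegative; activity levels are expressed in the
#' device's arbitrary units and the generated signal is clipped to \[0, 1\].
#'
#' @param hr_baseline group-mean resting HR level, bpm.
#' @param hr_baseline_sd between-subject SD of the baseline, bpm.
#' @param hr_circadian_amp amplitude of the 24-h HR sinusoid, bpm.
#' @param hr_activity_gain instantaneous HR response, bpm per activity unit.
#' @param hr_noise_sd stationary SD of the autocorrelated HR noise, bpm.
#' @param act_day_level typical daytime activity envelope level, units.
#' @param act_level_sd between-subject lognormal SD of the daytime level.
#' @param act_burst_rate daytime movement bursts per hour.
#' @param act_burst_scale median burst magnitude, units.
#' @param act_night_level nocturnal activity level, units.
#' @param mse_roughness AR(1) coefficient of the HR noise in \[0, 1);
#'   controls short-scale irregularity and hence the multiscale-entropy
#'   shape (higher = smoother, flatter entropy growth).
#' @param sleep_onset_jitter_sd per-day SD of the wake-onset time, hours.
#' @return a `group_profile` list.
#' @export
group_profile <- function(hr_baseline, hr_baseline_sd = 0, hr_circadian_amp = 5,
                          hr_activity_gain = 25, hr_noise_sd = 12,
                          act_day_level = 0.1, act_level_sd = 0,
                          act_burst_rate = 4, act_burst_scale = 0.2,
                          act_night_level = 0.01, mse_roughness = 0.5,
                          sleep_onset_jitter_sd = 0.5) {
  p <- list(hr_baseline = hr_baseline, hr_baseline_sd = hr_baseline_sd,
            hr_circadian_amp = hr_circadian_amp,
            hr_activity_gain = hr_activity_gain, hr_noise_sd = hr_noise_sd,
            act_day_level = act_day_level, act_level_sd = act_level_sd,
            act_burst_rate = act_burst_rate, act_burst_scale = act_burst_scale,
            act_night_level = act_night_level, mse_roughness = mse_roughness,
            sleep_onset_jitter_sd = sleep_onset_jitter_sd)
  nonneg <- c("hr_baseline", "hr_baseline_sd", "hr_circadian_amp",
              "hr_activity_gain", "hr_noise_sd", "act_day_level", "act_level_sd",
              "act_burst_rate", "act_burst_scale", "act_night_level",
              "sleep_onset_jitter_sd")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || is.na(p[[f]]) || p[[f]] < 0) {
      stop(sprintf("profile field `%s` must be a single nonnegative number", f),
           call. = FALSE)
    }
  }
  if (p$mse_roughness < 0 || p$mse_roughness >= 1) {
    stop("profile field `mse_roughness` must lie in [0, 1)", call. = FALSE)
  }
  if (p$act_day_level > 1 || p$act_night_level > 1) {
    stop("profile field `act_day_level` / `act_night_level` must lie in [0, 1]",
         call. = FALSE)
  }
  class(p) <- "group_profile"
  p
}

#' Acquisition model of the wearable device
#'
#' @param hr_interval_mean mean HR sampling interval, minutes (~10).
#' @param act_interval_mean mean activity sampling interval, minutes (~5).
#' @param interval_jitter_sd SD of the sampling intervals, minutes.
#' @param dropout_rate fraction of samples lost in contiguous gaps, in \[0, 1\].
#' @param artifact_rate fraction of HR samples replaced by implausible
#'   values (below 20 bpm), in \[0, 1\].
#' @param record_days recording length in days (>= 10 so best-10-day
#'   selection is exercised).
#' @return an `acquisition_model` list.
#' @export
acquisition_model <- function(hr_interval_mean = 10, act_interval_mean = 5,
                              interval_jitter_sd = 0.5, dropout_rate = 0,
                              artifact_rate = 0, record_days = 14) {
  for (f in c("dropout_rate", "artifact_rate")) {
    v <- get(f)
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must lie in [0, 1]", f), call. = FALSE)
    }
  }
  if (record_days < 1 || record_days != floor(record_days)) {
    stop("`record_days` must be a positive integer", call. = FALSE)
  }
  structure(list(hr_interval_mean = hr_interval_mean,
                 act_interval_mean = act_interval_mean,
                 interval_jitter_sd = interval_jitter_sd,
                 dropout_rate = dropout_rate, artifact_rate = artifact_rate,
                 record_days = record_days),
            class = "acquisition_model")
}

#' Packaged calibration profiles
#'
#' Versioned case-like / control-like generator profiles shipped with the
#' package (`inst/extdata/profiles.json`). They are calibrated so that the
#' synthetic groups reproduce the direction and rough magnitude of the
#' reference contrasts this package targets (elevated mean HR, reduced
#' activity dispersion and flatter HR entropy growth in the case group);
#' they are illustrative generator settings, not estimates of any real
#' population's parameters.
#'
#' @param path optional path to an alternative profile file.
#' @return list with `version`, `case` and `control` (`group_profile`s).
#' @export
calibration_profiles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "profiles.json", package = "cardioact")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(version = cfg$version,
       case = do.call(group_profile, as.list(cfg$case)),
       control = do.call(group_profile, as.list(cfg$control)))
}
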