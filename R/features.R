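## Assembly of the 36-feature vector (18 per signal).

.feature_base <- c("mean", "median", "mode", "std", "iqr",
                   "l5", "m10", "ra", "is", "iv",
                   "mse1", "mse2", "mse3", "mse4",
                   "te1", "te2", "te3", "te4")

#' Names of the 36 features
#'
#' 18 per signal: summary statistics (mean, median, mode, std, iqr),
#' rest-activity metrics (l5, m10, ra, is, iv), multiscale-entropy cubic
#' coefficients (mse1..mse4, constant term last) and transfer-entropy cubic
#' coefficients (te1..te4). The HR column's TE features are the
#' HR -> activity direction and the activity column's the activity -> HR
#' direction.
#'
#' @return character vector of length 36.
#' @export
feature_names <- function() {
  c(paste0("hr_", .feature_base), paste0("act_", .feature_base))
}

## linear + entropy features of one signal
signal_features <- function(series, mode_resolution, m = 1, r_fraction = 0.1) {
  st <- summary_stats(series$values, mode_resolution = mode_resolution)
  prof <- mean_daily_profile(series)
  lm10 <- l5_m10(prof, series$interval)
  ra <- as.numeric(relative_amplitude(lm10$L5, lm10$M10))
  isv <- as.numeric(interdaily_stability(series))
  ivv <- as.numeric(intradaily_variability(series))
  mse <- mse_profile(series$values, m = m, r_fraction = r_fraction)
  c(st, l5 = lm10$L5, m10 = lm10$M10, ra = ra, is = isv, iv = ivv,
    mse1 = unname(mse$coeffs[1]), mse2 = unname(mse$coeffs[2]),
    mse3 = unname(mse$coeffs[3]), mse4 = unname(mse$coeffs[4]))
}

#' Extract the 36-feature vector of one processed subject
#'
#' HR features come from the 10-min grid, activity features from the 5-min
#' grid, and the two transfer-entropy profiles from the synchronized 10-min
#' pair (HR with linearly down-sampled activity).
#'
#' @param subject a `processed_subject` from [preprocess_subject()].
#' @param m,r_fraction sample-entropy parameters.
#' @param te_args list of extra arguments for [te_profile()].
#' @return named numeric vector of length 36 (flagged-unavailable features
#'   are `NA`).
#' @export
extract_features <- function(subject, m = 1, r_fraction = 0.1, te_args = list()) {
  hr_f <- signal_features(subject$hr, mode_resolution = 1,
                          m = m, r_fraction = r_fraction)
  act_f <- signal_features(subject$activity, mode_resolution = 0.01,
                           m = m, r_fraction = r_fraction)
  te_ha <- do.call(te_profile, c(list(subject$hr, subject$activity10,
                                      direction = "hr_to_act"), te_args))
  te_ah <- do.call(te_profile, c(list(subject$hr, subject$activity10,
                                      direction = "act_to_hr"), te_args))
  out <- c(hr_f, unname(te_ha$coeffs), act_f, unname(te_ah$coeffs))
  names(out) <- feature_names()
  out
}

#' Build the cohort feature matrix
#'
#' @param subjects list of `processed_subject`s.
#' @param ... passed to [extract_features()].
#' @return data.frame with `subject_id`, `label` and the 36 feature columns.
#' @export
feature_matrix <- function(subjects, ...) {
  rows <- lapply(subjects, function(s) {
    f <- extract_features(s, ...)
    cbind(data.frame(subject_id = s$subject_id, label = s$label),
          as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
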