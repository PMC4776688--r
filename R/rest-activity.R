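## Summary statistics and non-parametric rest-activity metrics.

#' Summary statistics of a signal
#'
#' Mean, median, mode, standard deviation and interquartile range over the
#' non-missing values. The mode is taken after rounding to `mode_resolution`
#' (1 bpm for HR, 0.01 for activity); ties go to the smallest value.
#'
#' @param values numeric vector, possibly with `NA`.
#' @param mode_resolution rounding grid for the mode.
#' @return named numeric vector `mean`, `median`, `mode`, `std`, `iqr`.
#' @export
summary_stats <- function(values, mode_resolution = 1) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) {
    out <- rep(NA_real_, 5)
    names(out) <- c("mean", "median", "mode", "std", "iqr")
    attr(out, "flagged") <- "fewer than 2 non-missing values"
    return(out)
  }
  rounded <- round(v / mode_resolution) * mode_resolution
  tab <- table(rounded)
  md <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = smallest value
  c(mean = mean(v), median = median(v), mode = md, std = sd(v), iqr = IQR(v))
}

#' Mean daily (24-h) profile of a regular series
#'
#' Averages each slot-of-day position over all recorded days, skipping
#' missing slots; a position never observed is `NA` in the profile.
#'
#' @param series a `regular_series`.
#' @return numeric vector of length `1440 / interval`, starting at midnight.
#' @export
mean_daily_profile <- function(series) {
  per_day <- as.integer(round(1440 / series$interval))
  mins <- (as.numeric(series$times) / 60) %% 1440
  slot <- as.integer(round(mins / series$interval)) %% per_day + 1L
  prof <- rep(NA_real_, per_day)
  means <- tapply(series$values, slot, mean, na.rm = TRUE)
  prof[as.integer(names(means))] <- as.numeric(means)
  prof[is.nan(prof)] <- NA_real_
  prof
}

#' L5 and M10 of a mean daily profile
#'
#' L5 is the minimum, over all contiguous 5-h windows (wrapping across
#' midnight), of the sum of slot values in the window; M10 the maximum over
#' 10-h windows. Sums are over native-resolution slots, so a constant HR
#' profile of 65 bpm at 10-min slots gives L5 = 30 x 65. Ties are broken by
#' the earliest window start. Missing profile slots are circularly
#' interpolated first so window sums stay comparable across subjects.
#'
#' @param profile per-slot mean daily profile (from [mean_daily_profile()]).
#' @param interval slot interval in minutes.
#' @return list `L5`, `M10`, `l5_start`, `m10_start` (1-based slot indices).
#' @export
l5_m10 <- function(profile, interval) {
  p <- length(profile)
  w5 <- as.integer(round(5 * 60 / interval))
  w10 <- as.integer(round(10 * 60 / interval))
  if (p < w10) stop("profile shorter than the 10-h window", call. = FALSE)
  if (anyNA(profile)) profile <- fill_na_circular(profile)
  circ_sums <- function(w) {
    ext <- c(profile, profile[seq_len(w - 1L)])
    cs <- cumsum(c(0, ext))
    cs[(w + 1L):(p + w)] - cs[seq_len(p)]
  }
  s5 <- circ_sums(w5)
  s10 <- circ_sums(w10)
  list(L5 = min(s5), M10 = max(s10),
       l5_start = which.min(s5), m10_start = which.max(s10))
}

#' Relative amplitude
#'
#' RA = (M10 - L5) / (M10 + L5); strength of the daily rest-activity
#' contrast, in \[0, 1\] for nonnegative signals.
#'
#' @param L5,M10 window sums from [l5_m10()].
#' @return RA, or flagged `NA` when M10 + L5 = 0.
#' @export
relative_amplitude <- function(L5, M10) {
  if (M10 + L5 == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "M10 + L5 = 0"
    return(out)
  }
  (M10 - L5) / (M10 + L5)
}

## hourly means across the record (the x_i of IS/IV); NA hours interpolated
hourly_series <- function(series) {
  key <- format(series$times, "%Y-%m-%d %H", tz = "UTC")
  key <- factor(key, levels = unique(key))  # chronological
  hm <- tapply(series$values, key, mean, na.rm = TRUE)
  hm <- as.numeric(hm)
  hm[is.nan(hm)] <- NA_real_
  hour_of_day <- as.integer(substr(levels(key), 12, 13))
  if (anyNA(hm)) hm <- fill_na_linear(hm)
  list(x = hm, hour = hour_of_day)
}

#' Interdaily stability
#'
#' IS = n * sum_h (xbar_h - xbar)^2 / (p * sum_i (x_i - xbar)^2) computed on
#' the record's hourly means, with p = 24 hourly bins, xbar_h the per-hour-
#' of-day means and n the number of hourly values. IS is 1 for a perfectly
#' 24-h-periodic series and about 1/days for structureless noise.
#'
#' @param series a `regular_series` spanning at least 2 days.
#' @return IS, or flagged `NA` for a constant series.
#' @export
interdaily_stability <- function(series) {
  hs <- hourly_series(series)
  x <- hs$x
  n <- length(x)
  xbar <- mean(x)
  denom <- 24 * sum((x - xbar)^2)
  if (denom == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "zero variance"
    return(out)
  }
  xh <- tapply(x, hs$hour, mean)
  n * sum((xh - xbar)^2) / denom
}

#' Intradaily variability
#'
#' IV = n * sum_{i>=2} (x_i - x_{i-1})^2 / ((n - 1) * sum_i (x_i - xbar)^2)
#' on the hourly means; about 2 for structureless noise and well below 1 for
#' a smooth 24-h rhythm.
#'
#' @param series a `regular_series`.
#' @return IV, or flagged `NA` for a constant series.
#' @export
intradaily_variability <- function(series) {
  x <- hourly_series(series)$x
  n <- length(x)
  if (n < 2L) stop("need at least 2 hourly means", call. = FALSE)
  xbar <- mean(x)
  denom <- (n - 1) * sum((x - xbar)^2)
  if (denom == 0) {
    out <- NA_real_
    attr(out, "flagged") <- "zero variance"
    return(out)
  }
  n * sum(diff(x)^2) / denom
}
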