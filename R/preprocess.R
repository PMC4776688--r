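## Containers -----------------------------------------------------------------

#' Irregularly timestamped sample series
#'
#' @param time POSIXct timestamps (UTC), strictly increasing.
#' @param value numeric sample values; activity must lie in \[0, 1\].
#' @param kind `"hr"` (beats per minute) or `"activity"` (arbitrary units).
#' @return a `sample_series`: data.frame with columns `time`, `value` and a
#'   `kind` attribute.
#' @export
sample_series <- function(time, value, kind = c("hr", "activity")) {
  kind <- match.arg(kind)
  if (length(time) != length(value)) stop("time/value length mismatch", call. = FALSE)
  if (is.unsorted(as.numeric(time), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (kind == "activity" && length(value) &&
      (min(value, na.rm = TRUE) < 0 || max(value, na.rm = TRUE) > 1)) {
    stop("activity values must lie in [0, 1]", call. = FALSE)
  }
  out <- data.frame(time = time, value = as.numeric(value))
  attr(out, "kind") <- kind
  class(out) <- c("sample_series", "data.frame")
  out
}

series_kind <- function(series) attr(series, "kind") %||% "hr"

#' Evenly resampled series with explicit missingness
#'
#' @param values numeric vector; `NA` marks a missing slot.
#' @param interval slot interval in minutes.
#' @param start POSIXct time of the first slot (used when `times` is NULL).
#' @param times optional POSIXct slot times (for day-restricted series whose
#'   slots are not contiguous in calendar time).
#' @param kind `"hr"` or `"activity"`.
#' @return a `regular_series` list with fields `times`, `interval`, `values`,
#'   `kind`, `quality_fraction`.
#' @export
regular_series <- function(values, interval, start = NULL, times = NULL,
                           kind = c("hr", "activity")) {
  kind <- match.arg(kind)
  if (is.null(times)) {
    if (is.null(start)) stop("provide `start` or `times`", call. = FALSE)
    times <- start + (seq_along(values) - 1) * interval * 60
  }
  if (length(times) != length(values)) stop("times/values length mismatch", call. = FALSE)
  out <- list(times = times, interval = interval, values = as.numeric(values),
              kind = kind, quality_fraction = mean(is.na(values)))
  class(out) <- "regular_series"
  out
}

#' @export
print.regular_series <- function(x, ...) {
  cat(sprintf("<regular_series> %s, %d slots at %g min, %.1f%% missing\n",
              x$kind, length(x$values), x$interval, 100 * x$quality_fraction))
  invisible(x)
}

## Rules ----------------------------------------------------------------------

#' Flag long inter-sample gaps
#'
#' Any interval between consecutive samples exceeding 1.5x the nominal
#' collection rate (15 min for 10-min HR, 7.5 min for 5-min activity) is
#' annotated as a quality gap; the resampler will not hold values across an
#' annotated span.
#'
#' @param series a `sample_series`.
#' @param nominal_interval nominal collection interval in minutes.
#' @return `series` with a `gaps` attribute (data.frame `start`, `end` in
#'   POSIXct) and a `nominal_interval` attribute.
#' @export
flag_long_gaps <- function(series, nominal_interval) {
  tt <- as.numeric(series$time)
  if (is.unsorted(tt, strictly = TRUE)) stop("timestamps must be strictly increasing", call. = FALSE)
  thr <- 1.5 * nominal_interval * 60
  d <- diff(tt)
  idx <- which(d > thr)  # strictly "exceeding"
  gaps <- data.frame(start = series$time[idx], end = series$time[idx + 1L])
  attr(series, "gaps") <- gaps
  attr(series, "nominal_interval") <- nominal_interval
  series
}

#' Remove implausibly low heart-rate samples
#'
#' Samples strictly below `floor` bpm are removed and counted as artifacts;
#' a value exactly at the floor is retained.
#'
#' @param series an HR `sample_series`.
#' @param floor bpm threshold, default 20.
#' @return filtered series with attributes `artifact_count` and
#'   `artifact_fraction` (relative to the input sample count).
#' @export
filter_hr_floor <- function(series, floor = 20) {
  if (series_kind(series) != "hr") stop("HR floor filter applies to HR series only", call. = FALSE)
  n <- nrow(series)
  bad <- series$value < floor
  out <- series[!bad, , drop = FALSE]
  attr(out, "kind") <- "hr"
  class(out) <- c("sample_series", "data.frame")
  attr(out, "artifact_count") <- sum(bad)
  attr(out, "artifact_fraction") <- if (n > 0) sum(bad) / n else 0
  out
}

#' Zero-order-hold resampling onto a regular grid
#'
#' Each grid slot takes the most recent observed value (sample-and-hold).
#' A slot is missing when its most recent observation lies more than
#' 1.5x the nominal interval in the past, or when the slot falls strictly
#' inside a flagged quality gap.
#'
#' The grid is anchored at local midnight (UTC) of the first observation so
#' slot-of-day positions align across days, and extends to the first grid
#' point at or after the last observation.
#'
#' @param series a `sample_series`, gaps already flagged by [flag_long_gaps()].
#' @param interval grid interval in minutes.
#' @return a `regular_series`.
#' @export
resample_zoh <- function(series, interval) {
  if (nrow(series) == 0L) stop("cannot resample an empty series", call. = FALSE)
  gaps <- attr(series, "gaps")
  if (is.null(gaps)) {
    series <- flag_long_gaps(series, interval)
    gaps <- attr(series, "gaps")
  }
  tt <- as.numeric(series$time)
  day0 <- as.POSIXct(trunc(series$time[1], units = "days"))
  t0 <- as.numeric(day0)
  step <- interval * 60
  last <- tt[length(tt)]
  ## grid covers whole calendar days so multi-signal grids stay aligned;
  ## slots after the last observation become missing via the staleness rule
  end <- t0 + ceiling((last - t0) / 86400) * 86400
  nslot <- as.integer(round((end - t0) / step))
  slot_t <- t0 + (seq_len(nslot) - 1) * step
  idx <- findInterval(slot_t, tt)
  vals <- rep(NA_real_, nslot)
  has <- idx > 0L
  vals[has] <- series$value[idx[has]]
  stale <- has & (slot_t - tt[pmax(idx, 1L)] > 1.5 * step)
  vals[stale] <- NA_real_
  if (nrow(gaps)) {
    gs <- as.numeric(gaps$start); ge <- as.numeric(gaps$end)
    for (g in seq_along(gs)) {
      vals[slot_t > gs[g] & slot_t < ge[g]] <- NA_real_
    }
  }
  regular_series(vals, interval,
                 times = as.POSIXct(slot_t, origin = "1970-01-01", tz = "UTC"),
                 kind = series_kind(series))
}

#' Linear down-sampling of a regular series
#'
#' Each target slot is the mean of the consecutive source slots it covers
#' (for 5 -> 10 min, the two bracketing 5-min values); it is missing when any
#' covered source slot is missing. A trailing remainder is dropped.
#'
#' @param series a `regular_series`.
#' @param target target interval in minutes; must be a multiple of the
#'   source interval.
#' @return a `regular_series` at the target interval.
#' @export
downsample_linear <- function(series, target = 10) {
  ratio <- target / series$interval
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("target interval must be a multiple of the source interval", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  n <- length(series$values)
  nout <- n %/% ratio
  if (nout == 0L) stop("series shorter than one target slot", call. = FALSE)
  m <- matrix(series$values[seq_len(nout * ratio)], nrow = ratio)
  vals <- colMeans(m)  # NA if any covered slot is NA
  regular_series(vals, target,
                 times = series$times[seq(1L, by = ratio, length.out = nout)],
                 kind = series$kind)
}

## per-day missing fractions on the slot grid; partial calendar days count
## their absent slots as missing
day_missingness <- function(series) {
  dates <- as.Date(series$times, tz = "UTC")
  per_day <- as.integer(round(1440 / series$interval))
  present <- tapply(!is.na(series$values), dates, sum)
  days <- as.Date(names(present))
  data.frame(date = days,
             missing_fraction = 1 - as.numeric(present) / per_day,
             row.names = NULL)
}

#' Select the days with the least missing data
#'
#' Restricts a regular series to the `n_days` calendar days with the lowest
#' missing fraction; ties are broken in favour of the earlier date, which
#' makes the selection deterministic.
#'
#' @param series a `regular_series`.
#' @param n_days number of days to retain, default 10.
#' @param report optional externally computed per-day report (data.frame
#'   `date`, `missing_fraction`), e.g. a joint HR/activity fraction; defaults
#'   to this series' own missingness.
#' @return list with `series` (restricted), `days` (selected dates, sorted)
#'   and `report` (per-day fractions for the whole record).
#' @export
select_best_days <- function(series, n_days = 10, report = NULL) {
  rep_df <- report %||% day_missingness(series)
  if (nrow(rep_df) < n_days) {
    stop(sprintf("record spans %d day(s); %d required", nrow(rep_df), n_days),
         call. = FALSE)
  }
  ord <- order(rep_df$missing_fraction, rep_df$date)
  days <- sort(rep_df$date[ord[seq_len(n_days)]])
  keep <- as.Date(series$times, tz = "UTC") %in% days
  out <- regular_series(series$values[keep], series$interval,
                        times = series$times[keep], kind = series$kind)
  list(series = out, days = days, report = rep_df)
}

#' Subject-level quality gate
#'
#' Rejects a preprocessed subject when the HR artifact fraction exceeds the
#' threshold, or when the post-selection missing fraction of either signal
#' does. Comparisons are strict ("more than"), so a fraction exactly at the
#' threshold is accepted.
#'
#' @param artifact_fraction fraction of raw HR samples removed as artifacts.
#' @param hr_missing,act_missing missing fractions after day selection.
#' @param threshold default 0.10.
#' @return list with `accept` (logical) and `reasons` (character).
#' @export
quality_gate <- function(artifact_fraction, hr_missing, act_missing,
                         threshold = 0.10) {
  reasons <- character(0)
  if (artifact_fraction > threshold) {
    reasons <- c(reasons, sprintf("HR artifact fraction %.1f%% > %.0f%%",
                                  100 * artifact_fraction, 100 * threshold))
  }
  if (hr_missing > threshold) {
    reasons <- c(reasons, sprintf("HR missing %.1f%% > %.0f%%",
                                  100 * hr_missing, 100 * threshold))
  }
  if (act_missing > threshold) {
    reasons <- c(reasons, sprintf("activity missing %.1f%% > %.0f%%",
                                  100 * act_missing, 100 * threshold))
  }
  list(accept = length(reasons) == 0L, reasons = reasons)
}

## Subject / cohort drivers ---------------------------------------------------

#' Preprocess one subject record
#'
#' Applies the full rule set: HR floor filter, long-gap flagging for both
#' signals, zero-order-hold resampling (HR to 10 min, activity to 5 min),
#' joint best-day selection (days ranked by the mean of the two signals'
#' missing fractions so both share one retained-day set), linear
#' down-sampling of activity to the synchronized 10-min grid, and the 10%
#' quality gate.
#'
#' @param record a `subject_record` from the generator or [read_cohort_csv()].
#' @param hr_interval,act_interval grid intervals in minutes.
#' @param n_days days to retain, default 10.
#' @param gate quality-gate threshold, default 0.10.
#' @return a `processed_subject` list: `subject_id`, `label`, `hr` (10-min),
#'   `activity` (5-min), `activity10` (10-min, synchronized), `days`,
#'   `qc` (fractions, accept flag, reasons) and `day_report`.
#' @export
preprocess_subject <- function(record, hr_interval = 10, act_interval = 5,
                               n_days = 10, gate = 0.10) {
  hr_raw <- sample_series(record$hr$time, record$hr$value, "hr")
  act_raw <- sample_series(record$activity$time, record$activity$value, "activity")

  hr_f <- filter_hr_floor(hr_raw)
  artifact_fraction <- attr(hr_f, "artifact_fraction")
  hr_f <- flag_long_gaps(hr_f, hr_interval)
  act_f <- flag_long_gaps(act_raw, act_interval)

  hr_rs <- resample_zoh(hr_f, hr_interval)
  act_rs <- resample_zoh(act_f, act_interval)

  fr_hr <- day_missingness(hr_rs)
  fr_act <- day_missingness(act_rs)
  joint <- merge(fr_hr, fr_act, by = "date", suffixes = c("_hr", "_act"))
  joint$missing_fraction <- (joint$missing_fraction_hr + joint$missing_fraction_act) / 2

  reject <- function(reason) {
    structure(list(subject_id = record$subject_id, label = record$label,
                   accepted = FALSE, reason = reason),
              class = "rejected_subject")
  }
  if (nrow(joint) < n_days) {
    return(reject(sprintf("record spans %d day(s); %d required", nrow(joint), n_days)))
  }
  sel_hr <- select_best_days(hr_rs, n_days, report = joint[, c("date", "missing_fraction")])
  days <- sel_hr$days
  keep_act <- as.Date(act_rs$times, tz = "UTC") %in% days
  act_sel <- regular_series(act_rs$values[keep_act], act_interval,
                            times = act_rs$times[keep_act], kind = "activity")
  act10 <- downsample_days(act_sel, target = hr_interval)

  hr_missing <- sel_hr$series$quality_fraction
  act_missing <- act_sel$quality_fraction
  g <- quality_gate(artifact_fraction, hr_missing, act_missing, threshold = gate)
  if (!g$accept) return(reject(paste(g$reasons, collapse = "; ")))

  structure(list(subject_id = record$subject_id, label = record$label,
                 hr = sel_hr$series, activity = act_sel, activity10 = act10,
                 days = days,
                 qc = list(artifact_fraction = artifact_fraction,
                           hr_missing = hr_missing, act_missing = act_missing,
                           accepted = TRUE),
                 day_report = joint),
            class = "processed_subject")
}

## down-sample a possibly day-restricted series, day by day, so slot pairs
## never straddle a retained-day boundary
downsample_days <- function(series, target = 10) {
  dates <- as.Date(series$times, tz = "UTC")
  parts <- lapply(split(seq_along(series$values), dates), function(ix) {
    downsample_linear(regular_series(series$values[ix], series$interval,
                                     times = series$times[ix], kind = series$kind),
                      target = target)
  })
  vals <- unlist(lapply(parts, `[[`, "values"), use.names = FALSE)
  times <- do.call(c, lapply(parts, `[[`, "times"))
  regular_series(vals, target, times = times, kind = series$kind)
}

#' Preprocess a whole cohort
#'
#' @param records list of `subject_record`s.
#' @param ... passed to [preprocess_subject()].
#' @return list with `accepted` (processed subjects), `rejected` (data.frame
#'   `subject_id`, `label`, `reason`).
#' @export
preprocess_cohort <- function(records, ...) {
  out <- lapply(records, preprocess_subject, ...)
  ok <- vapply(out, function(x) inherits(x, "processed_subject"), logical(1))
  rejected <- data.frame(
    subject_id = vapply(out[!ok], `[[`, character(1), "subject_id"),
    label = vapply(out[!ok], `[[`, numeric(1), "label"),
    reason = vapply(out[!ok], `[[`, character(1), "reason")
  )
  list(accepted = out[ok], rejected = rejected)
}
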