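# Novel sleep features from per-night sleep variables.
#
# The per-night variables (onset/offset clock time, SPT-window duration,
# daytime sustained-inactivity duration, number of sleep periods, sleep
# efficiency) come from an external sleep-detection pipeline or from the
# synthetic generator; computing them from raw accelerometry is out of
# scope here.

is_weekend_night <- function(offset, tz = attr(offset, "tzone")) {
  # a night is a weekend night iff its wake-up falls on Saturday or Sunday
  # (the "free day" convention used for social-jetlag measures)
  format(offset, "%u", tz = tz) %in% c("6", "7")
}

#' Weekend minus weekday mean sleep duration
#'
#' Captures sleeping disproportionately on free days: mean sleep duration
#' over weekend nights minus the mean over weekday nights (hours). Missing
#' when either class has no nights.
#'
#' @param duration_h Per-night sleep durations in hours.
#' @param weekend Logical per night (see the wake-day convention above).
#' @return A single number (hours), positive when weekends are longer.
#' @export
we_wd_difference <- function(duration_h, weekend) {
  ok <- !is.na(duration_h)
  if (!any(weekend & ok) || !any(!weekend & ok)) return(NA_real_)
  mean(duration_h[weekend & ok]) - mean(duration_h[!weekend & ok])
}

#' Percentage of nights with sleep onset before midnight
#'
#' @param onset POSIXct sleep onsets.
#' @return Percentage in \[0, 100\] of nights whose onset clock time falls in
#'   \[19:00, 24:00); missing when no onsets are available.
#' @export
pct_onset_before_midnight <- function(onset) {
  onset <- onset[!is.na(onset)]
  if (length(onset) == 0) return(NA_real_)
  h <- as.numeric(format(onset, "%H")) + as.numeric(format(onset, "%M")) / 60
  100 * mean(h >= 19 & h < 24)
}

#' Trend of a per-night sleep variable over a wear period
#'
#' The Pearson correlation between the ordinal night index of the available
#' nights and the variable's value on those nights (the standardized slope
#' of the best-fit line). Night indices keep their calendar position, so a
#' skipped night leaves a gap rather than renumbering.
#'
#' @param night_index Integer night indices of the available nights.
#' @param value Variable values on those nights.
#' @param min_nights Minimum nights required; default 3.
#' @return Correlation in \[-1, 1\]; missing when fewer than `min_nights`
#'   complete pairs exist or the variable is constant.
#' @export
sleep_trend <- function(night_index, value, min_nights = 3) {
  ok <- !is.na(night_index) & !is.na(value)
  if (sum(ok) < min_nights) return(NA_real_)
  x <- night_index[ok]; y <- value[ok]
  if (sd(y) == 0 || sd(x) == 0) return(NA_real_)
  cor(x, y)
}

#' Extract the novel sleep features for one subject-period
#'
#' Eight features: the weekend-weekday sleep duration difference, the
#' percentage of nights with onset before midnight, and the trends of six
#' per-night variables (onset time, offset time, SPT-window duration,
#' daytime sustained-inactivity duration, number of sleep periods, sleep
#' efficiency). Onset clock times are encoded as hours since 19:00 so pre-
#' and post-midnight onsets are monotone on one axis; offsets as hours
#' since midnight.
#'
#' @param night_vars Tibble with one row per night: `night` (ordinal index),
#'   `onset`, `offset` (POSIXct), `spt_h`, `sibd_h`, `n_sleep_periods`,
#'   `sleep_eff`.
#' @return A one-row tibble of the 8 features.
#' @export
extract_sleep_features <- function(night_vars) {
  nv <- night_vars
  tz <- attr(nv$onset, "tzone")
  onset_h <- as.numeric(format(nv$onset, "%H", tz = tz)) +
    as.numeric(format(nv$onset, "%M", tz = tz)) / 60
  onset_rel <- (onset_h - 19) %% 24
  offset_h <- as.numeric(format(nv$offset, "%H", tz = tz)) +
    as.numeric(format(nv$offset, "%M", tz = tz)) / 60
  weekend <- is_weekend_night(nv$offset, tz)

  tibble::tibble(
    we_wd_diff = we_wd_difference(nv$spt_h, weekend),
    pct_onset_before_midnight = pct_onset_before_midnight(nv$onset),
    trend_onset = sleep_trend(nv$night, onset_rel),
    trend_offset = sleep_trend(nv$night, offset_h),
    trend_spt_dur = sleep_trend(nv$night, nv$spt_h),
    trend_sibd_dur = sleep_trend(nv$night, nv$sibd_h),
    trend_n_sleep_periods = sleep_trend(nv$night, nv$n_sleep_periods),
    trend_sleep_eff = sleep_trend(nv$night, nv$sleep_eff)
  )
}

#' Names of the novel sleep features
#' @return Character vector of the 8 feature names.
#' @export
sleep_feature_names <- function() {
  c("we_wd_diff", "pct_onset_before_midnight", "trend_onset", "trend_offset",
    "trend_spt_dur", "trend_sibd_dur", "trend_n_sleep_periods",
    "trend_sleep_eff")
}
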