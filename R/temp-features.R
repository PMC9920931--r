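# Novel temperature features.
#
# Per-night and per-day summaries are computed on smoothed quarter-hour
# series and aggregated to one row per wear period. The canonical set
# comprises 19 features; `extended = TRUE` adds the further means/sds the
# full mean-and-sd expansion would produce plus the "hours before waking"
# aliases of the after-onset timings.

#' Summarize one valid night of smoothed sleep temperature
#'
#' Computes the building blocks of the per-period temperature features from
#' a single night's smoothed quarter-hour series (sleep onset to offset,
#' closed interval): mean, sd and IQR of temperature; hours after sleep
#' onset at which the in-sleep minimum and maximum occur (ties broken by the
#' earliest occurrence); the maximum rate of temperature increase (MROI) and
#' decrease (MROD) across successive 15-min intervals together with their
#' timing (hours after onset at the end of the winning interval); and the
#' length-normalized approximate entropy.
#'
#' @param series Numeric vector of smoothed quarter-hour temperatures.
#' @param config A [wf_config()] list.
#' @return A one-row tibble.
#' @export
summarize_night <- function(series, config = wf_config()) {
  tibble::as_tibble(as.list(night_stats(series, config)))
}

night_stats <- function(series, config) {
  k <- length(series)
  d <- diff(series)
  has_d <- length(d) > 0
  c(
    t_mean = mean(series),
    t_sd = sd(series),
    t_iqr = IQR(series),
    t_min_rel = 0.25 * (which.min(series) - 1),
    t_max_rel = 0.25 * (which.max(series) - 1),
    mroi = if (has_d) max(d) else 0,
    mrod = if (has_d) max(-d) else 0,
    t_mroi = if (has_d) 0.25 * which.max(d) else NA_real_,
    t_mrod = if (has_d) 0.25 * which.max(-d) else NA_real_,
    apen_night = if (k >= config$apen_m + 2)
      apen_normalized(series, config$apen_m, config$apen_r_coeff) else NA_real_,
    k = k
  )
}

#' Summarize one valid 08:00-08:00 day of smoothed temperature
#'
#' @param series Numeric vector (97 quarter-hour points, smoothed).
#' @inheritParams summarize_night
#' @return A one-row tibble: clock timing (hours since the 08:00 window
#'   start) of the 24-h minimum and maximum, the min-max difference, and the
#'   normalized 24-h approximate entropy.
#' @export
summarize_day <- function(series, config = wf_config()) {
  tibble::as_tibble(as.list(day_stats(series, config)))
}

day_stats <- function(series, config) {
  c(
    t_day_min = 0.25 * (which.min(series) - 1),
    t_day_max = 0.25 * (which.max(series) - 1),
    min_max_diff = max(series) - min(series),
    apen_day = apen_normalized(series, config$apen_m, config$apen_r_coeff)
  )
}

#' Sleep-wake temperature difference over 48-h spans
#'
#' For each sleep window, over the 48 h starting at 00:00 on the day of
#' sleep onset: mean quarter-hour temperature inside any sleep window in the
#' span minus the mean over the remaining (wake) bins. Missing when either
#' class of bins has no data.
#'
#' @param qtemp Quarter-hour grid (columns `bin_start`, `temp`).
#' @param sleep_windows Tibble with `onset`, `offset` for the subject-period.
#' @return Numeric vector, one value per sleep window.
#' @export
sleep_wake_diff_48h <- function(qtemp, sleep_windows) {
  tz <- attr(qtemp$bin_start, "tzone")
  t_num <- as.numeric(qtemp$bin_start)
  in_sleep <- rep(FALSE, nrow(qtemp))
  for (i in seq_len(nrow(sleep_windows))) {
    in_sleep <- in_sleep |
      (t_num >= as.numeric(sleep_windows$onset[i]) &
         t_num <= as.numeric(sleep_windows$offset[i]))
  }
  vapply(seq_len(nrow(sleep_windows)), function(i) {
    d0 <- as.POSIXct(paste(as.Date(sleep_windows$onset[i], tz = tz), "00:00:00"), tz = tz)
    span <- t_num >= as.numeric(d0) & t_num < as.numeric(d0) + 48 * 3600
    sl <- qtemp$temp[span & in_sleep]; wk <- qtemp$temp[span & !in_sleep]
    sl <- sl[!is.na(sl)]; wk <- wk[!is.na(wk)]
    if (length(sl) == 0 || length(wk) == 0) NA_real_ else mean(sl) - mean(wk)
  }, numeric(1))
}

#' Names of the per-period temperature features
#'
#' @param which `"canonical"` (the counted 19) or `"extended"` (additional
#'   means/sds and before-waking aliases).
#' @return Character vector of feature names.
#' @export
temp_feature_names <- function(which = c("canonical", "extended")) {
  which <- match.arg(which)
  canonical <- c(
    "temp_mean_sd",
    "temp_sd_mean", "temp_sd_sd",
    "temp_iqr_mean", "temp_iqr_sd",
    "time_day_min_sd", "time_day_max_sd",
    "temp_min_after_onset_mean", "temp_min_after_onset_sd",
    "temp_max_after_onset_mean", "temp_max_after_onset_sd",
    "time_mroi_mean", "time_mroi_sd",
    "time_mrod_mean", "time_mrod_sd",
    "apen_sleep_all_nights",
    "apen_day_mean",
    "temp_min_max_diff",
    "sleep_wake_diff_mean"
  )
  if (which == "canonical") return(canonical)
  c("apen_sleep_mean", "apen_sleep_sd", "apen_day_sd", "sleep_wake_diff_sd",
    "mroi_mean", "mroi_sd", "mrod_mean", "mrod_sd",
    "temp_min_before_wake_mean", "temp_max_before_wake_mean")
}

sd2 <- function(x) { x <- x[!is.na(x)]; if (length(x) >= 2) sd(x) else NA_real_ }
mean1 <- function(x) { x <- x[!is.na(x)]; if (length(x) >= 1) mean(x) else NA_real_ }

#' Aggregate night and day summaries into per-period temperature features
#'
#' Means and standard deviations are taken across the available valid
#' nights/days of the wear period (sd features require at least two). The
#' all-nights entropy concatenates every valid night's smoothed series and
#' divides the ApEn of the concatenation by the total number of points.
#'
#' @param nights Night tibble from [extract_temp_windows()] (only valid
#'   nights are used).
#' @param days Day tibble from [extract_temp_windows()].
#' @param swd Numeric vector from [sleep_wake_diff_48h()] aligned with the
#'   night rows.
#' @inheritParams summarize_night
#' @param extended Also emit the extra means/sds and before-waking aliases.
#' @return A one-row tibble of temperature features (19 columns by default).
#' @export
aggregate_period <- function(nights, days, swd, config = wf_config(),
                             extended = FALSE) {
  vn <- nights[nights$valid, ]
  ns <- as.data.frame(if (nrow(vn))
    t(vapply(vn$series, night_stats, night_stats(rep(1, 5), config), config))
    else t(night_stats(rep(1, 5), config))[0, , drop = FALSE])
  vd <- days[days$valid, ]
  ds <- as.data.frame(if (nrow(vd))
    t(vapply(vd$series, day_stats, day_stats(rep(1, 5), config), config))
    else t(day_stats(rep(1, 5), config))[0, , drop = FALSE])
  swd_valid <- swd[nights$valid]

  concat <- unlist(vn$series)
  apen_all <- if (length(concat) >= config$apen_m + 2)
    apen(concat, config$apen_m, config$apen_r_coeff) / length(concat)
  else NA_real_

  out <- tibble::tibble(
    temp_mean_sd = sd2(ns$t_mean),
    temp_sd_mean = mean1(ns$t_sd), temp_sd_sd = sd2(ns$t_sd),
    temp_iqr_mean = mean1(ns$t_iqr), temp_iqr_sd = sd2(ns$t_iqr),
    time_day_min_sd = sd2(ds$t_day_min), time_day_max_sd = sd2(ds$t_day_max),
    temp_min_after_onset_mean = mean1(ns$t_min_rel),
    temp_min_after_onset_sd = sd2(ns$t_min_rel),
    temp_max_after_onset_mean = mean1(ns$t_max_rel),
    temp_max_after_onset_sd = sd2(ns$t_max_rel),
    time_mroi_mean = mean1(ns$t_mroi), time_mroi_sd = sd2(ns$t_mroi),
    time_mrod_mean = mean1(ns$t_mrod), time_mrod_sd = sd2(ns$t_mrod),
    apen_sleep_all_nights = apen_all,
    apen_day_mean = mean1(ds$apen_day),
    temp_min_max_diff = mean1(ds$min_max_diff),
    sleep_wake_diff_mean = mean1(swd_valid)
  )
  if (extended) {
    dur <- 0.25 * (ns$k - 1)
    out <- dplyr::bind_cols(out, tibble::tibble(
      apen_sleep_mean = mean1(ns$apen_night), apen_sleep_sd = sd2(ns$apen_night),
      apen_day_sd = sd2(ds$apen_day),
      sleep_wake_diff_sd = sd2(swd_valid),
      mroi_mean = mean1(ns$mroi), mroi_sd = sd2(ns$mroi),
      mrod_mean = mean1(ns$mrod), mrod_sd = sd2(ns$mrod),
      temp_min_before_wake_mean = mean1(dur - ns$t_min_rel),
      temp_max_before_wake_mean = mean1(dur - ns$t_max_rel)
    ))
  }
  out
}

#' Extract the novel temperature features for one subject-period
#'
#' Runs the full temperature chain on a recording plus its sleep windows:
#' low-temperature interpolation, quarter-hour averaging, non-wear
#' detection, noon-to-noon night validation, window extraction with
#' coverage rules, smoothing, per-night/per-day summaries, and aggregation.
#'
#' @param recording A `wf_recording` tibble for one subject and wear period.
#' @param sleep_windows Sleep windows for the same subject-period.
#' @param config A [wf_config()] list.
#' @param extended Emit the extended feature columns too.
#' @return A one-row tibble: `subject_id`, `period_id`, the temperature
#'   features, and bookkeeping counts `n_valid_nights`, `n_valid_days`.
#' @export
extract_temp_features <- function(recording, sleep_windows,
                                  config = wf_config(), extended = FALSE) {
  nonwear <- detect_nonwear(recording, config)
  valid_nights <- validate_nights(recording, nonwear, config)
  temp_imp <- impute_low_temperature(recording$temp, config)
  q_imp <- average_temp_15min(recording$time, temp_imp)
  q_raw <- average_temp_15min(recording$time, recording$temp)
  qtemp <- q_imp
  qtemp$temp_raw <- q_raw$temp[match(as.numeric(qtemp$bin_start),
                                     as.numeric(q_raw$bin_start))]
  win <- extract_temp_windows(qtemp, sleep_windows, valid_nights, config)
  swd <- sleep_wake_diff_48h(qtemp, sleep_windows)
  feats <- aggregate_period(win$nights, win$days, swd, config, extended)
  dplyr::bind_cols(
    tibble::tibble(subject_id = recording$subject_id[1],
                   period_id = recording$period_id[1]),
    feats,
    tibble::tibble(n_valid_nights = sum(win$nights$valid),
                   n_valid_days = sum(win$days$valid))
  )
}
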