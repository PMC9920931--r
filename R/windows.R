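# Night and day window extraction on the quarter-hour temperature grid.
#
# Conventions (all in local civil time):
#  * a "night" is labelled by the calendar date its 19:00 window starts on;
#    a sleep onset between 19:00 and 14:00 next day maps to that date
#    (onset - 14 h falls on the labelling date);
#  * night window 19:00 -> 14:00 next day: 77 quarter-hour points inclusive;
#  * day window 08:00 -> 08:00 next day: 97 points inclusive;
#  * sleep onset is rounded down and offset rounded up to the nearest
#    quarter hour, both endpoints included, so an h-hour sleep yields
#    4 h + 1 points.

floor_qtr <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 900) * 900, origin = "1970-01-01",
             tz = attr(t, "tzone"))
}
ceil_qtr <- function(t) {
  as.POSIXct(ceiling(as.numeric(t) / 900) * 900, origin = "1970-01-01",
             tz = attr(t, "tzone"))
}

night_date_of <- function(onset, tz = attr(onset, "tzone")) {
  as.Date(onset - 14 * 3600, tz = tz)
}

# pull values of a quarter-hour grid tibble for bins in [from, to] inclusive
grid_slice <- function(qtemp, from, to, col = "temp") {
  i0 <- match(as.numeric(from), as.numeric(qtemp$bin_start))
  i1 <- match(as.numeric(to), as.numeric(qtemp$bin_start))
  n_bins <- as.integer(round((as.numeric(to) - as.numeric(from)) / 900)) + 1L
  if (is.na(i0) && is.na(i1)) return(rep(NA_real_, n_bins))
  if (is.na(i0)) { # window starts before the grid
    lead <- as.integer(round((as.numeric(qtemp$bin_start[1]) - as.numeric(from)) / 900))
    c(rep(NA_real_, lead), grid_slice(qtemp, qtemp$bin_start[1], to, col))
  } else if (is.na(i1)) {
    n <- nrow(qtemp)
    trail <- as.integer(round((as.numeric(to) - as.numeric(qtemp$bin_start[n])) / 900))
    c(grid_slice(qtemp, from, qtemp$bin_start[n], col), rep(NA_real_, trail))
  } else {
    qtemp[[col]][i0:i1]
  }
}

# interpolate residual missing bins (coverage filters have already passed),
# extending flat at the edges, then smooth
fill_and_smooth <- function(x, q) {
  if (anyNA(x)) {
    ok <- which(!is.na(x))
    if (length(ok) == 0) return(x)
    x <- approx(ok, x[ok], xout = seq_along(x), method = "linear", rule = 2)$y
  }
  moving_average(x, q)
}

#' Build per-night and per-day smoothed temperature series
#'
#' Applies the window conventions for temperature feature extraction: sleep
#' onset/offset rounded down/up to the quarter hour (closed interval), night
#' coverage of at least 61 of the 77 possible 19:00-14:00 quarter-hour
#' values at or above the low-temperature threshold, at least 15 in-sleep
#' data points, day coverage of at least 77 of the 97 possible 08:00-08:00
#' values, and the noon-to-noon 10% non-wear rule. Series that pass are
#' gap-filled by linear interpolation and smoothed with the 7-point moving
#' average; failures are flagged with a reason, never dropped silently.
#'
#' @param qtemp Quarter-hour grid with columns `bin_start`, `temp`
#'   (low-temperature-imputed bin means) and `temp_raw` (bin means of the
#'   unimputed readings, used for the coverage counts).
#' @param sleep_windows Tibble with `onset`, `offset` (POSIXct) for one
#'   subject-period.
#' @param valid_nights Output of [validate_nights()].
#' @param config A [wf_config()] list.
#' @return A list with `nights` (tibble: `night_date, onset, offset, k,
#'   n_points, valid, reason, series` list-column of smoothed values) and
#'   `days` (tibble: `day_date, coverage, valid, series`).
#' @export
extract_temp_windows <- function(qtemp, sleep_windows, valid_nights,
                                 config = wf_config()) {
  tz <- attr(qtemp$bin_start, "tzone")
  thr <- config$low_temp_c

  nights <- purrr::map_dfr(seq_len(nrow(sleep_windows)), function(i) {
    onset <- sleep_windows$onset[i]; offset <- sleep_windows$offset[i]
    nd <- night_date_of(onset, tz)
    win_from <- as.POSIXct(paste(nd, sprintf("%02d:00:00", config$night_window_start)), tz = tz)
    win_to <- as.POSIXct(paste(nd + 1, sprintf("%02d:00:00", config$night_window_end)), tz = tz)
    raw_win <- grid_slice(qtemp, win_from, win_to, "temp_raw")
    coverage <- sum(!is.na(raw_win) & raw_win >= thr)

    on_q <- floor_qtr(onset); off_q <- ceil_qtr(offset)
    vals <- grid_slice(qtemp, on_q, off_q, "temp")
    n_points <- sum(!is.na(vals))
    k <- length(vals)

    noon_ok <- TRUE
    vn <- valid_nights$valid[valid_nights$night_date == nd]
    if (length(vn) == 1) noon_ok <- vn

    reason <- if (!noon_ok) "nonwear_night"
      else if (coverage < config$night_coverage_min) "night_coverage"
      else if (n_points < config$min_sleep_points) "few_sleep_points"
      else NA_character_
    valid <- is.na(reason)
    series <- if (valid) fill_and_smooth(vals, config$ma_q) else vals
    tibble::tibble(night_date = nd, onset = on_q, offset = off_q,
                   k = k, n_points = n_points, coverage = coverage,
                   valid = valid, reason = reason, series = list(series))
  })

  first_day <- as.Date(qtemp$bin_start[1], tz = tz)
  last_day <- as.Date(qtemp$bin_start[nrow(qtemp)], tz = tz)
  day_dates <- seq(first_day, last_day - 1, by = "day")
  days <- purrr::map_dfr(day_dates, function(d) {
    from <- as.POSIXct(paste(d, sprintf("%02d:00:00", config$day_window_start)), tz = tz)
    to <- from + 86400
    raw_win <- grid_slice(qtemp, from, to, "temp_raw")
    coverage <- sum(!is.na(raw_win) & raw_win >= thr)
    valid <- coverage >= config$day_coverage_min
    vals <- grid_slice(qtemp, from, to, "temp")
    series <- if (valid) fill_and_smooth(vals, config$ma_q) else vals
    tibble::tibble(day_date = d, coverage = coverage, valid = valid,
                   series = list(series))
  })

  list(nights = nights, days = days)
}
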