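#' Epoch activity summary: Euclidean norm minus one, negatives zeroed
#'
#' Summarizes calibrated tri-axial acceleration into a single non-negative
#' per-epoch value: `max(0, sqrt(x^2 + y^2 + z^2) - 1)`, expressed in
#' milli-g. At rest the norm equals gravity, so the summary is 0; sensor
#' noise can push the norm below 1 g, and those negative values are clipped.
#'
#' @param recording A `wf_recording` tibble (acceleration in g).
#' @return A tibble `time, enmonz` (mg), one row per epoch.
#' @export
compute_enmonz <- function(recording) {
  en <- sqrt(recording$x^2 + recording$y^2 + recording$z^2) - 1
  tibble::tibble(time = recording$time, enmonz = pmax(en, 0) * 1000)
}

#' Detect non-wear intervals from accelerometer stillness
#'
#' The recording is divided into 15-min blocks anchored to clock quarter
#' hours. Each block is classified using the 60-min window centred on the
#' block midpoint (clipped at the recording bounds): the block is non-wear
#' when, for at least two of the three axes, the windowed standard deviation
#' is below 13 mg or the windowed value range is below 50 mg. Adjacent
#' flagged blocks are merged into intervals.
#'
#' The criterion only uses per-axis dispersion, so it is invariant to a
#' constant offset added to all axes.
#'
#' @param recording A `wf_recording` tibble.
#' @param config A [wf_config()] list.
#' @return A tibble `start, end, n_axes` of merged non-wear intervals (15-min
#'   aligned); zero rows when nothing is flagged. Recordings shorter than one
#'   window return zero rows with a warning.
#' @export
detect_nonwear <- function(recording, config = wf_config()) {
  t_num <- as.numeric(recording$time)
  span <- t_num[length(t_num)] - t_num[1]
  empty <- tibble::tibble(start = recording$time[0], end = recording$time[0],
                          n_axes = integer())
  if (span < config$nonwear_window_min * 60) {
    warn("Recording shorter than one non-wear window; no classification done.")
    return(empty)
  }
  block_s <- config$nonwear_block_min * 60
  half_win <- config$nonwear_window_min * 60 / 2
  t0 <- floor(t_num[1] / block_s) * block_s
  block_starts <- seq(t0, t_num[length(t_num)], by = block_s)
  n_ep <- length(t_num)
  dt <- (t_num[n_ep] - t_num[1]) / (n_ep - 1)

  acc <- cbind(recording$x, recording$y, recording$z) * 1000  # mg
  sd_thr <- config$nonwear_sd_mg
  rg_thr <- config$nonwear_range_mg

  # epoch index ranges of the clipped centred windows (uniform spacing)
  mids <- block_starts + block_s / 2
  i0 <- pmax(ceiling((mids - half_win - t_num[1]) / dt) + 1L, 1L)
  i1 <- pmin(floor((mids + half_win - 1e-9 - t_num[1]) / dt) + 1L, n_ep)

  # windowed per-axis sd via cumulative sums; range via direct slice min/max
  cs <- apply(acc, 2, function(v) c(0, cumsum(v)))
  cs2 <- apply(acc, 2, function(v) c(0, cumsum(v^2)))
  nw_len <- i1 - i0 + 1L
  flag <- logical(length(block_starts))
  n_axes <- integer(length(block_starts))
  for (b in seq_along(block_starts)) {
    if (nw_len[b] < 2L) next
    a <- i0[b]; z <- i1[b]; m <- nw_len[b]
    still <- 0L
    for (ax in 1:3) {
      s1 <- cs[z + 1L, ax] - cs[a, ax]
      s2 <- cs2[z + 1L, ax] - cs2[a, ax]
      v <- max((s2 - s1^2 / m) / (m - 1), 0)
      if (sqrt(v) < sd_thr) { still <- still + 1L; next }
      w <- acc[a:z, ax]
      if (max(w) - min(w) < rg_thr) still <- still + 1L
    }
    n_axes[b] <- still
    flag[b] <- still >= config$nonwear_axes
  }
  if (!any(flag)) return(empty)

  runs <- rle(flag)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  keep <- which(runs$values)
  tz <- attr(recording$time, "tzone")
  tibble::tibble(
    start = as.POSIXct(block_starts[idx_start[keep]], origin = "1970-01-01", tz = tz),
    end = as.POSIXct(block_starts[idx_end[keep]] + block_s, origin = "1970-01-01", tz = tz),
    n_axes = vapply(keep, function(k) {
      max(n_axes[idx_start[k]:idx_end[k]])
    }, integer(1))
  )
}

# per-epoch wear flag from non-wear intervals
wear_flag <- function(times, nonwear) {
  flag <- rep(TRUE, length(times))
  if (nrow(nonwear) == 0) return(flag)
  t_num <- as.numeric(times)
  for (i in seq_len(nrow(nonwear))) {
    flag[t_num >= as.numeric(nonwear$start[i]) &
           t_num < as.numeric(nonwear$end[i])] <- FALSE
  }
  flag
}

#' Valid calendar days of a recording
#'
#' A calendar day is valid when at least `valid_day_hours` (default 16 h) of
#' wear time is present; a wear period is usable for analysis only when it
#' contains at least `min_valid_days` (default 7) valid days.
#'
#' @inheritParams detect_nonwear
#' @param nonwear Non-wear intervals from [detect_nonwear()].
#' @return A tibble `day, wear_hours, valid` with an attribute
#'   `usable_period` (logical).
#' @export
filter_valid_days <- function(recording, nonwear, config = wf_config()) {
  dt <- as.numeric(recording$time[2]) - as.numeric(recording$time[1])
  wear <- wear_flag(recording$time, nonwear)
  day <- as.Date(recording$time, tz = attr(recording$time, "tzone"))
  out <- tibble::tibble(day = day, wear = wear) |>
    dplyr::group_by(day) |>
    dplyr::summarise(wear_hours = sum(wear) * dt / 3600, .groups = "drop") |>
    dplyr::mutate(valid = .data$wear_hours >= config$valid_day_hours)
  attr(out, "usable_period") <- sum(out$valid) >= config$min_valid_days
  out
}

#' Impute activity during non-wear from matching clock times
#'
#' Each non-wear epoch on a valid day is replaced by the mean of the
#' same-clock-time epochs on the other days that have worn data; epochs with
#' no donor on any other day are left missing.
#'
#' @param activity Tibble `time, enmonz` from [compute_enmonz()].
#' @inheritParams filter_valid_days
#' @param valid_days Output of [filter_valid_days()].
#' @return `activity` with columns `enmonz` (imputed where possible, `NA`
#'   where no donor existed) and `imputed` (logical).
#' @export
impute_nonwear_epochs <- function(activity, nonwear, valid_days,
                                  config = wf_config()) {
  tz <- attr(activity$time, "tzone")
  wear <- wear_flag(activity$time, nonwear)
  day <- as.Date(activity$time, tz = tz)
  clock <- format(activity$time, "%H:%M:%S", tz = tz)
  on_valid <- day %in% valid_days$day[valid_days$valid]
  target <- !wear & on_valid

  out <- activity
  out$imputed <- FALSE
  if (!any(target)) return(out)

  # donor means per clock time, excluding the receiving day by leave-one-out
  don_sum <- tapply(ifelse(wear, activity$enmonz, 0), clock, sum)
  don_n <- tapply(wear, clock, sum)
  for (i in which(target)) {
    ck <- clock[i]
    # all donors share this clock time and are on other days because the
    # receiving epoch itself is non-wear (contributes nothing to the sums)
    n <- don_n[[ck]]
    if (is.na(n) || n == 0) {
      out$enmonz[i] <- NA_real_
    } else {
      out$enmonz[i] <- don_sum[[ck]] / n
      out$imputed[i] <- TRUE
    }
  }
  out
}

#' Classify noon-to-noon nights by non-wear burden
#'
#' Nights are 24-h windows from 12:00 to 12:00 (local civil time). A night
#' with strictly more than `night_invalid_frac` (default 10%) of its span
#' covered by non-wear is excluded from temperature feature extraction.
#'
#' @inheritParams filter_valid_days
#' @return A tibble `night_date, noon_start, nonwear_frac, valid`, one row
#'   per noon-to-noon window overlapping the recording. `night_date` is the
#'   calendar date the window starts on.
#' @export
validate_nights <- function(recording, nonwear, config = wf_config()) {
  tz <- attr(recording$time, "tzone")
  first_day <- as.Date(recording$time[1], tz = tz)
  last_day <- as.Date(recording$time[nrow(recording)], tz = tz)
  dates <- seq(first_day - 1, last_day, by = "day")
  noon <- as.POSIXct(paste(dates, "12:00:00"), tz = tz)
  keep <- (noon + 86400) > recording$time[1] & noon < recording$time[nrow(recording)]
  dates <- dates[keep]; noon <- noon[keep]

  frac <- vapply(seq_along(noon), function(i) {
    a <- as.numeric(noon[i]); b <- a + 86400
    if (nrow(nonwear) == 0) return(0)
    ov <- pmin(as.numeric(nonwear$end), b) - pmax(as.numeric(nonwear$start), a)
    sum(pmax(ov, 0)) / 86400
  }, numeric(1))

  tibble::tibble(night_date = dates, noon_start = noon, nonwear_frac = frac,
                 valid = frac <= config$night_invalid_frac)
}

#' Interpolate implausibly low temperature readings
#'
#' Readings below `low_temp_c` (default 24 deg C; wrist skin temperature
#' cannot plausibly be that low while the device is worn) are replaced by
#' linear interpolation between the nearest flanking readings at or above
#' the threshold. Runs at the start or end of the series have no anchor on
#' one side and are left missing rather than extrapolated. Pre-existing
#' missing values are preserved. The operation is idempotent and never
#' produces a value below the threshold.
#'
#' @param temp Numeric vector of temperatures (deg C), may contain `NA`.
#' @param config A [wf_config()] list.
#' @return Numeric vector of the same length.
#' @export
impute_low_temperature <- function(temp, config = wf_config()) {
  thr <- config$low_temp_c
  low <- !is.na(temp) & temp < thr
  if (!any(low)) return(temp)
  anchor <- !is.na(temp) & temp >= thr
  if (sum(anchor) < 2) {
    warn("Fewer than two readings at or above the low-temperature threshold; low run left missing.")
    temp[low] <- NA_real_
    return(temp)
  }
  idx <- seq_along(temp)
  filled <- approx(idx[anchor], temp[anchor], xout = idx[low],
                   method = "linear", rule = 1)$y
  temp[low] <- filled  # NA outside the anchored span (leading/trailing runs)
  temp
}

#' Average temperature into quarter-hour bins
#'
#' Bins are anchored to clock quarter hours (:00/:15/:30/:45). Each bin gets
#' the mean of the epoch temperatures falling in it; bins with no data are
#' missing. The full regular grid from the first to the last occupied bin is
#' returned so downstream window extraction can index by clock time.
#'
#' @param times POSIXct epoch timestamps.
#' @param temp Temperatures at those epochs (post low-temperature handling).
#' @return A tibble `bin_start, temp, n` on a regular 15-min grid.
#' @export
average_temp_15min <- function(times, temp) {
  tz <- attr(times, "tzone")
  t_num <- as.numeric(times)
  bin <- floor(t_num / 900) * 900
  grid <- seq(min(bin), max(bin), by = 900)
  idx <- as.integer((bin - grid[1]) / 900) + 1L
  sums <- rowsum(ifelse(is.na(temp), 0, temp), idx)
  ns <- rowsum((!is.na(temp)) + 0, idx)
  pos <- as.integer(rownames(sums))
  val <- rep(NA_real_, length(grid)); cnt <- integer(length(grid))
  cnt[pos] <- as.integer(ns)
  val[pos] <- ifelse(ns > 0, sums / ns, NA_real_)
  tibble::tibble(
    bin_start = as.POSIXct(grid, origin = "1970-01-01", tz = tz),
    temp = val, n = cnt
  )
}

#' Centred moving average with clipped windows
#'
#' Smooths a series with a simple moving average of nominal window length
#' `2q + 1` points. At the series edges the window is clipped to the
#' available points (a partial-window mean), so the output has the same
#' length as the input; with `q = 0` the series is returned unchanged.
#' Missing values are ignored within each window; positions whose window
#' holds no data stay missing.
#'
#' @param x Numeric vector.
#' @param q Half-width in points; default 3 (a 7-point window at 15-min
#'   resolution, i.e. 1.75 h).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, q = 3) {
  n <- length(x)
  if (q == 0 || n == 1) return(x)
  val <- ifelse(is.na(x), 0, x)
  cs <- c(0, cumsum(val))
  cn <- c(0, cumsum(!is.na(x)))
  i <- seq_len(n)
  lo <- pmax(i - q, 1L); hi <- pmin(i + q, n)
  tot <- cs[hi + 1L] - cs[lo]
  cnt <- cn[hi + 1L] - cn[lo]
  out <- ifelse(cnt > 0, tot / cnt, NA_real_)
  out[is.na(x) & cnt == 0] <- NA_real_
  out
}
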