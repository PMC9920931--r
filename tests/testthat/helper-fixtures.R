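# Programmatic fixtures: recordings and cohorts built in code at test time.

fix_tz <- "UTC"

# epoch recording with given channel generators; time from `start`,
# `hours` long at `epoch` seconds
make_recording <- function(hours = 24, epoch = 60,
                           start = as.POSIXct("2023-03-06 00:00:00", tz = fix_tz),
                           x = 0, y = 0, z = 1, temp = 33, light = 100,
                           subject_id = "S001", period_id = "p1") {
  n <- as.integer(hours * 3600 / epoch)
  times <- start + (seq_len(n) - 1L) * epoch
  rec <- tibble::tibble(
    subject_id = subject_id, period_id = period_id, time = times,
    x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n),
    temp = rep_len(temp, n), light = rep_len(light, n)
  )
  as_wf_recording(rec)
}

# "worn and moving": per-axis noise well above the stillness thresholds
active_axes <- function(n, sd_g = 0.12) {
  list(x = rnorm(n, 0, sd_g), y = rnorm(n, 0, sd_g), z = 1 + rnorm(n, 0, sd_g))
}

# quarter-hour grid tibble for window tests
make_qtemp <- function(hours = 48, temp = 33,
                       start = as.POSIXct("2023-03-06 00:00:00", tz = fix_tz)) {
  n <- as.integer(hours * 4) + 1L
  bins <- start + (seq_len(n) - 1L) * 900
  tibble::tibble(bin_start = bins, temp = rep_len(temp, n),
                 temp_raw = rep_len(temp, n), n = 15L)
}

# small default cohort for pipeline-level tests
small_cohort <- function(n_subjects = 8, days = 7, periods = 1, seed = 42, ...) {
  generate_cohort(cohort_spec(n_subjects = n_subjects,
                              periods_per_subject = periods,
                              days_per_period = days, seed = seed, ...))
}

sleep_window_at <- function(date, onset_h, dur_h, subject_id = "S001",
                            period_id = "p1", night = 1L) {
  onset <- as.POSIXct(paste(date, "00:00:00"), tz = fix_tz) + onset_h * 3600
  tibble::tibble(subject_id = subject_id, period_id = period_id,
                 night = night, onset = onset, offset = onset + dur_h * 3600)
}
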