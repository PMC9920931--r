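#' Read an epoch-level wrist-sensor recording
#'
#' Canonical on-disk dialect: a delimited text file with a named header and
#' columns `subject_id, period_id, time, x, y, z, temp` and optionally
#' `light`. `time` is ISO-8601; acceleration is in g, temperature in deg C,
#' light in lux. Timestamps must be strictly increasing with a fixed epoch
#' spacing; clock-time rules downstream (19:00 night window, noon-to-noon
#' nights, 08:00 day window) are evaluated in the civil time of `tz`.
#'
#' @param path File to read.
#' @param tz Time zone the timestamps are interpreted in. Default "UTC".
#' @return A tibble of class `wf_recording`, one row per epoch.
#' @export
read_recording <- function(path, tz = "UTC") {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "period_id", "time", "x", "y", "z", "temp")
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols) > 0) {
    abort(sprintf("Recording at '%s' lacks mandatory column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  dat$time <- as.POSIXct(dat$time, tz = tz)
  as_wf_recording(dat)
}

#' Validate and classify an in-memory recording
#'
#' @param dat Data frame with the recording columns (see [read_recording()]).
#' @return The data as a `wf_recording` tibble.
#' @export
as_wf_recording <- function(dat) {
  dat <- tibble::as_tibble(dat)
  if (anyNA(dat$time)) abort("Recording has unparseable timestamps.")
  dt <- diff(as.numeric(dat$time))
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1] + 1L
    abort(sprintf("Recording timestamps not strictly increasing at row %d.", bad))
  }
  if (length(unique(round(dt, 6))) > 1) {
    abort("Recording epoch spacing is not uniform.")
  }
  n <- nrow(dat)
  for (ch in c("x", "y", "z", "temp")) {
    if (length(dat[[ch]]) != n) abort(sprintf("Channel '%s' length mismatch.", ch))
  }
  class(dat) <- c("wf_recording", class(dat))
  dat
}

#' @rdname read_recording
#' @param recording A `wf_recording` tibble.
#' @export
write_recording <- function(recording, path) {
  out <- recording
  out$time <- format(out$time, "%Y-%m-%dT%H:%M:%S%z")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write per-night sleep windows
#'
#' Columns: `subject_id, period_id, night, onset, offset` with ISO-8601
#' instants. Each row is one detected sleep period (onset strictly before
#' offset, duration under 19 h).
#'
#' @param path File to read or write.
#' @param tz Time zone for parsing. Default "UTC".
#' @return A tibble, one row per night.
#' @export
read_sleep_windows <- function(path, tz = "UTC") {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "period_id", "night", "onset", "offset")
  if (!all(need %in% names(dat))) {
    abort(sprintf("Sleep-window file lacks column(s): %s",
                  paste(setdiff(need, names(dat)), collapse = ", ")))
  }
  dat$onset <- as.POSIXct(dat$onset, tz = tz)
  dat$offset <- as.POSIXct(dat$offset, tz = tz)
  validate_sleep_windows(dat)
}

validate_sleep_windows <- function(dat) {
  if (any(dat$offset <= dat$onset)) abort("Sleep window with offset <= onset.")
  dur_h <- as.numeric(dat$offset - dat$onset, units = "hours")
  if (any(dur_h >= 19)) abort("Sleep window of 19 h or longer is implausible.")
  tibble::as_tibble(dat)
}

#' @rdname read_sleep_windows
#' @param windows Sleep-window tibble.
#' @export
write_sleep_windows <- function(windows, path) {
  out <- windows
  out$onset <- format(out$onset, "%Y-%m-%dT%H:%M:%S%z")
  out$offset <- format(out$offset, "%Y-%m-%dT%H:%M:%S%z")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# questionnaire score ranges used for outcome validation
outcome_ranges <- list(
  mrs = c(0, 5), gad7 = c(0, 21), phq2 = c(0, 6),
  fq_ag = c(0, 40), fq_soc = c(0, 40), fq_sp = c(0, 40)
)

#' Read and write the outcome table
#'
#' Long format: one row per subject and timepoint (`baseline`, `after_p1`,
#' `after_p2`) with per-subject fields `sex`, `age`, `diagnosis` ("stroke" or
#' "tia") and questionnaire scores `mrs` (0-5), `gad7` (0-21), `phq2` (0-6),
#' `fq_ag`, `fq_soc`, `fq_sp` (0-40). PHQ-2 is administered only at baseline
#' and after the first wear period; values at `after_p2` must be missing.
#' Out-of-range scores are rejected, not coerced.
#'
#' @param path File to read or write.
#' @return A tibble of outcomes.
#' @export
read_outcomes <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_outcomes(dat)
}

#' @rdname read_outcomes
#' @param outcomes Outcome tibble.
#' @export
validate_outcomes <- function(outcomes) {
  dat <- tibble::as_tibble(outcomes)
  need <- c("subject_id", "timepoint", "sex", "age", "diagnosis",
            names(outcome_ranges))
  if (!all(need %in% names(dat))) {
    abort(sprintf("Outcome table lacks column(s): %s",
                  paste(setdiff(need, names(dat)), collapse = ", ")))
  }
  if (!all(dat$timepoint %in% c("baseline", "after_p1", "after_p2"))) {
    abort("`timepoint` must be baseline/after_p1/after_p2.")
  }
  if (!all(dat$diagnosis %in% c("stroke", "tia"))) {
    abort("`diagnosis` must be 'stroke' or 'tia'.")
  }
  for (q in names(outcome_ranges)) {
    rng <- outcome_ranges[[q]]
    v <- dat[[q]]
    bad <- !is.na(v) & (v < rng[1] | v > rng[2])
    if (any(bad)) {
      abort(sprintf("Outcome '%s' out of range [%g, %g] at row %d (value %g).",
                    q, rng[1], rng[2], which(bad)[1], v[which(bad)[1]]))
    }
  }
  if (any(!is.na(dat$phq2[dat$timepoint == "after_p2"]))) {
    abort("PHQ-2 is only recorded at baseline and after the first wear period.")
  }
  dat
}

#' @rdname read_outcomes
#' @export
write_outcomes <- function(outcomes, path) {
  readr::write_csv(outcomes, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read and write a feature table
#'
#' Wide format: one row per (subject, wear period) sample, keyed by
#' `subject_id` and `period_id`; remaining columns are named features. An
#' attribute `feature_groups` (named character vector: feature ->
#' "demographic"/"sleep"/"pa"/"novel") records the group of each column and
#' round-trips through a `# group:` comment line is avoided by writing a
#' sidecar column dictionary when requested.
#'
#' @param path File to read or write.
#' @return A feature tibble.
#' @export
read_feature_table <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  if (!all(c("subject_id", "period_id") %in% names(dat))) {
    abort("Feature table must have subject_id and period_id key columns.")
  }
  if (anyDuplicated(dat[c("subject_id", "period_id")]) > 0) {
    abort("Feature table has duplicate (subject_id, period_id) keys.")
  }
  tibble::as_tibble(dat)
}

#' @rdname read_feature_table
#' @param features Feature tibble.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path, na = "NA", progress = FALSE)
  invisible(path)
}
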