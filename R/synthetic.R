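# Synthetic multimodal cohort generator.
#
# Emulates the data regime the pipeline targets: multi-day epoch recordings
# of tri-axial acceleration (g), wrist temperature (deg C) and ambient
# light per subject and wear period, GGIR-style per-night sleep variables,
# questionnaire outcomes at three timepoints, and a truth table of every
# planted parameter. All distributions are artifact choices (no public
# per-signal description of such cohorts exists); they are the simplest
# forms that exhibit every pattern the features measure.

#' Specification of a synthetic cohort
#'
#' Defaults describe a stroke/TIA-like cohort: 25 subjects over two wear
#' periods of 14 days at 60-s epochs, 60% in the "stroke" group. Group
#' contrasts are planted in the between-night variability of the nightly
#' mean wrist temperature (`temp_sd_of_mean`, deg C; stroke lower) and in
#' the irregularity of the temperature signal (`temp_apen_scale`; stroke
#' higher), with directions following the clinical literature on circadian
#' temperature rhythms after stroke.
#'
#' @param n_subjects Number of subjects.
#' @param periods_per_subject Wear periods per subject (1 or 2).
#' @param days_per_period Nights per wear period (>= 7 so fixtures survive
#'   the valid-day rule).
#' @param epoch_seconds Epoch length of the synthetic series (default 60 s;
#'   every downstream computation operates at epoch or 15-min scale, so raw
#'   high-frequency simulation would add cost without exercising anything).
#' @param group_fraction Fraction of subjects in the "stroke" group.
#' @param temp_sd_of_mean Named per-group sd (deg C) of the planted nightly
#'   mean temperatures.
#' @param temp_sd_jitter Lognormal sd of the per-subject multiplier on the
#'   group temperature-variability level (individual heterogeneity).
#' @param temp_apen_scale Named per-group multiplier on the temperature
#'   noise level (drives approximate entropy).
#' @param base_temp_mean,base_temp_sd Between-subject distribution of the
#'   wrist temperature baseline (deg C).
#' @param circ_amp Amplitude (deg C) of the 24-h circadian component.
#' @param circ_peak_h Clock hour of the circadian temperature peak (distal
#'   skin temperature peaks at night).
#' @param noise_sd Stationary sd (deg C) of the AR(1) temperature noise.
#' @param ar_phi AR(1) coefficient of the temperature noise.
#' @param sleep_onset_mean,sleep_onset_sd Clock hour (h) and spread of sleep
#'   onset; values above 24 denote past-midnight onsets.
#' @param sleep_dur_mean,sleep_dur_sd Sleep duration (h) and nightly spread.
#' @param we_extra_hours Planted extra weekend sleep (h).
#' @param trend_slope_sd Between-subject sd of the per-night drift of sleep
#'   duration (h/night); other sleep variables drift proportionally via a
#'   shared latent "recovery" factor.
#' @param nonwear_rate Expected non-wear episodes per day.
#' @param nonwear_dur_min Mean episode duration (minutes).
#' @param outcome_effect Linear coupling strength of planted features to
#'   questionnaire scores (0 decouples them).
#' @param ambient_c Ambient temperature toward which the sensor decays when
#'   off wrist.
#' @param awake_sd_g,asleep_sd_g Per-axis acceleration noise sd (g) while
#'   awake and asleep. Asleep movement stays above the stillness thresholds
#'   so genuine sleep is not mistaken for non-wear.
#' @param tz Time zone of the cohort (fixed-offset zones only).
#' @param start_date First recording day of period 1 (a Monday by default).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec including this seed.
#' @return A validated list of class `wf_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 25,
                        periods_per_subject = 2,
                        days_per_period = 14,
                        epoch_seconds = 60,
                        group_fraction = 0.6,
                        temp_sd_of_mean = c(stroke = 0.725, tia = 0.820),
                        temp_sd_jitter = 0.10,
                        temp_apen_scale = c(stroke = 1.3, tia = 1.0),
                        base_temp_mean = 33.5,
                        base_temp_sd = 0.4,
                        circ_amp = 1.0,
                        circ_peak_h = 4,
                        noise_sd = 0.15,
                        ar_phi = 0.8,
                        sleep_onset_mean = 23,
                        sleep_onset_sd = 0.75,
                        sleep_dur_mean = 7.5,
                        sleep_dur_sd = 0.75,
                        we_extra_hours = 0.5,
                        trend_slope_sd = 0.03,
                        nonwear_rate = 0.5,
                        nonwear_dur_min = 90,
                        outcome_effect = 1,
                        ambient_c = 21,
                        awake_sd_g = 0.12,
                        asleep_sd_g = 0.02,
                        tz = "UTC",
                        start_date = as.Date("2023-03-06"),
                        seed = 1L) {
  spec <- as.list(environment())
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid cohort spec field `%s`: %s", field, msg))
  }
  chk(n_subjects >= 1, "n_subjects", "must be a positive count")
  chk(periods_per_subject %in% 1:2, "periods_per_subject", "must be 1 or 2")
  chk(days_per_period >= 7, "days_per_period",
      "must be at least 7 (valid-day rule)")
  chk(epoch_seconds > 0, "epoch_seconds", "must be positive")
  chk(group_fraction >= 0 && group_fraction <= 1, "group_fraction",
      "must lie in [0, 1]")
  chk(all(c("stroke", "tia") %in% names(temp_sd_of_mean)),
      "temp_sd_of_mean", "needs named entries 'stroke' and 'tia'")
  chk(all(temp_sd_of_mean > 0), "temp_sd_of_mean", "must be positive")
  chk(all(c("stroke", "tia") %in% names(temp_apen_scale)),
      "temp_apen_scale", "needs named entries 'stroke' and 'tia'")
  chk(nonwear_rate >= 0, "nonwear_rate", "must be non-negative")
  chk(sleep_dur_mean > 0, "sleep_dur_mean", "must be positive")
  structure(spec, class = "wf_cohort_spec")
}

#' Calibrate the planted group contrast to a standardized gap
#'
#' Sets the two group levels of `temp_sd_of_mean` so that the expected
#' between-group difference of the extracted "sd of nightly mean
#' temperature" feature equals `gap` pooled within-group standard
#' deviations. The pooled sd combines the sampling noise of an sd estimate
#' from `days_per_period` nights (`sigma / sqrt(2(n-1))`) with the
#' per-subject lognormal heterogeneity `temp_sd_jitter`.
#'
#' @param spec A [cohort_spec()].
#' @param gap Desired standardized between-group gap.
#' @param center Geometric centre of the two levels (deg C).
#' @return The spec with `temp_sd_of_mean` replaced.
#' @export
calibrate_group_gap <- function(spec, gap, center = 0.7) {
  n <- spec$days_per_period
  rel_sd <- sqrt(spec$temp_sd_jitter^2 + 1 / (2 * (n - 1)))
  delta <- gap * rel_sd
  spec$temp_sd_of_mean <- c(stroke = center * (1 - delta / 2),
                            tia = center * (1 + delta / 2))
  spec
}

#' Generate a synthetic cohort
#'
#' Produces, deterministically for a given spec (including its seed):
#' epoch-level recordings per subject-period, sleep windows, GGIR-style
#' per-night sleep variables, an outcome table whose scores are linear
#' functions of the planted features plus noise, and a truth table of every
#' planted parameter.
#'
#' Planted structure: a 24-h circadian temperature cycle; during each sleep
#' window the temperature is shifted so the night mean equals a planted
#' nightly mean drawn with the group's between-night variability; AR(1)
#' noise scaled by the group irregularity multiplier; accelerometer
#' quiescence (but not stillness) during sleep; non-wear episodes with
#' frozen acceleration and exponential temperature decay toward ambient,
#' exercising both the stillness rule and the low-temperature rule.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `wf_cohort`: `recordings` (named list of
#'   `wf_recording`), `sleep_windows`, `night_vars`, `outcomes`, `truth`,
#'   and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "wf_cohort_spec"))
  set.seed(spec$seed)

  n <- spec$n_subjects
  n_stroke <- round(n * spec$group_fraction)
  group <- sample(c(rep("stroke", n_stroke), rep("tia", n - n_stroke)))
  subj_ids <- sprintf("S%03d", seq_len(n))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(pmin(pmax(stats::rnorm(n, 64, 10), 39), 85))

  recordings <- list()
  sw_all <- list(); nv_all <- list(); truth_rows <- list()

  # per-subject latent parameters shared across periods
  base_temp <- stats::rnorm(n, spec$base_temp_mean, spec$base_temp_sd)
  onset_mean_s <- stats::rnorm(n, spec$sleep_onset_mean, 0.5)
  dur_mean_s <- stats::rnorm(n, spec$sleep_dur_mean, 0.35)
  sigma_jit <- stats::rnorm(n, 0, 1)          # z-scored heterogeneity
  sigma_subj <- spec$temp_sd_of_mean[group] *
    exp(spec$temp_sd_jitter * sigma_jit)

  z_slope <- matrix(NA_real_, n, spec$periods_per_subject)

  for (s in seq_len(n)) {
    for (p in seq_len(spec$periods_per_subject)) {
      period_id <- paste0("p", p)
      start <- spec$start_date + (p - 1) * 42
      b <- stats::rnorm(1)                    # latent recovery factor
      z_slope[s, p] <- b
      slope_dur <- b * spec$trend_slope_sd
      params <- list(
        subject_id = subj_ids[s], period_id = period_id,
        tz = spec$tz, start_date = start,
        days = spec$days_per_period, epoch_seconds = spec$epoch_seconds,
        base_temp = base_temp[s], circ_amp = spec$circ_amp,
        circ_peak_h = spec$circ_peak_h,
        noise_sd = spec$noise_sd * spec$temp_apen_scale[[group[s]]],
        ar_phi = spec$ar_phi, ambient_c = spec$ambient_c,
        awake_sd_g = spec$awake_sd_g, asleep_sd_g = spec$asleep_sd_g
      )

      mid <- (spec$days_per_period + 1) / 2
      days_i <- seq_len(spec$days_per_period)
      night_date <- start + days_i - 1
      weekend <- format(night_date + 1, "%u") %in% c("6", "7")
      onset_h <- pmin(pmax(
        onset_mean_s[s] + stats::rnorm(spec$days_per_period, 0, spec$sleep_onset_sd),
        19.25), 26)
      dur <- dur_mean_s[s] + slope_dur * (days_i - mid) +
        spec$we_extra_hours * weekend +
        stats::rnorm(spec$days_per_period, 0, spec$sleep_dur_sd)
      dur <- pmin(pmax(dur, 4), 10.5)
      dur <- pmin(dur, 37.5 - onset_h)   # offset no later than 13:30 next day
      day0 <- as.POSIXct(paste(night_date, "00:00:00"), tz = spec$tz)
      onset <- day0 + onset_h * 3600
      offset <- onset + dur * 3600
      nightly_mean <- stats::rnorm(spec$days_per_period,
                                   base_temp[s] + 0.8, sigma_subj[s])

      # correlated drifts of the other sleep variables
      slope_np <- b * 0.06 + stats::rnorm(1, 0, 0.02)
      slope_eff <- b * 0.004
      slope_sibd <- -b * 0.03 + stats::rnorm(1, 0, 0.01)
      n_periods_night <- pmax(1, round(2 + slope_np * (days_i - mid) +
                                         stats::rnorm(spec$days_per_period, 0, 0.8)))
      sleep_eff <- pmin(pmax(0.88 + slope_eff * (days_i - mid) +
                               stats::rnorm(spec$days_per_period, 0, 0.03), 0.5), 1)
      sibd_h <- pmin(pmax(1.5 + slope_sibd * (days_i - mid) +
                            stats::rnorm(spec$days_per_period, 0, 0.4), 0), 6)

      n_nw <- stats::rpois(1, spec$nonwear_rate * spec$days_per_period)
      nonwear <- if (n_nw > 0) {
        nw_day <- sample(days_i, n_nw, replace = TRUE)
        nw_start <- as.POSIXct(paste(start + nw_day - 1, "00:00:00"),
                               tz = spec$tz) + stats::runif(n_nw, 9, 17) * 3600
        nw_dur <- pmin(pmax(stats::rexp(n_nw, 1 / spec$nonwear_dur_min), 20), 180)
        tibble::tibble(start = nw_start, end = nw_start + nw_dur * 60)[
          order(nw_start), ]
      } else {
        tibble::tibble(start = day0[0], end = day0[0])
      }

      sw <- tibble::tibble(subject_id = subj_ids[s], period_id = period_id,
                           night = days_i, onset = onset, offset = offset)
      params$sleep_windows <- sw
      params$nightly_mean <- nightly_mean
      params$nonwear <- nonwear

      recordings[[paste(subj_ids[s], period_id, sep = "_")]] <-
        generate_recording(params)
      sw_all[[length(sw_all) + 1]] <- sw
      nv_all[[length(nv_all) + 1]] <- tibble::tibble(
        subject_id = subj_ids[s], period_id = period_id, night = days_i,
        onset = onset, offset = offset, spt_h = dur, sibd_h = sibd_h,
        n_sleep_periods = n_periods_night, sleep_eff = sleep_eff
      )
      grp_s <- group[s]
      truth_rows[[length(truth_rows) + 1]] <- tibble::tibble(
        subject_id = subj_ids[s], period_id = period_id, group = grp_s,
        base_temp = base_temp[s], sigma_temp = unname(sigma_subj[s]),
        apen_scale = unname(spec$temp_apen_scale[[grp_s]]),
        slope_dur = slope_dur, mean_dur = dur_mean_s[s],
        n_nonwear = n_nw,
        nonwear_min = sum(as.numeric(nonwear$end - nonwear$start,
                                     units = "mins")),
        nightly_means = list(nightly_mean),
        nonwear_intervals = list(nonwear)
      )
    }
  }

  truth <- dplyr::bind_rows(truth_rows)
  outcomes <- generate_outcomes(spec, subj_ids, group, sex, age,
                                sigma_jit, z_slope)
  night_vars <- dplyr::bind_rows(nv_all)
  external <- build_external_features(night_vars, subj_ids)

  structure(list(
    recordings = recordings,
    sleep_windows = dplyr::bind_rows(sw_all),
    night_vars = night_vars,
    outcomes = outcomes,
    external_features = external,
    truth = truth,
    spec = spec
  ), class = "wf_cohort")
}

# questionnaire outcomes as linear functions of planted features plus noise:
#  * GAD-7 and FQ-specific decrease when the planted sleep-duration trend is
#    positive (more sleep over the period -> less anxiety/phobia);
#  * post-period mRS decreases with the subject's planted temperature
#    variability (higher variability -> more improvement);
#  * PHQ-2 exists only at baseline and after period 1.
generate_outcomes <- function(spec, subj_ids, group, sex, age,
                              sigma_jit, z_slope) {
  n <- length(subj_ids)
  e <- spec$outcome_effect
  clipr <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

  mrs_base <- ifelse(group == "stroke",
                     sample(0:4, n, replace = TRUE, prob = c(.20, .35, .25, .15, .05)),
                     sample(0:2, n, replace = TRUE, prob = c(.60, .30, .10)))
  gad_base <- clipr(stats::rnorm(n, 6, 3), 0, 21)
  phq_base <- clipr(stats::rnorm(n, 2, 1.2), 0, 6)
  fq_ag_base <- clipr(stats::rnorm(n, 10, 5), 0, 40)
  fq_soc_base <- clipr(stats::rnorm(n, 12, 5), 0, 40)
  fq_sp_base <- clipr(stats::rnorm(n, 14, 6), 0, 40)

  rows <- list()
  rows[[1]] <- tibble::tibble(
    subject_id = subj_ids, timepoint = "baseline", sex = sex, age = age,
    diagnosis = group, mrs = mrs_base, gad7 = gad_base, phq2 = phq_base,
    fq_ag = fq_ag_base, fq_soc = fq_soc_base, fq_sp = fq_sp_base
  )
  for (p in seq_len(spec$periods_per_subject)) {
    zs <- z_slope[, p]
    rows[[p + 1]] <- tibble::tibble(
      subject_id = subj_ids, timepoint = paste0("after_p", p),
      sex = sex, age = age, diagnosis = group,
      mrs = clipr(mrs_base - e * 0.8 * sigma_jit + stats::rnorm(n, 0, 0.5), 0, 5),
      gad7 = clipr(gad_base - e * 3 * zs + stats::rnorm(n, 0, 1.5), 0, 21),
      phq2 = if (p == 1) clipr(phq_base + stats::rnorm(n, 0, 0.8), 0, 6)
             else NA_real_,
      fq_ag = clipr(fq_ag_base + stats::rnorm(n, 0, 2), 0, 40),
      fq_soc = clipr(fq_soc_base + stats::rnorm(n, 0, 2), 0, 40),
      fq_sp = clipr(fq_sp_base - e * 4 * zs + stats::rnorm(n, 0, 2), 0, 40)
    )
  }
  validate_outcomes(dplyr::bind_rows(rows))
}

# GGIR-style external feature table: honest summaries of the provided
# per-night sleep variables plus synthetic physical-activity summaries from
# a per-subject activity level (no planted group contrast -- activity
# computation from raw signals is external territory and is only emulated
# here so the multi-group ensemble has realistic inputs)
build_external_features <- function(night_vars, subj_ids) {
  sleep_sum <- night_vars |>
    dplyr::group_by(.data$subject_id, .data$period_id) |>
    dplyr::summarise(
      ggir_spt_mean = mean(.data$spt_h),
      ggir_spt_sd = sd(.data$spt_h),
      ggir_eff_mean = mean(.data$sleep_eff),
      ggir_nper_mean = mean(.data$n_sleep_periods),
      ggir_sibd_mean = mean(.data$sibd_h),
      .groups = "drop"
    )
  act_level <- setNames(stats::rnorm(length(subj_ids), 30, 8), subj_ids)
  n <- nrow(sleep_sum)
  sleep_sum$pa_mean_enmo <- pmax(act_level[sleep_sum$subject_id] +
                                   stats::rnorm(n, 0, 3), 5)
  sleep_sum$pa_sd_enmo <- pmax(0.8 * sleep_sum$pa_mean_enmo +
                                 stats::rnorm(n, 0, 4), 2)
  sleep_sum$pa_m5 <- sleep_sum$pa_mean_enmo * stats::runif(n, 2.2, 3.0)
  sleep_sum$pa_l5 <- sleep_sum$pa_mean_enmo * stats::runif(n, 0.05, 0.15)
  sleep_sum$pa_mvpa_min <- pmax(2.5 * act_level[sleep_sum$subject_id] +
                                  stats::rnorm(n, 0, 12), 0)
  sleep_sum
}

#' Generate one epoch-level recording from planted parameters
#'
#' The temperature model is baseline + 24-h sinusoid + a night shift making
#' each sleep window's mean equal its planted nightly mean + AR(1) noise;
#' non-wear episodes freeze the accelerometer at its entry value and decay
#' the temperature exponentially toward ambient (time constant 12 min), so
#' one mechanism triggers both the stillness rule and the low-temperature
#' rule. The recording spans `days` full calendar days plus a 14-h tail so
#' the last night's sleep window is always covered; the tail day is too
#' short to pass the 16-h valid-day rule by construction.
#'
#' @param params List of planted parameters as assembled by
#'   [generate_cohort()] (`subject_id`, `period_id`, `tz`, `start_date`,
#'   `days`, `epoch_seconds`, `base_temp`, `circ_amp`, `circ_peak_h`,
#'   `noise_sd`, `ar_phi`, `ambient_c`, `awake_sd_g`, `asleep_sd_g`,
#'   `sleep_windows`, `nightly_mean`, `nonwear`).
#' @param seed Optional seed for standalone use; when `NULL` the current RNG
#'   stream is used (as inside [generate_cohort()]).
#' @return A `wf_recording` tibble.
#' @export
generate_recording <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- params
  tz <- pr$tz
  t0 <- as.POSIXct(paste(pr$start_date, "00:00:00"), tz = tz)
  n_epochs <- as.integer((pr$days * 86400 + 14 * 3600) / pr$epoch_seconds)
  t_num <- as.numeric(t0) + (seq_len(n_epochs) - 1L) * pr$epoch_seconds
  times <- as.POSIXct(t_num, origin = "1970-01-01", tz = tz)
  h <- ((t_num - as.numeric(t0)) / 3600) %% 24

  temp <- pr$base_temp - 0.8 +
    pr$circ_amp * cos(2 * pi * (h - pr$circ_peak_h) / 24)

  asleep <- rep(FALSE, n_epochs)
  sw <- pr$sleep_windows
  for (i in seq_len(nrow(sw))) {
    mask <- t_num >= as.numeric(sw$onset[i]) & t_num < as.numeric(sw$offset[i])
    asleep[mask] <- TRUE
    if (any(mask)) temp[mask] <- temp[mask] + (pr$nightly_mean[i] - mean(temp[mask]))
  }

  if (pr$noise_sd > 0) {
    eps <- stats::rnorm(n_epochs, 0, pr$noise_sd * sqrt(1 - pr$ar_phi^2))
    temp <- temp + as.numeric(stats::filter(eps, pr$ar_phi, method = "recursive"))
  }

  sd_axis <- ifelse(asleep, pr$asleep_sd_g, pr$awake_sd_g)
  x <- stats::rnorm(n_epochs, 0, sd_axis)
  y <- stats::rnorm(n_epochs, 0, sd_axis)
  z <- 1 + stats::rnorm(n_epochs, 0, sd_axis)
  light <- ifelse(h >= 8 & h < 20, 400, 2) + abs(stats::rnorm(n_epochs, 0, 20))

  nw <- pr$nonwear
  for (i in seq_len(nrow(nw))) {
    idx <- which(t_num >= as.numeric(nw$start[i]) & t_num < as.numeric(nw$end[i]))
    if (length(idx) == 0) next
    entry <- max(idx[1] - 1L, 1L)
    t_rel <- t_num[idx] - t_num[idx[1]]
    temp[idx] <- pr$ambient_c + (temp[entry] - pr$ambient_c) * exp(-t_rel / 720)
    x[idx] <- x[entry]; y[idx] <- y[entry]; z[idx] <- z[entry]
  }

  temp <- pmin(pmax(temp, 15), 40)
  as_wf_recording(tibble::tibble(
    subject_id = pr$subject_id, period_id = pr$period_id,
    time = times, x = x, y = y, z = z, temp = temp, light = light
  ))
}

#' Write a synthetic cohort to delimited files
#'
#' Emits the same formats the readers consume (`recordings/<id>.csv`,
#' `sleep_windows.csv`, `night_vars.csv`, `outcomes.csv`) plus
#' `truth.csv`, one row per subject-period with the planted scalar
#' parameters, for test assertions.
#'
#' @param cohort A `wf_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$recordings)) {
    write_recording(cohort$recordings[[nm]],
                    file.path(dir, "recordings", paste0(nm, ".csv")))
  }
  write_sleep_windows(cohort$sleep_windows, file.path(dir, "sleep_windows.csv"))
  nv <- cohort$night_vars
  nv$onset <- format(nv$onset, "%Y-%m-%dT%H:%M:%S%z")
  nv$offset <- format(nv$offset, "%Y-%m-%dT%H:%M:%S%z")
  readr::write_csv(nv, file.path(dir, "night_vars.csv"), progress = FALSE)
  write_outcomes(cohort$outcomes, file.path(dir, "outcomes.csv"))
  truth <- dplyr::select(cohort$truth, -"nightly_means", -"nonwear_intervals")
  readr::write_csv(truth, file.path(dir, "truth.csv"), progress = FALSE)
  invisible(dir)
}

#' @export
print.wf_cohort <- function(x, ...) {
  cat(sprintf("<wf_cohort> %d subjects x %d period(s), %d days/period, %d recordings\n",
              x$spec$n_subjects, x$spec$periods_per_subject,
              x$spec$days_per_period, length(x$recordings)))
  invisible(x)
}
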