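test_that("a constant night has zero variability, rates and entropy", {
  s <- summarize_night(rep(34, 33))
  expect_equal(s$t_sd, 0)
  expect_equal(s$t_iqr, 0)
  expect_equal(s$mroi, 0)
  expect_equal(s$mrod, 0)
  expect_equal(s$apen_night, 0)
})

test_that("a single step yields the step as MROI at the interval end", {
  # +0.5 step between the 4th and 5th bins; elsewhere flat
  series <- c(rep(33, 4), rep(33.5, 29))
  s <- summarize_night(series)
  expect_equal(s$mroi, 0.5)
  # interval 4 -> 5 ends at bin 5, one hour after onset (bin 1 = onset = 0 h)
  expect_equal(s$t_mroi, 1)
  expect_equal(s$mrod, 0)   # no decrease anywhere

  # V-shaped series with its minimum at onset
  v <- c(seq(33, 34, length.out = 17), seq(34, 33.9, length.out = 16))
  expect_equal(summarize_night(v)$t_min_rel, 0)
})

test_that("nightly aggregation reproduces closed-form values", {
  mk_night <- function(level) rep(level, 33)
  nights <- tibble::tibble(
    night_date = as.Date("2023-03-06") + 0:1,
    valid = TRUE,
    series = list(mk_night(34), mk_night(35))
  )
  days <- tibble::tibble(day_date = as.Date("2023-03-06"), valid = FALSE,
                         series = list(NULL))
  feats <- aggregate_period(nights, days, swd = c(NA, NA))
  expect_equal(feats$temp_mean_sd, sd(c(34, 35)))
  expect_equal(feats$temp_mean_sd, 0.707, tolerance = 1e-3)
  expect_equal(feats$temp_sd_mean, 0)
  expect_equal(feats$temp_iqr_sd, 0)
  # all nights identical: every sd-type feature 0
  nights2 <- nights; nights2$series <- list(mk_night(34), mk_night(34))
  feats2 <- aggregate_period(nights2, days, swd = c(NA, NA))
  sd_cols <- setdiff(grep("_sd$", temp_feature_names(), value = TRUE),
                     c("time_day_min_sd", "time_day_max_sd"))  # no valid days here
  for (col in sd_cols) expect_equal(feats2[[col]], 0, label = col)
})

test_that("the all-nights entropy equals the oracle on the concatenation", {
  n1 <- rep(33, 20); n2 <- rep(35, 24)
  nights <- tibble::tibble(night_date = as.Date("2023-03-06") + 0:1,
                           valid = TRUE, series = list(n1, n2))
  days <- tibble::tibble(day_date = as.Date("2023-03-06"), valid = FALSE,
                         series = list(NULL))
  feats <- aggregate_period(nights, days, swd = c(NA, NA))
  concat <- c(n1, n2)
  want <- apen_oracle(concat, 2, 0.2 * sd(concat)) / length(concat)
  expect_equal(feats$apen_sleep_all_nights, want, tolerance = 1e-12)
})

test_that("sleep-wake 48-h difference matches a two-mean oracle", {
  q <- make_qtemp(hours = 48)
  sw <- sleep_window_at("2023-03-06", onset_h = 23, dur_h = 8)
  in_sleep <- q$bin_start >= sw$onset & q$bin_start <= sw$offset
  q$temp[in_sleep] <- 35
  q$temp[!in_sleep] <- 33
  expect_equal(sleep_wake_diff_48h(q, sw), 2.0)

  q$temp <- 33.3
  expect_equal(sleep_wake_diff_48h(q, sw), 0)

  # randomized fixture against an independent masking computation
  set.seed(21)
  q$temp <- rnorm(nrow(q), 33, 1)
  got <- sleep_wake_diff_48h(q, sw)
  span <- q$bin_start >= as.POSIXct("2023-03-06 00:00:00", tz = fix_tz) &
    q$bin_start < as.POSIXct("2023-03-08 00:00:00", tz = fix_tz)
  want <- mean(q$temp[span & in_sleep]) - mean(q$temp[span & !in_sleep])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the canonical temperature feature set has exactly 19 members", {
  expect_length(temp_feature_names("canonical"), 19)
  nights <- tibble::tibble(night_date = as.Date("2023-03-06") + 0:2,
                           valid = TRUE,
                           series = list(rnorm(33) + 33, rnorm(33) + 33,
                                         rnorm(33) + 34))
  days <- tibble::tibble(day_date = as.Date("2023-03-06") + 0:1, valid = TRUE,
                         series = list(rnorm(97) + 33, rnorm(97) + 33))
  feats <- aggregate_period(nights, days, swd = c(1, 0.5, 0.8))
  expect_named(feats, temp_feature_names("canonical"))
  ext <- aggregate_period(nights, days, swd = c(1, 0.5, 0.8), extended = TRUE)
  expect_true(all(temp_feature_names("extended") %in% names(ext)))
})

test_that("adding a constant to every temperature leaves all features unchanged", {
  # variability, timing and entropy features are shift invariant by design,
  # and the sleep-wake contrast subtracts two shifted means
  set.seed(31)
  mk <- function(shift) {
    nights <- tibble::tibble(
      night_date = as.Date("2023-03-06") + 0:2, valid = TRUE,
      series = lapply(1:3, function(i) {
        set.seed(100 + i); rnorm(33, 33 + 0.3 * i, 0.4) + shift
      })
    )
    days <- tibble::tibble(
      day_date = as.Date("2023-03-06") + 0:1, valid = TRUE,
      series = lapply(1:2, function(i) {
        set.seed(200 + i); rnorm(97, 33, 0.8) + shift
      })
    )
    aggregate_period(nights, days, swd = c(1.2, 0.9, 1.1))
  }
  base <- mk(0); shifted <- mk(2.5)
  for (col in temp_feature_names()) {
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-9, label = col)
  }
})
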