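test_that("ENMONZ is zero at rest and clips negative norms", {
  rec <- make_recording(hours = 1)
  cases <- list(
    list(x = 0, y = 0, z = 1, want = 0),       # at rest: norm equals gravity
    list(x = 0, y = 0, z = 0.9, want = 0),     # sub-gravity noise clipped
    list(x = 0.6, y = 0, z = 0.8, want = 0),   # 3-4-5 norm exactly 1 g
    list(x = 0, y = 1.05, z = 0, want = 50)    # 50 mg above gravity
  )
  for (cs in cases) {
    rec$x <- cs$x; rec$y <- cs$y; rec$z <- cs$z
    expect_equal(compute_enmonz(rec)$enmonz, rep(cs$want, nrow(rec)),
                 tolerance = 1e-9)
  }
})

test_that("stillness on at least two axes flags non-wear, movement does not", {
  set.seed(5)
  n <- 4 * 60  # 4 h at 60 s
  rec <- make_recording(hours = 4)

  # still on all three axes (sd ~5 mg)
  rec_still <- rec
  rec_still$x <- rnorm(n, 0, 0.005); rec_still$y <- rnorm(n, 0, 0.005)
  rec_still$z <- 1 + rnorm(n, 0, 0.005)
  nw <- detect_nonwear(rec_still)
  expect_gt(nrow(nw), 0)
  # interior of the recording is covered by flagged blocks
  mid <- rec$time[n / 2]
  expect_true(any(nw$start <= mid & nw$end > mid))

  # vigorous on all axes: sd ~100 mg, range far above 50 mg
  rec_act <- rec
  ax <- active_axes(n, sd_g = 0.1)
  rec_act$x <- ax$x; rec_act$y <- ax$y; rec_act$z <- ax$z
  expect_equal(nrow(detect_nonwear(rec_act)), 0)

  # still on exactly two axes is enough ("at least two of the three")
  rec_two <- rec
  rec_two$x <- rnorm(n, 0, 0.005)
  rec_two$y <- rnorm(n, 0, 0.005)
  rec_two$z <- 1 + rnorm(n, 0, 0.1)  # third axis moving
  nw2 <- detect_nonwear(rec_two)
  expect_gt(nrow(nw2), 0)
})

test_that("non-wear detection is invariant to a constant axis offset", {
  set.seed(6)
  n <- 3 * 60
  rec <- make_recording(hours = 3)
  rec$x <- rnorm(n, 0, 0.004); rec$y <- rnorm(n, 0, 0.004)
  rec$z <- 1 + rnorm(n, 0, 0.004)
  nw_a <- detect_nonwear(rec)
  rec$x <- rec$x + 0.3; rec$y <- rec$y - 0.2; rec$z <- rec$z + 0.5
  nw_b <- detect_nonwear(rec)
  expect_equal(nw_a$start, nw_b$start)
  expect_equal(nw_a$end, nw_b$end)
})

test_that("short recordings yield no non-wear classification, with a warning", {
  rec <- make_recording(hours = 0.5)
  expect_warning(nw <- detect_nonwear(rec), "shorter")
  expect_equal(nrow(nw), 0)
})

test_that("valid days need 16 h of wear and periods need 7 valid days", {
  set.seed(8)
  # 3 full days of movement, non-wear planted by frozen axes
  rec <- make_recording(hours = 72)
  n <- nrow(rec)
  ax <- active_axes(n)
  rec$x <- ax$x; rec$y <- ax$y; rec$z <- ax$z

  freeze <- function(rec, from_h, to_h) {
    i <- which(as.numeric(rec$time - rec$time[1], units = "hours") >= from_h &
                 as.numeric(rec$time - rec$time[1], units = "hours") < to_h)
    rec$x[i] <- 0.1; rec$y[i] <- 0.02; rec$z[i] <- 0.95
    rec
  }
  # day 1: 7 h non-wear -> 17 h wear -> valid (inclusive rule)
  rec <- freeze(rec, 2, 9)
  # day 2: 14 h non-wear -> 10 h wear -> invalid
  rec <- freeze(rec, 26, 40)
  nw <- detect_nonwear(rec)
  vd <- filter_valid_days(rec, nw)
  expect_equal(vd$valid, c(TRUE, FALSE, TRUE))
  expect_equal(vd$wear_hours[1], 17, tolerance = 0.6)
  # 2 valid days of 3: far below the 7-day rule
  expect_false(attr(vd, "usable_period"))
})

test_that("non-wear epochs are imputed from same-clock-time donors", {
  act <- tibble::tibble(
    time = seq(as.POSIXct("2023-03-06 00:00:00", tz = "UTC"), by = 3600,
               length.out = 72),
    enmonz = rep(c(10, 20, 30), each = 24)
  )
  # non-wear at 03:00 on day 3
  nonwear <- tibble::tibble(
    start = as.POSIXct("2023-03-08 03:00:00", tz = "UTC"),
    end = as.POSIXct("2023-03-08 04:00:00", tz = "UTC")
  )
  vd <- tibble::tibble(day = as.Date(c("2023-03-06", "2023-03-07", "2023-03-08")),
                       wear_hours = 24, valid = TRUE)
  out <- impute_nonwear_epochs(act, nonwear, vd)
  i <- which(format(act$time, "%Y-%m-%d %H") == "2023-03-08 03")
  expect_equal(out$enmonz[i], 15)  # donors 10 and 20
  expect_true(out$imputed[i])
  # all other epochs untouched
  expect_equal(out$enmonz[-i], act$enmonz[-i])

  # no donors anywhere: value left missing
  nonwear_all <- tibble::tibble(
    start = as.POSIXct(paste(as.Date(c("2023-03-06", "2023-03-07", "2023-03-08")),
                             "05:00:00"), tz = "UTC"),
    end = as.POSIXct(paste(as.Date(c("2023-03-06", "2023-03-07", "2023-03-08")),
                           "06:00:00"), tz = "UTC")
  )
  out2 <- impute_nonwear_epochs(act, nonwear_all, vd)
  j <- which(format(act$time, "%H") == "05")
  expect_true(all(is.na(out2$enmonz[j])))

  # zero non-wear: identity
  none <- nonwear[0, ]
  out3 <- impute_nonwear_epochs(act, none, vd)
  expect_equal(out3$enmonz, act$enmonz)
})

test_that("noon-to-noon nights tolerate at most 10% non-wear", {
  rec <- make_recording(hours = 72)
  mk_nw <- function(hours) tibble::tibble(
    start = as.POSIXct("2023-03-06 14:00:00", tz = "UTC"),
    end = as.POSIXct("2023-03-06 14:00:00", tz = "UTC") + hours * 3600
  )
  vn <- validate_nights(rec, mk_nw(2.4))   # exactly 10%
  expect_true(vn$valid[vn$night_date == as.Date("2023-03-06")])
  vn <- validate_nights(rec, mk_nw(3))     # 12.5%
  expect_false(vn$valid[vn$night_date == as.Date("2023-03-06")])
  vn <- validate_nights(rec, mk_nw(0)[0, ])
  expect_true(all(vn$valid))
})

test_that("sub-24 degree readings are linearly interpolated between anchors", {
  expect_equal(impute_low_temperature(c(30, 20, 32)), c(30, 31, 32))
  expect_equal(impute_low_temperature(c(30, 20, 20, 30)), c(30, 30, 30, 30))
  # leading run has no left anchor: left missing
  out <- impute_low_temperature(c(20, 21, 30, 32))
  expect_true(all(is.na(out[1:2])))
  expect_equal(out[3:4], c(30, 32))
})

test_that("low-temperature imputation is idempotent and never emits < 24", {
  set.seed(9)
  for (i in 1:20) {
    x <- runif(50, 18, 36)
    once <- impute_low_temperature(x)
    expect_true(all(is.na(once) | once >= 24))
    expect_equal(impute_low_temperature(once), once)
  }
  # an entirely sub-threshold series is all-missing, with a warning
  expect_warning(all_low <- impute_low_temperature(rep(20, 10)), "threshold")
  expect_true(all(is.na(all_low)))
})

test_that("quarter-hour averaging bins correctly and flags empty bins", {
  times <- seq(as.POSIXct("2023-03-06 00:00:00", tz = "UTC"), by = 60,
               length.out = 60)
  q <- average_temp_15min(times, rep(33, 60))
  expect_equal(q$temp, rep(33, 4))

  # one bin containing two readings 32 and 34
  t2 <- as.POSIXct(c("2023-03-06 00:02:00", "2023-03-06 00:11:00",
                     "2023-03-06 00:31:00"), tz = "UTC")
  q2 <- average_temp_15min(t2, c(32, 34, 30))
  expect_equal(q2$temp[1], 33)
  expect_true(is.na(q2$temp[2]))  # 00:15 bin has no data
  expect_equal(q2$temp[3], 30)
})

test_that("moving average uses clipped windows and preserves structure", {
  expect_equal(moving_average(rep(5, 10), 3), rep(5, 10))
  # symmetric window on linear data leaves interior points unchanged
  ramp <- seq(1, 20)
  sm <- moving_average(ramp, 3)
  expect_equal(sm[4:17], ramp[4:17])
  expect_equal(moving_average(c(0, 0, 7, 0, 0), 1), c(0, 7 / 3, 7 / 3, 7 / 3, 0))
  # q = 0 is the identity, so the global mean is preserved exactly
  set.seed(2)
  x <- rnorm(40)
  expect_identical(moving_average(x, 0), x)
})
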