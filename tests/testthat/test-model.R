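make_cv_data <- function(n_subj = 12, sep = 3, seed = 1) {
  set.seed(seed)
  subj <- sprintf("S%02d", seq_len(n_subj))
  y <- rep(0:1, length.out = n_subj)
  x <- tibble::tibble(
    good = y * sep + rnorm(n_subj, 0, 0.5),
    noise1 = rnorm(n_subj),
    noise2 = rnorm(n_subj)
  )
  list(x = x, y = y, subj = subj)
}

test_that("within-subject imputation fills from the other period then prunes", {
  ft <- tibble::tibble(
    subject_id = rep(c("S001", "S002", "S003"), each = 2),
    period_id = rep(c("p1", "p2"), 3),
    a = c(NA, 2, 4, 4, 5, 6),        # S001 p1 missing, donor in p2
    b = c(1, 1, NA, NA, 2, 2),       # S002 has no donor in either period
    we_wd_diff = c(0.5, 0.4, NA, NA, 0.2, 0.1),
    trend_spt_dur = c(0.1, 0.2, NA, NA, 0.3, 0.2)
  )
  out <- prepare_features(ft)
  expect_equal(out$a[out$subject_id == "S001" & out$period_id == "p1"], 2)
  # S002's rows have every sleep feature missing and are removed entirely
  expect_false("S002" %in% out$subject_id)
  expect_equal(nrow(attr(out, "dropped_samples")), 2)
  # b is complete after the sample removal, so no column is dropped
  expect_length(attr(out, "dropped_features"), 0)

  # a column missing for a single-period subject is dropped
  ft2 <- tibble::tibble(
    subject_id = c("S001", "S002", "S003"), period_id = "p1",
    a = c(1, NA, 3), we_wd_diff = c(0.1, 0.2, 0.3)
  )
  out2 <- prepare_features(ft2)
  expect_false("a" %in% names(out2))
  expect_equal(attr(out2, "dropped_features"), "a")

  # a complete table passes through unchanged
  ft3 <- ft; ft3$a[1] <- 9; ft3$b[3:4] <- 7; ft3$we_wd_diff[3:4] <- 0
  ft3$trend_spt_dur[3:4] <- 0
  expect_equal(as.data.frame(prepare_features(ft3)), as.data.frame(ft3),
               ignore_attr = TRUE)
})

test_that("targets encode diagnosis and post-period disability correctly", {
  co <- small_cohort(n_subjects = 4, periods = 2, seed = 91)
  samples <- tibble::tibble(subject_id = rep(sprintf("S%03d", 1:4), each = 2),
                            period_id = rep(c("p1", "p2"), 4))
  y_diag <- encode_target(co$outcomes, samples, "diagnosis")
  base <- co$outcomes[co$outcomes$timepoint == "baseline", ]
  expect_equal(y_diag, as.integer(base$diagnosis[match(samples$subject_id,
                                                       base$subject_id)] == "stroke"))
  y_sev <- encode_target(co$outcomes, samples, "severity")
  after <- co$outcomes[co$outcomes$timepoint != "baseline", ]
  key <- paste(after$subject_id, sub("after_", "", after$timepoint))
  want <- as.integer(after$mrs[match(paste(samples$subject_id, samples$period_id),
                                     key)] > 0)
  expect_equal(y_sev, want)
})

test_that("a separable feature achieves AUC 1 at k = 1 under LOSO", {
  d <- make_cv_data(sep = 6, seed = 93)
  cv <- loso_fit_predict(d$x, d$y, d$subj, c("good", "noise1"), k = 1)
  expect_equal(nrow(cv), length(d$y))   # each sample predicted exactly once
  expect_equal(metrics_binary(cv$prob, cv$y)$auc, 1)
  curve <- auc_curve(d$x, d$y, d$subj, c("good", "noise1", "noise2"))
  expect_equal(curve$auc[1], 1)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
  expect_equal(nrow(curve), 3)
  # deterministic pipeline: identical on re-run
  curve2 <- auc_curve(d$x, d$y, d$subj, c("good", "noise1", "noise2"))
  expect_equal(curve$auc, curve2$auc)
})

test_that("standardization statistics never see the held-out subject", {
  d <- make_cv_data(n_subj = 10, seed = 95)
  cv_clean <- loso_fit_predict(d$x, d$y, d$subj, names(d$x), k = 3)
  # corrupt one subject's features wildly; all other folds' held-out
  # predictions must be bitwise unchanged
  x_bad <- d$x
  x_bad[d$subj == "S03", ] <- x_bad[d$subj == "S03", ] + 1000
  cv_bad <- loso_fit_predict(x_bad, d$y, d$subj, names(d$x), k = 3)
  # the fold that holds S03 out trains without it: its standardization
  # statistics must be bitwise identical despite the corruption
  expect_identical(attr(cv_bad, "fold_stats")[["S03"]],
                   attr(cv_clean, "fold_stats")[["S03"]])
  # every other fold trains on S03 and must see the change
  other <- setdiff(unique(d$subj), "S03")
  moved <- vapply(other, function(s) {
    !identical(attr(cv_bad, "fold_stats")[[s]]$mean,
               attr(cv_clean, "fold_stats")[[s]]$mean)
  }, logical(1))
  expect_true(all(moved))
})

test_that("single-class training folds abort with the subject named", {
  x <- tibble::tibble(f = rnorm(6))
  y <- c(1, 0, 0, 0, 0, 0)
  subj <- sprintf("S%02d", 1:6)
  expect_error(loso_fit_predict(x, y, subj, "f", 1), "S01")
})

test_that("metrics match the U-statistic oracle and handle ties", {
  # perfect ranking
  m <- metrics_binary(c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9), c(0, 0, 0, 1, 1, 1))
  expect_equal(m$auc, 1)
  expect_equal(m$balanced_accuracy, 1)
  # constant probabilities tie everywhere
  expect_equal(metrics_binary(rep(0.4, 8), rep(0:1, 4))$auc, 0.5)
  # random cases against the all-pairs oracle, and against pROC
  set.seed(97)
  for (i in 1:10) {
    n <- 30
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)  # rounding forces ties
    got <- metrics_binary(p, y)$auc
    expect_equal(got, auc_oracle(p, y), tolerance = 1e-12)
    proc <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                           direction = "<")))
    expect_equal(got, proc, tolerance = 1e-9)
  }
  expect_error(metrics_binary(c(0.2, 0.8), c(1, 1)), "Both classes")
})

test_that("the weighted ensemble is the stated convex combination", {
  expect_equal(weighted_ensemble(cbind(0.2, 0.6), c(1, 1)), 0.4)
  # all weight on one model returns that model
  expect_equal(weighted_ensemble(cbind(0.2, 0.9), c(1e-9, 1)), 0.9,
               tolerance = 1e-6)
  set.seed(99)
  pm <- matrix(runif(40), 10, 4)
  w <- c(0.766, 0.778, 0.684, 0.807)
  ens <- weighted_ensemble(pm, w)
  expect_true(all(ens >= apply(pm, 1, min) - 1e-12))
  expect_true(all(ens <= apply(pm, 1, max) + 1e-12))
  expect_equal(weighted_ensemble(pm, rep(2, 4)), rowMeans(pm), tolerance = 1e-12)
  pm[3, 2] <- NA
  expect_error(weighted_ensemble(pm, w), "every sample")
})
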