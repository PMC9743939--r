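# Screening: half-day trimming, valid-day rules, sleep detection, and
# intensity classification.

test_that("trimming keeps only complete midnight-to-midnight days", {
  # wear Monday 14:00 -> Tuesday 10:00: no complete day survives
  n <- (10 + 10) * 60                       # 20 h of 60-s epochs
  es <- toy_series(rep(10, n), start = 14 * 3600)
  tr <- trim_half_days(es)
  expect_length(tr, 0)
  expect_true(isTRUE(attr(tr, "empty")))

  # wear Monday 14:00 -> 09:00 eight full days later: keep earliest 6
  n2 <- (10 + 8 * 24 + 9) * 60
  es2 <- toy_series(rep(10, n2), start = 14 * 3600)
  tr2 <- trim_half_days(es2)
  expect_equal(length(tr2) * 60 / 86400, 6)
  expect_equal(tr2$time[1], 86400)          # first midnight after start

  # exact midnight-to-midnight 5 days: unchanged
  es3 <- toy_series(rep(10, 5 * 1440))
  tr3 <- trim_half_days(es3)
  expect_identical(tr3$enmo, es3$enmo)
  expect_identical(tr3$time, es3$time)
})

test_that("validity rules encode the 4-day / weekend / calibration screen", {
  day <- rep(10, 1440)
  # 5 full-wear days starting Wednesday: Sat + Sun inside -> included
  es <- toy_series(rep(day, 5), start_dow = 3L)
  v <- assess_validity(es)
  expect_true(v$included)
  expect_equal(v$exclusion_reason, "none")
  expect_equal(v$n_valid_days, 5)

  # 4 weekday-only days (Mon-Thu) -> excluded for wear_time
  es2 <- toy_series(rep(day, 4), start_dow = 1L)
  v2 <- assess_validity(es2)
  expect_false(v2$included)
  expect_equal(v2$exclusion_reason, "wear_time")
  expect_false(v2$has_weekend_day)

  # 3 valid days (others below 10 h wear) -> excluded
  wear <- c(rep(TRUE, 3 * 1440),
            rep(c(rep(TRUE, 9 * 60), rep(FALSE, 15 * 60)), 2))
  es3 <- toy_series(rep(day, 5), wear = wear, start_dow = 5L)
  v3 <- assess_validity(es3)
  expect_equal(v3$n_valid_days, 3)
  expect_false(v3$included)

  # calibration error above 10 mg dominates the exclusion reason
  es4 <- toy_series(rep(day, 5), calibration_error = 12, start_dow = 3L)
  v4 <- assess_validity(es4)
  expect_false(v4$included)
  expect_equal(v4$exclusion_reason, "calibration")

  # 4 valid days incl. Saturday -> included
  es5 <- toy_series(rep(day, 4), start_dow = 4L)  # Thu..Sun
  expect_true(assess_validity(es5)$included)
})

test_that("sleep detector finds a planted quiescent night within 15 min", {
  set.seed(7)
  sod <- (0:(2 * 17280 - 1) * 5) %% 86400
  night <- sod >= 23 * 3600 | sod < 7 * 3600
  enmo <- ifelse(night, abs(rnorm(length(sod), 2, 1)),
                 abs(rnorm(length(sod), 30, 8)))
  es <- epoch_series((0:(2 * 17280 - 1)) * 5, enmo, epoch_len = 5)
  win <- detect_sleep(es)
  expect_gt(nrow(win), 0)
  # the interior full-night window: onset near 23:00, wake near 07:00
  full <- win[win$duration_h > 7.5, ]
  expect_equal(nrow(full), 1)
  expect_lt(abs((full$start %% 86400) - 23 * 3600), 15 * 60)
  expect_lt(abs((full$end %% 86400) - 7 * 3600), 15 * 60)
})

test_that("constant high activity yields no sleep window, with a warning", {
  es <- toy_series(rep(50, 1440))
  expect_warning(win <- detect_sleep(es), "no main sleep window")
  expect_equal(nrow(win), 0)
})

test_that("daytime naps are kept as analysable waking time", {
  set.seed(8)
  n <- 17280
  sod <- (0:(n - 1)) * 5
  night <- sod >= 23 * 3600 | sod < 7 * 3600
  nap <- sod >= 14 * 3600 & sod < 15 * 3600
  enmo <- ifelse(night | nap, abs(rnorm(n, 2, 1)), abs(rnorm(n, 30, 8)))
  es <- epoch_series(sod, enmo, epoch_len = 5)
  win <- detect_sleep(es)
  iseries <- classify_intensity(es, win)
  nap_labels <- as.character(iseries$labels[nap])
  expect_false(any(nap_labels == "SLEEP"))
  expect_true(all(nap_labels == "SB"))      # low ENMO, analysable
})

test_that("cut-points classify with upper-class-inclusive boundaries", {
  es <- toy_series(c(30, 70, 150, 44.8, 100.6, 120), epoch_len = 60)
  win <- tibble::tibble(start = 5 * 60, end = 6 * 60)  # last epoch asleep
  iseries <- classify_intensity(es, win)
  expect_equal(as.character(iseries$labels),
               c("SB", "LPA", "MVPA", "LPA", "MVPA", "SLEEP"))
})

test_that("labels partition every epoch exactly once", {
  es <- generate_epoch_series(signal_spec(days = 2, seed = 14))
  truth <- attr(es, "truth")
  win <- detect_sleep(es, ground_truth = tibble::tibble(
    onset = truth$sleep_onset, wake = truth$wake))
  iseries <- classify_intensity(es, win)
  counts <- table(iseries$labels)
  expect_equal(sum(counts), length(es))
  expect_equal(unname(counts[["NONWEAR"]]), 0)
})

test_that("conventional variables are day-order invariant means", {
  lab <- c(rep("SB", 600), rep("LPA", 300), rep("MVPA", 240), rep("SLEEP", 300))
  day1 <- toy_intensity(c(lab), epoch_len = 60)
  # two days, reversed composition on day 2
  labs2 <- c(lab, rev(lab))
  is2 <- toy_intensity(labs2, epoch_len = 60)
  is2$enmo <- c(rep(10, 1440), rep(20, 1440))
  cv <- conventional_variables(is2, valid_days = c(0, 1))
  expect_equal(cv$time_sb, 10)
  expect_equal(cv$time_mvpa, 4)
  expect_equal(cv$mean_enmo, 15)
})
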