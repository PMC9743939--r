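# Intensity-distribution metrics: histogram accounting, intensity
# gradient, MX metrics.

make_day_series <- function(enmo_per_epoch, epoch_len = 60) {
  toy_series(enmo_per_epoch, epoch_len = epoch_len)
}

test_that("histogram minutes per day total 1440 over full days", {
  set.seed(41)
  es <- make_day_series(abs(rnorm(2 * 1440, 50, 60)))
  h <- intensity_histogram(es, valid_days = c(0, 1))
  expect_equal(sum(h$minutes), 1440)
  expect_true(all(h$minutes >= 0))
})

test_that("flat log-time profile has zero gradient", {
  # equal minutes in every finite bin: ln(time) constant
  h <- tibble::tibble(lo = seq(0, 4000, 25),
                      hi = c(seq(25, 4000, 25), Inf),
                      mid = c(seq(12.5, 3987.5, 25), NA),
                      minutes = c(rep(9, 160), 0))
  g <- intensity_gradient(h)
  expect_equal(g$gradient, 0, tolerance = 1e-12)
})

test_that("planted power-law histogram recovers its exponent exactly", {
  mids <- seq(12.5, 3987.5, 25)
  h <- tibble::tibble(lo = seq(0, 4000, 25),
                      hi = c(seq(25, 4000, 25), Inf),
                      mid = c(mids, NA),
                      minutes = c(mids^-2, 0))
  g <- intensity_gradient(h)
  expect_equal(g$gradient, -2, tolerance = 1e-9)
  expect_equal(g$r_squared, 1, tolerance = 1e-12)
})

test_that("gradient is invariant to uniform time rescaling", {
  set.seed(42)
  mins <- c(rexp(160, 1 / 10), 0)
  h <- tibble::tibble(lo = seq(0, 4000, 25),
                      hi = c(seq(25, 4000, 25), Inf),
                      mid = c(seq(12.5, 3987.5, 25), NA),
                      minutes = mins)
  h2 <- h; h2$minutes <- h$minutes * 7
  expect_equal(intensity_gradient(h)$gradient,
               intensity_gradient(h2)$gradient, tolerance = 1e-12)
})

test_that("a more active profile has a less negative gradient", {
  set.seed(43)
  mk <- function(scale) {
    x <- pmin(4200, stats::rexp(1440 * 4, 1 / scale))
    intensity_histogram(make_day_series(x), valid_days = 0:3)
  }
  g_sed <- intensity_gradient(mk(15))$gradient
  g_act <- intensity_gradient(mk(60))$gradient
  expect_gt(g_act, g_sed)
})

test_that("gradient is undefined below two usable bins", {
  h <- tibble::tibble(lo = 0, hi = 25, mid = 12.5, minutes = 1440)
  expect_message(g <- intensity_gradient(h), "fewer than two")
  expect_true(is.na(g$gradient))
})

test_that("MX equals the k-th largest epoch and the planted plateau", {
  # 180 five-second epochs at 200 mg: M0.25 (15 min = 180 epochs) = 200
  n <- 17280
  x <- c(rep(200, 180), rep(10, n - 180))
  es <- epoch_series((0:(n - 1)) * 5, x, epoch_len = 5)
  expect_equal(mx_metric(es, 15, valid_days = 0), 200)
  # constant series: MX = c for any window
  es2 <- make_day_series(rep(33, 1440))
  expect_equal(mx_metric(es2, 15, 0), 33)
  expect_equal(mx_metric(es2, 480, 0), 33)
})

test_that("MX matches the order-statistic oracle on random days", {
  set.seed(44)
  for (rep in 1:5) {
    x <- abs(rnorm(1440, 40, 30))
    es <- make_day_series(x)
    for (w in c(15, 120, 480)) {
      expect_equal(mx_metric(es, w, 0), kth_largest_oracle(x, w),
                   tolerance = 1e-12)
    }
  }
})

test_that("shorter MX windows never fall below longer ones", {
  set.seed(45)
  for (s in 1:5) {
    es <- make_day_series(abs(rnorm(1440, 40, 30)))
    expect_gte(mx_metric(es, 15, 0), mx_metric(es, 480, 0))
  }
})
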