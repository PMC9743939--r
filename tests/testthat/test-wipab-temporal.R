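# Temporal metrics: DFA, lag autocorrelation, LZ76 complexity, sample
# entropy, symbolic dynamics. Long-series DFA calibrations live in the
# acceptance suite; here shorter series and exact oracles.

test_that("DFA separates anti-correlated, white and integrated noise", {
  cfg <- dfa_config(scale_min_min = 5, scale_max_min = 60, epoch_len = 5)
  n <- 17280 * 2
  set.seed(71)
  white <- rnorm(n)
  brown <- cumsum(rnorm(n))
  anti <- diff(rnorm(n + 1))
  a_w <- dfa_alpha(white, cfg)$alpha_full
  a_b <- dfa_alpha(brown, cfg)$alpha_full
  a_a <- dfa_alpha(anti, cfg)$alpha_full
  expect_equal(a_w, 0.5, tolerance = 0.1 / 0.5)
  expect_equal(a_b, 1.5, tolerance = 0.1 / 1.5)
  expect_lt(a_a, 0.5)
})

test_that("DFA fluctuation table matches a plain reference implementation", {
  dfa_ref <- function(x, scales) {
    y <- cumsum(x - mean(x))
    vapply(scales, function(s) {
      nw <- length(y) %/% s
      res2 <- 0
      for (w in seq_len(nw)) {
        seg <- y[((w - 1) * s + 1):(w * s)]
        t <- seq_len(s)
        fit <- lm.fit(cbind(1, t), seg)
        res2 <- res2 + sum(fit$residuals^2)
      }
      sqrt(res2 / (nw * s))
    }, numeric(1))
  }
  set.seed(72)
  x <- rnorm(4000)
  cfg <- dfa_config(scale_min_min = 1, scale_max_min = 20, n_scales = 10,
                    epoch_len = 5)
  got <- dfa_alpha(x, cfg)$fluctuations
  expect_equal(got$f, dfa_ref(x, got$scale_epochs), tolerance = 1e-10)
})

test_that("short series lose the long band but keep the short band", {
  set.seed(73)
  x <- rnorm(3000)  # ~4.2 h of 5-s epochs; 360-min scales unreachable
  d <- dfa_alpha(x, dfa_config(epoch_len = 5))
  expect_true(is.na(d$alpha_long))
  expect_false(is.na(d$alpha_short))
})

test_that("lag autocorrelation matches the definition and its edge cases", {
  set.seed(74)
  x <- rnorm(500)
  for (k in c(1, 7, 100)) {
    expect_equal(autocorrelation_lag(x, k), acf_oracle(x, k),
                 tolerance = 1e-12)
    # cross-check against the standard acf implementation
    expect_equal(autocorrelation_lag(x, k),
                 stats::acf(x, lag.max = k, plot = FALSE,
                            demean = TRUE)$acf[k + 1],
                 tolerance = 1e-10)
  }
  # exactly periodic series: the biased convention caps the lag-k
  # autocorrelation at (n - k)/n, here 3/4
  per <- rep(sin(2 * pi * (1:288) / 288), 4)
  expect_equal(autocorrelation_lag(per, 288), 3 / 4, tolerance = 0.01)
  set.seed(75)
  w <- rnorm(10000)
  expect_lt(abs(autocorrelation_lag(w, 288)), 3 / sqrt(10000))
  expect_message(r <- autocorrelation_lag(rep(4, 100), 10), "constant")
  expect_true(is.na(r))
})

test_that("LZ76 count matches hand parses and the substring oracle", {
  # classic worked parse: 0.001.10.100.1000.101 -> 6 phrases
  s <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(lempel_ziv(s, 2)$c, 6)
  expect_equal(lz76_oracle(s), 6)
  # constant sequence parses into two phrases
  const <- lempel_ziv(rep(3L, 100), alphabet_size = 6)
  expect_equal(const$c, 2)
  expect_equal(const$lzc, 2 * log(100) / log(6) / 100)
  set.seed(76)
  for (r in 1:10) {
    seq <- sample.int(4, sample(20:200, 1), replace = TRUE)
    expect_equal(lempel_ziv(seq, 4)$c, lz76_oracle(seq))
  }
})

test_that("a random sequence is more complex than a constant one", {
  set.seed(77)
  rnd <- sample.int(6, 500, replace = TRUE)
  expect_gt(lempel_ziv(rnd, 6)$lzc, lempel_ziv(rep(1L, 500), 6)$lzc)
})

test_that("sample entropy matches the brute-force oracle", {
  set.seed(78)
  for (r in 1:10) {
    x <- rnorm(sample(25:200, 1))
    expect_equal(sample_entropy(x), sampen_oracle(x), tolerance = 1e-10)
  }
  expect_equal(sample_entropy(rep(2, 50)), 0)
})

test_that("sorting a series lowers its sample entropy", {
  set.seed(79)
  x <- rnorm(300)
  expect_gt(sample_entropy(x), sample_entropy(sort(x)))
})

test_that("the four pattern families partition all 216 windows", {
  grid <- expand.grid(s1 = 1:6, s2 = 1:6, s3 = 1:6)
  fam <- classify_pattern(grid$s1, grid$s2, grid$s3)
  expect_equal(length(fam), 216)
  expect_false(anyNA(fam))
  expect_setequal(unique(fam), c("0V", "1V", "2LV", "2UV"))
  expect_equal(sum(table(fam)), 216)
})

test_that("worked pattern examples classify as printed", {
  expect_equal(classify_pattern(3, 3, 3), "0V")
  expect_equal(classify_pattern(3, 3, 1), "1V")
  expect_equal(classify_pattern(1, 3, 3), "1V")
  expect_equal(classify_pattern(6, 4, 1), "2LV")
  expect_equal(classify_pattern(2, 3, 5), "2LV")
  expect_equal(classify_pattern(3, 1, 2), "2UV")
  expect_equal(classify_pattern(4, 5, 1), "2UV")
})

test_that("symbolic 2UV share behaves on degenerate and monotone input", {
  expect_equal(symbolic_2uv(rep(5, 100)), 0)            # zero variance
  expect_equal(symbolic_2uv(1:100), 0)                  # monotone staircase
  set.seed(80)
  x <- rnorm(2000)
  expect_gt(symbolic_2uv(x), 0)
})

test_that("2UV share is invariant under monotone transforms", {
  set.seed(81)
  x <- abs(rnorm(1000, 30, 10))
  # a monotone transform changes symbol values but clipping/binning is
  # distribution-dependent; rank-preserving linear maps must be exact
  expect_equal(symbolic_2uv(x), symbolic_2uv(3 * x + 7), tolerance = 1e-12)
})

test_that("state symbolisation respects duration classes and conserves time", {
  labels <- c(rep("SB", 600), rep("LPA", 60), rep("SB", 20),
              rep("SLEEP", 100), rep("MVPA", 150))
  iseries <- toy_intensity(labels, epoch_len = 60)
  bouts <- find_bouts(iseries)
  sym <- symbolize_states(iseries, bouts)
  expect_length(sym, sum(labels != "SLEEP"))
  # 600-min SB bout -> long-SB symbol 3; 20-min SB -> mid symbol 2
  expect_equal(unique(sym[1:600]), 3L)
  expect_equal(unique(sym[661:680]), 2L)
  # 2.5 h MVPA bout -> long-MVPA symbol 7
  expect_equal(unique(sym[681:830]), 7L)
  # a 45-min vs 5-min SB bout get different symbols
  l2 <- c(rep("SB", 45), rep("LPA", 15), rep("SB", 5))
  i2 <- toy_intensity(l2, epoch_len = 60)
  s2 <- symbolize_states(i2, find_bouts(i2))
  expect_false(s2[1] == s2[65])
})
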