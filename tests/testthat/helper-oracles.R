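# Independent brute-force oracles used to validate the package's
# implementations on short series. Each is written directly from the
# defining formula, with no shared code with the implementation under test.

# Sample entropy by naive O(n^2) template counting (Richman-Moorman
# convention: n - m templates of length m+1, self-matches excluded).
sampen_oracle <- function(x, m = 2, r = 0.2) {
  z <- (x - mean(x)) / sd(x)
  n <- length(z)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(z[i:(i + m - 1)] - z[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(z[i + m] - z[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# LZ76 phrase count by direct substring parsing: a phrase starting at l is
# complete at length L when s[l..l+L-1] does not occur inside s[1..l+L-2];
# a final still-reproducible phrase counts once.
lz76_oracle <- function(s) {
  ch <- letters[as.integer(as.factor(s))]
  n <- length(ch)
  cnt <- 0L
  l <- 1L
  while (l <= n) {
    L <- 1L
    while (l + L - 1L <= n) {
      phrase <- paste(ch[l:(l + L - 1L)], collapse = "")
      window <- paste(ch[seq_len(l + L - 2L)], collapse = "")
      if (grepl(phrase, window, fixed = TRUE)) L <- L + 1L else break
    }
    cnt <- cnt + 1L
    l <- l + L
  }
  cnt
}

# Autocorrelation at lag k straight from the definition.
acf_oracle <- function(x, k) {
  xm <- x - mean(x)
  n <- length(x)
  sum(xm[1:(n - k)] * xm[(k + 1):n]) / sum(xm^2)
}

# Gini index by the full pairwise double sum.
gini_oracle <- function(x) {
  n <- length(x)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) tot <- tot + abs(x[i] - x[j])
  tot / (2 * n^2 * mean(x))
}

# k-th largest value by repeated maximum removal (no sorting).
kth_largest_oracle <- function(x, k) {
  for (i in seq_len(k - 1)) x <- x[-which.max(x)]
  max(x)
}

# A flat midnight-aligned series builder for screening/bout tests.
toy_series <- function(enmo_by_epoch, epoch_len = 60, start = 0,
                       wear = NULL, calibration_error = 0, start_dow = 1L) {
  epoch_series(time = start + (seq_along(enmo_by_epoch) - 1) * epoch_len,
               enmo = enmo_by_epoch, epoch_len = epoch_len, wear = wear,
               calibration_error = calibration_error, start_dow = start_dow)
}

# A labelled intensity series built directly from labels (for bout tests).
toy_intensity <- function(labels, epoch_len = 5) {
  structure(list(
    labels = factor(labels, levels = c("SB", "LPA", "MVPA", "SLEEP", "NONWEAR")),
    time = (seq_along(labels) - 1) * epoch_len,
    epoch_len = epoch_len,
    enmo = rep(10, length(labels)),
    cut_points = c(sb_lpa = 44.8, lpa_mvpa = 100.6)),
    class = "intensity_series")
}

# Clock "HH:MM" to seconds since midnight (test-local copy).
parse_clock_for_test <- function(x) {
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 3600 + p[2] * 60
}
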