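# Temporal-correlation and regularity WIPAB metrics: detrended fluctuation
# analysis, the 24-h autocorrelation, Lempel-Ziv complexity of the
# PA-state sequence, sample entropy, and symbolic dynamics.

#' DFA configuration
#'
#' Scales span 5--360 min with 100 log-spaced candidate scales (snapped to
#' whole epochs, duplicates removed); the short band covers 5--90 min and
#' the long band 120--360 min, omitting the transitional region between
#' them. Detrending is linear (DFA-1) over non-overlapping windows.
#'
#' @param scale_min_min,scale_max_min scale range in minutes.
#' @param n_scales number of candidate log-spaced scales.
#' @param short_band,long_band numeric length-2 band limits in minutes.
#' @param epoch_len epoch length in seconds.
#' @return List with class `dfa_config`.
#' @export
dfa_config <- function(scale_min_min = 5, scale_max_min = 360,
                       n_scales = 100,
                       short_band = c(5, 90), long_band = c(120, 360),
                       epoch_len = 5) {
  if (scale_min_min >= scale_max_min) {
    stop_config("scale range", "min must be below max")
  }
  structure(list(scale_min_min = scale_min_min,
                 scale_max_min = scale_max_min,
                 n_scales = n_scales,
                 short_band = short_band, long_band = long_band,
                 epoch_len = epoch_len),
            class = "dfa_config")
}

#' Detrended fluctuation analysis (DFA-1)
#'
#' The mean-removed series is integrated into a profile; for each scale the
#' profile is split into non-overlapping windows, linearly detrended per
#' window, and the root-mean-square fluctuation F(s) computed over all
#' windowed points. The scaling exponent alpha is the OLS slope of
#' `log F(s)` on `log s` over a band of scales. Alpha near 0.5 indicates an
#' uncorrelated (white-noise) series, below 0.5 anti-correlation, above 0.5
#' persistence, and values around 1 the strongest temporal correlation.
#'
#' @param x numeric series at epoch resolution.
#' @param cfg a [dfa_config()].
#' @return List with `alpha_short`, `alpha_long`, `alpha_full` and a
#'   tibble `fluctuations` (`scale_epochs`, `scale_min`, `f`). Bands whose
#'   scales exceed half the series length are `NA` (the short band is
#'   computed whenever feasible).
#' @export
dfa_alpha <- function(x, cfg = dfa_config()) {
  x <- as.numeric(x)
  n <- length(x)
  el <- cfg$epoch_len
  s_min <- max(4, round(cfg$scale_min_min * 60 / el))
  s_max <- round(cfg$scale_max_min * 60 / el)
  scales <- unique(round(exp(seq(log(s_min), log(s_max),
                                 length.out = cfg$n_scales))))
  scales <- scales[scales >= 4 & scales <= floor(n / 2)]
  if (length(scales) < 2) {
    return(list(alpha_short = NA_real_, alpha_long = NA_real_,
                alpha_full = NA_real_,
                fluctuations = tibble::tibble(scale_epochs = integer(0),
                                              scale_min = numeric(0),
                                              f = numeric(0))))
  }
  y <- cumsum(x - mean(x))
  f <- vapply(scales, function(s) {
    nw <- n %/% s
    m <- matrix(y[seq_len(nw * s)], nrow = s)
    t_c <- seq_len(s) - (s + 1) / 2
    stt <- sum(t_c^2)
    cm <- colMeans(m)
    syy <- colSums(m^2) - s * cm^2
    slope <- as.numeric(crossprod(t_c, m)) / stt
    ss <- pmax(syy - slope^2 * stt, 0)
    sqrt(sum(ss) / (nw * s))
  }, numeric(1))
  ok <- f > 0
  tab <- tibble::tibble(scale_epochs = scales[ok],
                        scale_min = scales[ok] * el / 60,
                        f = f[ok])
  band_alpha <- function(lo, hi) {
    use <- tab$scale_min >= lo & tab$scale_min <= hi
    if (sum(use) < 2) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log(tab$scale_epochs[use])),
                       log(tab$f[use])))[2])
  }
  list(alpha_short = band_alpha(cfg$short_band[1], cfg$short_band[2]),
       alpha_long = band_alpha(cfg$long_band[1], cfg$long_band[2]),
       alpha_full = band_alpha(cfg$scale_min_min, cfg$scale_max_min),
       fluctuations = tab)
}

#' Autocorrelation at a fixed lag
#'
#' The standard biased-normalised autocorrelation
#' `sum_t (x_t - xbar)(x_{t+k} - xbar) / sum_t (x_t - xbar)^2`.
#' At a 24-h lag it measures how consistently the timing of activity
#' repeats from day to day.
#'
#' @param x numeric series at epoch resolution.
#' @param lag_epochs lag in epochs (24 h at 5-s epochs is 17280).
#' @return Coefficient in `[-1, 1]`; `NA` (with a message) for a constant
#'   series or one shorter than twice the lag.
#' @export
autocorrelation_lag <- function(x, lag_epochs) {
  x <- as.numeric(x)
  n <- length(x)
  k <- as.integer(lag_epochs)
  if (n < 2 * k) {
    message("series shorter than twice the lag; autocorrelation undefined")
    return(NA_real_)
  }
  xm <- x - mean(x)
  denom <- sum(xm^2)
  if (denom == 0) {
    message("constant series; autocorrelation undefined")
    return(NA_real_)
  }
  sum(xm[seq_len(n - k)] * xm[(k + 1):n]) / denom
}

#' The default reconstructed PA-state alphabet
#'
#' Maps each awake epoch to a symbol combining its intensity class with its
#' bout-duration class. The published state table this reconstructs was not
#' available, so the default is a synthetic reconstruction -- sedentary
#' bouts in three duration classes (under 10 min, 10--30 min, 30 min and
#' over), light and MVPA bouts in two each (under vs at least 10 min) --
#' and any user-supplied map with columns `intensity`, `min_duration`
#' (inclusive lower bound, minutes) and `symbol` may replace it.
#'
#' @return Tibble with columns `intensity`, `min_duration`, `symbol`.
#' @export
state_alphabet <- function() {
  tibble::tibble(
    intensity = c("SB", "SB", "SB", "LPA", "LPA", "MVPA", "MVPA"),
    min_duration = c(0, 10, 30, 0, 10, 0, 10),
    symbol = 1:7)
}

#' Symbolise awake epochs into PA states
#'
#' Each awake epoch receives the symbol of its bout's intensity and
#' duration class per the alphabet (the highest `min_duration` row of the
#' epoch's intensity not exceeding the bout duration).
#'
#' @param iseries an `intensity_series`.
#' @param bouts a `bout_list` over the same series.
#' @param alphabet a state map as returned by [state_alphabet()].
#' @return Integer vector of symbols, one per awake epoch, in time order.
#' @export
symbolize_states <- function(iseries, bouts, alphabet = state_alphabet()) {
  el <- iseries$epoch_len
  lab <- as.character(iseries$labels)
  awake_idx <- which(!(lab %in% c("SLEEP", "NONWEAR")))
  sym <- integer(0)
  if (nrow(bouts) == 0) return(sym)
  out <- integer(length(iseries$time))
  for (b in seq_len(nrow(bouts))) {
    ints <- bouts$intensity[b]
    rows <- alphabet[alphabet$intensity == ints &
                     alphabet$min_duration <= bouts$duration_min[b], ]
    if (nrow(rows) == 0) {
      stop("state alphabet has no entry for state: ", ints, " of ",
           bouts$duration_min[b], " min", call. = FALSE)
    }
    s <- rows$symbol[which.max(rows$min_duration)]
    n_ep <- round(bouts$duration_min[b] * 60 / el)
    i0 <- round((bouts$start[b] - iseries$time[1]) / el) + 1L
    out[i0:(i0 + n_ep - 1L)] <- s
  }
  out[awake_idx]
}

#' Normalised Lempel-Ziv complexity
#'
#' Parses the symbol sequence with the LZ76 scheme and normalises the
#' phrase count so the measure is independent of sequence length:
#' `LZC = c(n) * log_alpha(n) / n` with `alpha` the alphabet size. Higher
#' values indicate a greater rate of new subpatterns, i.e. a more complex
#' activity profile.
#'
#' @param seq integer (or factor) symbol sequence.
#' @param alphabet_size number of symbols in the alphabet; defaults to the
#'   number of distinct values, but should be the full alphabet size when
#'   some states never occur.
#' @return List with `c` (phrase count) and `lzc` (normalised complexity).
#' @export
lempel_ziv <- function(seq, alphabet_size = NULL) {
  s <- as.integer(as.factor(seq))
  n <- length(s)
  if (n < 2) stop("sequence must have at least 2 symbols", call. = FALSE)
  a <- alphabet_size %||% max(length(unique(s)), 2L)
  if (a < 2) a <- 2L
  cn <- .lz76_count(s)
  list(c = cn, lzc = cn * (log(n) / log(a)) / n)
}

#' Sample-entropy configuration
#'
#' @param m template length (default 2).
#' @param r tolerance as a multiple of the standardised series' sd
#'   (default 0.2; the series is standardised to mean 0 and variance 1
#'   before matching, so the tolerance is exactly `r`).
#' @return List with class `sampen_config`.
#' @export
sampen_config <- function(m = 2, r = 0.2) {
  assert_scalar_num(m, "m", lower = 1)
  assert_scalar_num(r, "r", lower = 1e-12)
  structure(list(m = as.integer(m), r = r), class = "sampen_config")
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` is the number of template pairs of length `m`
#' within Chebyshev distance `r` and `A` the number still matching when
#' extended to `m+1`; self-matches excluded. The series is standardised to
#' mean 0 and unit variance first. Higher values indicate a more
#' irregular, less predictable series. A constant series returns 0 by the
#' convention that all templates match.
#'
#' @param x numeric series.
#' @param cfg a [sampen_config()].
#' @return Entropy in nats (non-negative), or `NA` (with a message) when no
#'   extended match exists (infinite entropy).
#' @export
sample_entropy <- function(x, cfg = sampen_config()) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= cfg$m + 1) stop("series too short for sample entropy", call. = FALSE)
  s <- sd(x)
  if (s == 0) return(0)
  z <- (x - mean(x)) / s
  ab <- .sampen_counts(z, cfg$m, cfg$r)
  if (ab[2] == 0 || ab[1] == 0) {
    message("no template matches; sample entropy undefined")
    return(NA_real_)
  }
  -log(ab[1] / ab[2])
}

#' Symbolic-dynamics configuration
#'
#' @param n_symbols quantisation levels (default 6).
#' @param pattern_len window length L (default 3; the four-family scheme is
#'   defined for L = 3).
#' @param clip_sd clip bounds at mean +/- `clip_sd` standard deviations.
#' @return List with class `symbolic_config`.
#' @export
symbolic_config <- function(n_symbols = 6, pattern_len = 3, clip_sd = 3) {
  assert_scalar_num(n_symbols, "n_symbols", lower = 2)
  if (pattern_len != 3) {
    stop_config("pattern_len", "must be 3 for the 0V/1V/2LV/2UV families")
  }
  structure(list(n_symbols = as.integer(n_symbols), pattern_len = 3L,
                 clip_sd = clip_sd), class = "symbolic_config")
}

#' Classify a length-3 symbol window into a variation family
#'
#' `0V`: no variation (e.g. 3-3-3). `1V`: exactly one variation
#' (3-3-1, 1-3-3). `2LV`: two like variations, monotone ascent or descent
#' (6-4-1, 2-3-5). `2UV`: two unlike variations, one rise and one fall
#' (3-1-2, 4-5-1). The four families partition all windows.
#'
#' @param s1,s2,s3 integer symbols (vectorised).
#' @return Character vector in `c("0V", "1V", "2LV", "2UV")`.
#' @export
classify_pattern <- function(s1, s2, s3) {
  d1 <- s2 - s1
  d2 <- s3 - s2
  ifelse(d1 == 0 & d2 == 0, "0V",
  ifelse(d1 == 0 | d2 == 0, "1V",
  ifelse(sign(d1) == sign(d2), "2LV", "2UV")))
}

#' Quantise a series into symbols
#'
#' Clips the series to mean +/- `clip_sd` sd, then cuts the clipped range
#' into `n_symbols` equal-width, left-closed bins (the top bin closed),
#' yielding symbols 1..n. A zero-variance series maps entirely to symbol 1.
#'
#' @param x numeric series.
#' @param cfg a [symbolic_config()].
#' @return Integer vector of symbols.
#' @export
quantise_symbols <- function(x, cfg = symbolic_config()) {
  x <- as.numeric(x)
  mu <- mean(x)
  s <- sd(x)
  if (is.na(s) || s == 0) return(rep(1L, length(x)))
  lo <- mu - cfg$clip_sd * s
  hi <- mu + cfg$clip_sd * s
  xc <- pmin(pmax(x, lo), hi)
  sym <- floor((xc - lo) / (hi - lo) * cfg$n_symbols) + 1L
  pmin(sym, cfg$n_symbols)
}

#' Symbolic dynamics: share of 2UV patterns
#'
#' Quantises the series (see [quantise_symbols()]), slides overlapping
#' windows of length 3, classifies each window into one of the four
#' variation families, and returns the percentage of windows in the most
#' complex family (two unlike variations). Only this family is reported
#' because the four shares are compositional.
#'
#' @param x numeric series.
#' @param cfg a [symbolic_config()].
#' @return Percentage of 2UV windows in `[0, 100]`.
#' @export
symbolic_2uv <- function(x, cfg = symbolic_config()) {
  sym <- quantise_symbols(x, cfg)
  n <- length(sym)
  if (n < 3) stop("series must have at least 3 epochs", call. = FALSE)
  fam <- classify_pattern(sym[1:(n - 2)], sym[2:(n - 1)], sym[3:n])
  100 * mean(fam == "2UV")
}
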