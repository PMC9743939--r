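# Synthetic epoch-level accelerometry. The generator plants a known
# diurnal structure -- nightly sleep windows, alternating waking bouts with
# state-level mean accelerations, tunable epoch noise -- so that every
# downstream stage (screening, bout detection, WIPAB metrics, models) can be
# tested against ground truth.

#' Bout-length distribution constructors
#'
#' Waking time is generated as a concatenation of bouts whose lengths (in
#' minutes) are drawn from one of three families: a continuous power law
#' (Pareto) with density proportional to `x^-exponent` above `xmin`, a
#' log-normal, or a fixed length.
#'
#' @param exponent power-law exponent, must exceed 1.
#' @param xmin lower bound of the power law, minutes.
#' @param mu,sigma log-scale mean and sd of the log-normal, minutes.
#' @param len fixed bout length, minutes.
#' @return A list with class `bout_dist` describing the family.
#' @export
dist_power_law <- function(exponent = 2.5, xmin = 1) {
  assert_scalar_num(exponent, "exponent", lower = 1 + 1e-9)
  assert_scalar_num(xmin, "xmin", lower = 1e-9)
  structure(list(family = "power_law", exponent = exponent, xmin = xmin),
            class = "bout_dist")
}

#' @rdname dist_power_law
#' @export
dist_lognormal <- function(mu = log(2), sigma = 0.6) {
  assert_scalar_num(sigma, "sigma", lower = 0)
  structure(list(family = "lognormal", mu = mu, sigma = sigma),
            class = "bout_dist")
}

#' @rdname dist_power_law
#' @export
dist_fixed <- function(len = 10) {
  assert_scalar_num(len, "len", lower = 1e-9)
  structure(list(family = "fixed", len = len), class = "bout_dist")
}

#' Draw bout lengths from a bout-length distribution
#'
#' @param dist a [dist_power_law()], [dist_lognormal()] or [dist_fixed()].
#' @param n number of draws.
#' @return Numeric vector of bout lengths in minutes (continuous; callers
#'   snap to whole epochs when laying bouts into a series).
#' @export
draw_bout_lengths <- function(dist, n) {
  switch(dist$family,
    power_law = dist$xmin * runif(n)^(-1 / (dist$exponent - 1)),
    lognormal = rlnorm(n, dist$mu, dist$sigma),
    fixed     = rep(dist$len, n),
    stop("unknown bout distribution family: ", dist$family, call. = FALSE))
}

#' Epoch-noise model constructors
#'
#' Noise added on top of the state-level mean acceleration: white Gaussian,
#' first-order autoregressive, or pink (1/f) noise synthesised by spectral
#' shaping of white noise.
#'
#' @param sd standard deviation (milli-g) of the noise.
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @return A list with class `noise_model`.
#' @export
noise_white <- function(sd = 5) {
  assert_scalar_num(sd, "sd", lower = 0)
  structure(list(model = "white", sd = sd), class = "noise_model")
}

#' @rdname noise_white
#' @export
noise_ar1 <- function(phi = 0.5, sd = 5) {
  assert_scalar_num(sd, "sd", lower = 0)
  if (abs(phi) >= 1) stop_config("phi", "must satisfy |phi| < 1")
  structure(list(model = "ar1", phi = phi, sd = sd), class = "noise_model")
}

#' @rdname noise_white
#' @export
noise_pink <- function(sd = 5) {
  assert_scalar_num(sd, "sd", lower = 0)
  structure(list(model = "pink", sd = sd), class = "noise_model")
}

#' Simulate a noise series from a noise model
#'
#' Uses the current RNG state; callers seed beforehand. The AR(1) series is
#' scaled so its innovations have the requested sd (marginal sd is
#' `sd/sqrt(1-phi^2)`); the pink series is rescaled to the requested sd.
#'
#' @param n series length in epochs.
#' @param model a [noise_white()], [noise_ar1()] or [noise_pink()].
#' @return Numeric vector of length `n`.
#' @export
simulate_noise <- function(n, model) {
  switch(model$model,
    white = rnorm(n, 0, model$sd),
    ar1 = as.numeric(stats::filter(rnorm(n, 0, model$sd), model$phi,
                                   method = "recursive")),
    pink = pink_noise(n) * model$sd,
    stop("unknown noise model: ", model$model, call. = FALSE))
}

#' Pink (1/f) noise by spectral synthesis
#'
#' White Gaussian noise is Fourier transformed, its amplitude spectrum is
#' shaped by `f^(-1/2)` (power spectral density proportional to 1/f), and the
#' result is inverse transformed and standardised to unit sd. This is the
#' canonical regime of maximal temporal correlation for DFA (scaling
#' exponent near 1).
#'
#' @param n series length.
#' @return Numeric vector with mean ~0 and sd 1.
#' @export
pink_noise <- function(n) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  w <- rnorm(n)
  spec <- fft(w)
  # frequency index of each FFT bin (0, 1, ..., n/2, ..., 1)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k)
  shape <- c(0, 1 / sqrt(k[-1]))  # zero out DC
  x <- Re(fft(spec * shape, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

#' Specification of a synthetic epoch-level acceleration signal
#'
#' Houses the generative knobs for one participant's record: epoch length,
#' number of complete days, the nightly sleep window, per-intensity
#' bout-length distributions, state-level mean accelerations, state
#' transition weights and the epoch-noise model. Defaults are calibrated so
#' that a generated participant resembles the adult general-population
#' profile the package targets: roughly 12 h/day sedentary, 1.3 h/day MVPA
#' and a 24-h average acceleration near 25 milli-g, with an 8-h nightly
#' sleep window.
#'
#' @param epoch_len epoch length in seconds, must divide 60.
#' @param days number of complete (midnight-to-midnight) days.
#' @param sleep_onset,wake clock times ("HH:MM") of the nightly sleep window.
#' @param bout_dist named list of [dist_power_law()]/[dist_lognormal()]/
#'   [dist_fixed()] per intensity (`SB`, `LPA`, `MVPA`).
#' @param intensity_levels named numeric, mean ENMO (milli-g) per state.
#' @param state_weights named numeric sampling weights for the next bout's
#'   intensity; the next state is drawn among states other than the current
#'   one, so consecutive equal-intensity bouts never merge and planted bout
#'   lengths are exactly recoverable.
#' @param noise a noise model from [noise_white()] and friends; noise sd is
#'   attenuated by `sleep_noise_factor` during sleep.
#' @param sleep_level mean ENMO during sleep, milli-g.
#' @param sleep_noise_factor multiplier on noise sd inside sleep windows.
#' @param calibration_error post-calibration error metadata, milli-g.
#' @param start_dow day of week (1 = Monday ... 7 = Sunday) of the first
#'   generated day. The default 3 (Wednesday) makes a 6-day record span one
#'   full weekend.
#' @param seed integer seed; identical specs and seed give bit-identical
#'   series.
#' @return A validated list with class `signal_spec`.
#' @export
signal_spec <- function(epoch_len = 5,
                        days = 6,
                        sleep_onset = "23:00",
                        wake = "07:00",
                        bout_dist = list(
                          SB   = dist_power_law(2.4, xmin = 2),
                          LPA  = dist_lognormal(log(2), 0.6),
                          MVPA = dist_lognormal(log(1.5), 0.7)),
                        intensity_levels = c(SB = 16, LPA = 70, MVPA = 160),
                        state_weights = c(SB = 0.88, LPA = 0.08, MVPA = 0.04),
                        noise = noise_ar1(0.5, 5),
                        sleep_level = 2,
                        sleep_noise_factor = 0.2,
                        calibration_error = 0,
                        start_dow = 3L,
                        seed = 1L) {
  assert_scalar_num(epoch_len, "epoch_len", 1, 60)
  if (60 %% epoch_len != 0) stop_config("epoch_len", "must divide 60")
  assert_scalar_num(days, "days", 1, 60)
  onset <- parse_clock(sleep_onset)
  wk <- parse_clock(wake)
  states <- c("SB", "LPA", "MVPA")
  if (!all(states %in% names(bout_dist))) {
    stop_config("bout_dist", "must name SB, LPA and MVPA distributions")
  }
  for (s in states) {
    if (!inherits(bout_dist[[s]], "bout_dist")) {
      stop_config("bout_dist", paste0("entry '", s, "' is not a bout_dist"))
    }
  }
  if (!all(states %in% names(intensity_levels))) {
    stop_config("intensity_levels", "must name SB, LPA and MVPA levels")
  }
  if (any(intensity_levels < 0)) stop_config("intensity_levels", "must be >= 0")
  if (!all(states %in% names(state_weights)) || any(state_weights < 0) ||
      sum(state_weights) <= 0) {
    stop_config("state_weights", "must be non-negative weights for SB/LPA/MVPA")
  }
  if (!inherits(noise, "noise_model")) stop_config("noise", "must be a noise_model")
  assert_scalar_num(sleep_level, "sleep_level", lower = 0)
  assert_scalar_num(sleep_noise_factor, "sleep_noise_factor", lower = 0)
  assert_scalar_num(calibration_error, "calibration_error", lower = 0)
  structure(
    list(epoch_len = epoch_len, days = as.integer(days),
         sleep_onset = onset, wake = wk,
         bout_dist = bout_dist[states],
         intensity_levels = intensity_levels[states],
         state_weights = state_weights[states],
         noise = noise, sleep_level = sleep_level,
         sleep_noise_factor = sleep_noise_factor,
         calibration_error = calibration_error,
         start_dow = as.integer(start_dow), seed = as.integer(seed)),
    class = "signal_spec")
}

# Sleep mask (logical per epoch) for the nightly window of a spec.
nightly_sleep_mask <- function(sod, onset, wake) {
  if (onset > wake) sod >= onset | sod < wake else sod >= onset & sod < wake
}

#' Generate a synthetic epoch series
#'
#' Lays out `days` complete days of `epoch_len`-second epochs. Epochs inside
#' the nightly sleep window get the sleep-level mean; waking time is filled
#' with consecutive bouts whose intensities are sampled from the state
#' weights (never repeating the previous intensity) and whose lengths are
#' drawn from the per-intensity distributions. Model noise is added on top
#' and the result floored at zero.
#'
#' The planted truth is attached as `attr(series, "truth")`: the noise-free
#' per-epoch state, the planted bout table (intensity and length per waking
#' bout) and the sleep window clock times.
#'
#' @param spec a [signal_spec()].
#' @return An [epoch_series()] with a `truth` attribute.
#' @examples
#' es <- generate_epoch_series(signal_spec(days = 2, seed = 7))
#' es
#' @export
generate_epoch_series <- function(spec) {
  if (!inherits(spec, "signal_spec")) {
    stop_config("spec", "must be a signal_spec")
  }
  set.seed(spec$seed)
  epd <- 86400 / spec$epoch_len                # epochs per day
  n <- spec$days * epd
  time <- (seq_len(n) - 1) * spec$epoch_len
  sod <- secs_of_day(time)
  asleep <- nightly_sleep_mask(sod, spec$sleep_onset, spec$wake)

  state <- character(n)
  state[asleep] <- "SLEEP"
  states <- names(spec$state_weights)
  w <- spec$state_weights / sum(spec$state_weights)

  # Fill each contiguous awake block with alternating-intensity bouts.
  blocks <- true_runs(!asleep)
  bout_int <- character(0)
  bout_len <- numeric(0)
  for (b in seq_len(nrow(blocks))) {
    pos <- blocks$start[b]
    end <- blocks$end[b]
    prev <- NA_character_
    while (pos <= end) {
      wsel <- w
      if (!is.na(prev) && sum(w[states != prev]) > 0) wsel[prev] <- 0
      st <- sample(states, 1, prob = wsel)
      len_min <- draw_bout_lengths(spec$bout_dist[[st]], 1)
      len_ep <- max(1L, round(len_min * 60 / spec$epoch_len))
      len_ep <- min(len_ep, end - pos + 1L)
      state[pos:(pos + len_ep - 1L)] <- st
      pos <- pos + len_ep
      prev <- st
    }
    # planted truth: realized maximal runs within the block (draws from a
    # single-intensity spec merge, exactly as a bout detector would see them)
    r <- rle(state[blocks$start[b]:blocks$end[b]])
    bout_int <- c(bout_int, r$values)
    bout_len <- c(bout_len, r$lengths * spec$epoch_len / 60)
  }

  base <- ifelse(asleep, spec$sleep_level,
                 spec$intensity_levels[state])
  eps <- simulate_noise(n, spec$noise)
  eps[asleep] <- eps[asleep] * spec$sleep_noise_factor
  enmo <- pmax(0, as.numeric(base) + eps)

  series <- epoch_series(time, enmo, spec$epoch_len,
                         calibration_error = spec$calibration_error,
                         start_dow = spec$start_dow)
  attr(series, "truth") <- list(
    state = state,
    bouts = tibble::tibble(intensity = bout_int, duration_min = bout_len),
    sleep_onset = spec$sleep_onset, wake = spec$wake,
    spec = spec)
  series
}
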