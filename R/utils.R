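# Shared small helpers: clock-time parsing, seed handling, assertions.

#' Parse a clock time of day into seconds since midnight
#'
#' Accepts `"HH:MM"` or `"HH:MM:SS"`. Used for sleep-onset/wake times and
#' search-window boundaries.
#'
#' @param x character scalar clock time.
#' @return Number of seconds since midnight (0 to 86399).
#' @keywords internal
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) < 2 || length(parts) > 3 || anyNA(parts)) {
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got: ", x, call. = FALSE)
  }
  if (length(parts) == 2) parts <- c(parts, 0)
  sec <- parts[1] * 3600 + parts[2] * 60 + parts[3]
  if (sec < 0 || sec >= 86400) stop("clock time out of range: ", x, call. = FALSE)
  sec
}

# Seconds since midnight for each timestamp (UTC arithmetic; timestamps are
# stored as seconds since an origin midnight so no DST complications arise).
secs_of_day <- function(time) as.numeric(time) %% 86400

# Calendar day index (0-based) counted from the epoch origin midnight.
day_index <- function(time) floor(as.numeric(time) / 86400)

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

assert_scalar_num <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop_config(field, "must be a single number")
  }
  if (x < lower || x > upper) {
    stop_config(field, sprintf("must be in [%s, %s]", lower, upper))
  }
  invisible(x)
}

# Draw integer sub-seeds (< 2^31) deterministically from a parent seed.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Run-length starts/ends of TRUE stretches in a logical vector.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
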