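# EpochSeries: the package's core container for one participant's
# epoch-level ENMO record.

#' Construct an epoch series
#'
#' An `epoch_series` holds one participant's uniformly spaced epoch-level
#' ENMO accelerations (in milli-g), together with per-epoch wear flags and
#' the device's post-calibration error. All downstream screening, bout and
#' WIPAB computations consume this container.
#'
#' @param time numeric or POSIXct vector of epoch start times. Internally
#'   stored as seconds; `0` corresponds to a midnight. Must be uniformly
#'   spaced at `epoch_len` seconds.
#' @param enmo non-negative numeric vector, ENMO in milli-g per epoch.
#' @param epoch_len epoch length in seconds; must divide 60.
#' @param wear logical vector of per-epoch wear flags (default all `TRUE`).
#' @param calibration_error post-calibration error in milli-g (metadata used
#'   by [assess_validity()]; files above 10 mg are excluded).
#' @param id optional participant identifier.
#' @param start_dow integer day of week of the calendar day containing
#'   `time = 0` (1 = Monday ... 7 = Sunday). Weekend detection uses this.
#' @return An object of class `epoch_series`: a list with fields `time`,
#'   `enmo`, `epoch_len`, `wear`, `calibration_error`, `id`, `start_dow`.
#' @examples
#' es <- epoch_series(time = seq(0, 59, by = 5), enmo = rep(20, 12))
#' es
#' @export
epoch_series <- function(time, enmo, epoch_len = 5, wear = NULL,
                         calibration_error = 0, id = "p1", start_dow = 1L) {
  if (inherits(time, "POSIXct")) time <- as.numeric(time)
  time <- as.numeric(time)
  enmo <- as.numeric(enmo)
  if (length(time) != length(enmo)) {
    stop("time and enmo must have equal length", call. = FALSE)
  }
  assert_scalar_num(epoch_len, "epoch_len", 1, 60)
  if (60 %% epoch_len != 0) stop_config("epoch_len", "must divide 60")
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(abs(dt - epoch_len) > 1e-6)) {
      stop("timestamps must be uniformly spaced at epoch_len seconds",
           call. = FALSE)
    }
  }
  if (any(enmo < 0, na.rm = TRUE)) stop("enmo must be non-negative", call. = FALSE)
  if (is.null(wear)) wear <- rep(TRUE, length(enmo))
  if (length(wear) != length(enmo)) {
    stop("wear flag length must match enmo", call. = FALSE)
  }
  structure(
    list(time = time, enmo = enmo, epoch_len = epoch_len,
         wear = as.logical(wear),
         calibration_error = as.numeric(calibration_error),
         id = id, start_dow = as.integer(start_dow)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  n <- length(x$enmo)
  cat(sprintf("<epoch_series '%s': %d epochs x %gs (%.2f days), calib err %.1f mg>\n",
              x$id, n, x$epoch_len, n * x$epoch_len / 86400,
              x$calibration_error))
  if (n > 0) {
    cat(sprintf("  ENMO mean %.1f mg, range [%.1f, %.1f] mg\n",
                mean(x$enmo), min(x$enmo), max(x$enmo)))
  }
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$enmo)

# Subset helper keeping metadata.
slice_series <- function(series, idx) {
  epoch_series(series$time[idx], series$enmo[idx], series$epoch_len,
               series$wear[idx], series$calibration_error, series$id,
               series$start_dow)
}

#' Read / write epoch series files
#'
#' Per-participant epoch files hold two columns: `timestamp` (seconds since
#' the recording origin midnight, or ISO-8601 when written from POSIXct) and
#' `enmo_mg`. CSV is the default; Parquet is available when the `arrow`
#' package is installed.
#'
#' @param path file path; format inferred from the extension
#'   (`.csv` or `.parquet`).
#' @param series an [epoch_series()].
#' @param epoch_len,calibration_error,id,start_dow metadata not stored in the
#'   two-column file; supplied by the caller (e.g. from a cohort table).
#' @return `read_epoch_series()` returns an [epoch_series()];
#'   `write_epoch_series()` returns `path` invisibly.
#' @export
read_epoch_series <- function(path, epoch_len = 5, calibration_error = 0,
                              id = NULL, start_dow = 1L) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required to read Parquet files", call. = FALSE)
    }
    df <- as.data.frame(arrow::read_parquet(path))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (!all(c("timestamp", "enmo_mg") %in% names(df))) {
    stop("epoch file must have columns 'timestamp' and 'enmo_mg'", call. = FALSE)
  }
  ts <- df$timestamp
  if (is.character(ts)) ts <- as.numeric(as.POSIXct(ts, tz = "UTC"))
  epoch_series(ts, df$enmo_mg, epoch_len = epoch_len,
               calibration_error = calibration_error,
               id = id %||% sub("\\.(csv|parquet)$", "", basename(path)),
               start_dow = start_dow)
}

#' @rdname read_epoch_series
#' @export
write_epoch_series <- function(series, path) {
  df <- tibble::tibble(timestamp = series$time, enmo_mg = series$enmo)
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("the 'arrow' package is required to write Parquet files", call. = FALSE)
    }
    arrow::write_parquet(df, path)
  } else {
    readr::write_csv(df, path, progress = FALSE)
  }
  invisible(path)
}
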