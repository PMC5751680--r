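#' Interval series
#'
#' The package's core container: an ordered vector of positive millisecond
#' values of one kind — call durations, inter-onset intervals (IOI),
#' inter-peak intervals (IPI), or their within-bout ("short") subsets.
#'
#' @param values Numeric vector of positive milliseconds, in temporal order.
#'   Values are stored at microsecond (1e-6 ms) precision: quantizing away
#'   sub-nanosecond floating-point noise from frame-time arithmetic keeps
#'   exact-equality comparisons (e.g. a KS test of IOI against IPI on a
#'   constant-offset fixture) meaningful.
#' @param kind One of `"duration"`, `"IOI"`, `"IPI"`, `"IOI_short"`,
#'   `"IPI_short"`.
#' @return An `interval_series` tibble with a single `value_ms` column and
#'   the kind attached as an attribute (see [series_kind()]).
#' @export
interval_series <- function(values, kind = c("duration", "IOI", "IPI",
                                             "IOI_short", "IPI_short")) {
  kind <- match.arg(kind)
  values <- round(as.numeric(values), 6)
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort(paste0("interval series '", kind, "' must contain finite positive milliseconds"))
  }
  out <- tibble(value_ms = values)
  class(out) <- c("interval_series", class(out))
  attr(out, "kind") <- kind
  out
}

#' @rdname interval_series
#' @param s An `interval_series`.
#' @export
series_kind <- function(s) attr(s, "kind")

#' Call durations
#'
#' Duration of each retained call, `(offset - onset) * 1000` ms.
#'
#' @param calls Tibble with `onset`/`offset` columns in seconds, sorted by
#'   onset (e.g. from [select_calls()] or [call_peaks()]).
#' @return An [interval_series()] of kind `"duration"`, one value per call
#'   (empty for an empty call table).
#' @export
call_durations <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("onset", "offset") %in% names(calls)))
  interval_series((calls$offset - calls$onset) * 1000, kind = "duration")
}

#' Inter-onset intervals (IOI)
#'
#' Time elapsed between the onsets of consecutive retained calls, in ms.
#' With `n` calls the series has `n - 1` values (empty for 0 or 1 calls).
#'
#' @inheritParams call_durations
#' @return An [interval_series()] of kind `"IOI"`.
#' @export
inter_onset_intervals <- function(calls) {
  stopifnot(is.data.frame(calls), "onset" %in% names(calls))
  d <- diff(calls$onset) * 1000
  if (any(d <= 0)) {
    abort("duplicate or non-increasing call onsets: every inter-onset interval must be positive")
  }
  interval_series(d, kind = "IOI")
}

#' Inter-peak intervals (IPI)
#'
#' Time between the maximum-intensity peaks of consecutive retained calls,
#' in ms. Requires the `peak_time` column added by [call_peaks()].
#'
#' @inheritParams call_durations
#' @return An [interval_series()] of kind `"IPI"`.
#' @export
inter_peak_intervals <- function(calls) {
  stopifnot(is.data.frame(calls), "peak_time" %in% names(calls))
  d <- diff(calls$peak_time) * 1000
  if (any(d <= 0)) {
    abort("non-increasing consecutive peak times: every inter-peak interval must be positive")
  }
  interval_series(d, kind = "IPI")
}

#' Within-bout interval threshold
#'
#' The adaptive threshold separating within-bout intervals from between-bout
#' gaps: `k` times the minimum value of the series (default `k = 4`, which
#' on the original recording gives approximately 3900 ms).
#'
#' @param s An [interval_series()].
#' @param k Positive multiplier (default 4).
#' @return Threshold in milliseconds.
#' @export
short_threshold <- function(s, k = 4) {
  stopifnot(inherits(s, "interval_series"), k > 0)
  if (nrow(s) == 0L) abort("cannot compute a threshold from an empty interval series")
  k * min(s$value_ms)
}

#' Keep within-bout ("short") intervals
#'
#' Retains the values at or below the threshold (boundary inclusive),
#' preserving order — the subset that isolates timing within vocalization
#' bouts from the pooled within-plus-between-bout series.
#'
#' @param s An [interval_series()] of kind `"IOI"` or `"IPI"`.
#' @param threshold Threshold in ms, typically from [short_threshold()].
#' @param inclusive Keep values equal to the threshold (default `TRUE`).
#' @return An [interval_series()] of kind `"IOI_short"` / `"IPI_short"`.
#' @export
filter_short <- function(s, threshold = short_threshold(s), inclusive = TRUE) {
  stopifnot(inherits(s, "interval_series"), threshold > 0)
  kind <- switch(series_kind(s),
    IOI = "IOI_short", IPI = "IPI_short",
    abort("filter_short() applies to IOI or IPI series"))
  keep <- if (inclusive) s$value_ms <= threshold else s$value_ms < threshold
  interval_series(s$value_ms[keep], kind = kind)
}

#' Write an interval series to CSV
#'
#' One value column in milliseconds, rounded to 0.1 ms; the header row is
#' the series kind. This is the schema of the pipeline's five output files
#' (`durations_all.csv`, `IOI_all.csv`, `IPI_all.csv`, `IOI_short.csv`,
#' `IPI_short.csv`).
#'
#' @param s An [interval_series()].
#' @param path Output path.
#' @param digits Rounding digits (default 1, i.e. 0.1 ms).
#' @return Invisibly, `path`.
#' @export
write_interval_csv <- function(s, path, digits = 1) {
  stopifnot(inherits(s, "interval_series"))
  d <- data.frame(x = round(s$value_ms, digits))
  names(d) <- series_kind(s)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an interval series from CSV
#'
#' Accepts any single-numeric-column CSV (including the deposited data
#' files); the series kind is taken from the header when recognised,
#' otherwise from `kind`.
#'
#' @param path CSV path.
#' @param kind Fallback kind when the header is not one of the five series
#'   names (default `"duration"`).
#' @return An [interval_series()].
#' @export
read_interval_csv <- function(path, kind = "duration") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) != 1L) {
    abort(paste0("expected a single-column CSV, got ", ncol(d), " columns in ", path))
  }
  v <- d[[1]]
  if (!is.numeric(v)) {
    bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
    abort(paste0("non-numeric value at data row ", bad, " of ", path, ": ", v[bad]))
  }
  known <- c("duration", "IOI", "IPI", "IOI_short", "IPI_short")
  hdr <- names(d)[1]
  interval_series(v, kind = if (hdr %in% known) hdr else kind)
}
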