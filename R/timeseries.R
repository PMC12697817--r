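#' Uniformly sampled time series
#'
#' The universal carrier between all analysis stages: a uniformly sampled
#' scalar signal with a unit tag. Time is always in seconds internally;
#' readers are expected to convert.
#'
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing with a constant step.
#' @param values Numeric vector of signal values, same length as `times`.
#'   `NA` entries mark missing samples and must be resolved (see
#'   [fill_missing()]) before analysis.
#' @param unit Unit tag for the values: `"mV"`, `"V"`, `"F"`, `"Ohm"` or
#'   `"uA"`.
#' @param label Free-text label for the recording.
#'
#' @return An object of class `protodyn_ts`: a list with elements `times`,
#'   `values`, `unit`, `label` and `fs` (sampling rate in Hz, `1/dt`).
#' @export
#' @examples
#' ts <- timeseries(0:9, sin(0:9), unit = "mV", label = "demo")
#' ts$fs
timeseries <- function(times, values, unit = "mV", label = "") {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) < 2L)
    stop("timeseries needs at least 2 samples", call. = FALSE)
  if (length(times) != length(values))
    stop("times and values must have the same length", call. = FALSE)
  dts <- diff(times)
  bad <- which(dts <= 0)
  if (length(bad))
    stop(sprintf("time axis not strictly increasing at index %d", bad[1] + 1L),
         call. = FALSE)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-9 * max(dt, 1)))
    stop("time step is not uniform (relative tolerance 1e-9)", call. = FALSE)
  unit <- match.arg(unit, c("mV", "V", "F", "Ohm", "uA", "rad"))
  structure(
    list(times = times, values = values, unit = unit, label = label,
         fs = 1 / dt),
    class = "protodyn_ts"
  )
}

#' @export
print.protodyn_ts <- function(x, ...) {
  cat(sprintf("<protodyn_ts> %s: %d samples @ %.6g Hz, [%g, %g] s, unit %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$values), x$fs, x$times[1],
              x$times[length(x$times)], x$unit))
  invisible(x)
}

#' @export
length.protodyn_ts <- function(x) length(x$values)

is_timeseries <- function(x) inherits(x, "protodyn_ts")

stopifnot_ts <- function(x) {
  if (!is_timeseries(x))
    stop("expected a protodyn_ts object (see timeseries())", call. = FALSE)
  invisible(x)
}

#' Resolve marked-missing samples
#'
#' Interior `NA` runs are linearly interpolated from their finite
#' neighbours; leading and trailing `NA`s are filled with the nearest
#' finite value.
#'
#' @param series A [timeseries()] object possibly containing `NA` values.
#' @return The series with all values finite.
#' @export
fill_missing <- function(series) {
  stopifnot_ts(series)
  v <- series$values
  if (!anyNA(v)) return(series)
  if (all(is.na(v)))
    stop("all values are missing", call. = FALSE)
  v <- stats::approx(series$times[!is.na(v)], v[!is.na(v)],
                     xout = series$times, method = "linear", rule = 2)$y
  series$values <- v
  series
}

#' Read a time series from CSV
#'
#' Reads a two-column (or wider) CSV with a header, takes the named time
#' and value columns, marks non-numeric value cells as missing and resolves
#' them by linear interpolation (nearest-value fill at the edges). The
#' sampling rate is inferred from the median time step.
#'
#' @param path Path to a CSV file (UTF-8, header required).
#' @param time_column,value_column Column names to use.
#' @param unit Unit tag for the values (see [timeseries()]).
#' @param label Label for the series; defaults to the file name.
#' @return A [timeseries()] object.
#' @export
read_timeseries <- function(path, time_column = "time_s",
                            value_column = "value", unit = "mV",
                            label = basename(path)) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(time_column, value_column))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not present in %s", col, path), call. = FALSE)
  if (nrow(df) < 2L)
    stop("need at least 2 rows", call. = FALSE)
  tt <- suppressWarnings(as.numeric(df[[time_column]]))
  if (anyNA(tt))
    stop("non-numeric entries in the time column", call. = FALSE)
  vv <- suppressWarnings(as.numeric(df[[value_column]]))
  fill_missing(timeseries(tt, vv, unit = unit, label = label))
}

#' Write a time series to CSV
#'
#' Emits the same two-column dialect [read_timeseries()] consumes.
#'
#' @param series A [timeseries()] object.
#' @param path Output path.
#' @param time_column,value_column Column names to write.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(series, path, time_column = "time_s",
                             value_column = "value") {
  stopifnot_ts(series)
  df <- data.frame(series$times, series$values)
  names(df) <- c(time_column, value_column)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Interpolate several recordings onto a common time axis
#'
#' All series are resampled by linear interpolation onto the time axis of
#' the longest input (most samples; ties broken by longest span). Outside a
#' series' native span values are held at the nearest endpoint.
#'
#' @param series_list A list of [timeseries()] objects.
#' @return A list of series all sharing the common axis, in input order.
#' @export
interpolate_common_axis <- function(series_list) {
  if (!is.list(series_list) || length(series_list) == 0L)
    stop("need a non-empty list of series", call. = FALSE)
  lapply(series_list, stopifnot_ts)
  ns <- vapply(series_list, length, integer(1))
  spans <- vapply(series_list, function(s) diff(range(s$times)), numeric(1))
  idx <- order(-ns, -spans)[1]
  axis <- series_list[[idx]]$times
  lapply(series_list, function(s) {
    v <- stats::approx(s$times, s$values, xout = axis, method = "linear",
                       rule = 2)$y
    timeseries(axis, v, unit = s$unit, label = s$label)
  })
}

#' Subtract the initial-window baseline
#'
#' The baseline is the mean of the samples in the first `window_seconds`
#' of the recording (missing values ignored); it is subtracted from the
#' whole series so downstream statistics measure deviation from rest.
#'
#' @param series A [timeseries()] object.
#' @param window_seconds Length of the initial averaging window, seconds.
#' @return A list of class `protodyn_baseline` with elements `baseline`
#'   (in series units), `window_samples` and `adjusted` (the corrected
#'   [timeseries()]).
#' @export
subtract_baseline <- function(series, window_seconds = 10) {
  stopifnot_ts(series)
  t0 <- series$times[1]
  span <- series$times[length(series$times)] - t0
  if (span < window_seconds)
    stop("series shorter than the baseline window", call. = FALSE)
  in_win <- series$times < t0 + window_seconds
  baseline <- mean(series$values[in_win], na.rm = TRUE)
  adjusted <- series
  adjusted$values <- series$values - baseline
  structure(
    list(baseline = baseline, window_samples = sum(in_win),
         adjusted = adjusted),
    class = "protodyn_baseline"
  )
}

#' Flag outliers by the IQR rule
#'
#' A value is flagged when it lies more than `k` interquartile ranges
#' outside the quartiles, i.e. below `Q1 - k*IQR` or above `Q3 + k*IQR`.
#' Quartiles use linear interpolation between order statistics.
#'
#' @param values Numeric vector, length at least 4.
#' @param k IQR multiplier (1.5 is the conventional fence).
#' @return Logical mask, `TRUE` for flagged values.
#' @export
#' @examples
#' iqr_outlier_flags(c(1, 2, 3, 4, 100))
iqr_outlier_flags <- function(values, k = 1.5) {
  values <- as.numeric(values)
  if (length(values) < 4L)
    stop("need at least 4 values for quartiles", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}
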