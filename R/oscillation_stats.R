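## Descriptive and oscillation metrics of a recording: moments, quantiles,
## peak-to-peak amplitude (max - min), PSD-based dominant frequency and
## period, coefficient of variation, and the amplification factor between
## two amplitudes.

#' Dominant frequency of a recording
#'
#' Frequency of the maximum of the Welch-averaged PSD, excluding the
#' zero-frequency bin, computed on the linearly detrended series. The
#' period is its reciprocal.
#'
#' @param series A [timeseries()] with at least 64 samples.
#' @param nperseg Welch segment length; defaults to
#'   `min(4096, 2^floor(log2(n/4)))` (power of two, at least 8 averaged
#'   half-overlapping segments).
#' @return A list with `freq` (Hz) and `period` (s).
#' @export
#' @examples
#' ts <- gen_oscillation(oscillation_spec(f0 = 0.1, duration = 4096,
#'                                        noise_sd = 0))
#' dominant_frequency(ts)$freq
dominant_frequency <- function(series, nperseg = NULL) {
  stopifnot_ts(series)
  n <- length(series$values)
  if (n < 64L) stop("need at least 64 samples", call. = FALSE)
  x <- linear_detrend(series$values)
  if (all(abs(x) < 1e-15))
    stop("degenerate (all-zero) series: dominant frequency undefined",
         call. = FALSE)
  if (is.null(nperseg))
    nperseg <- max(16L, min(4096L, 2^floor(log2(n / 4))))
  det <- timeseries(series$times, x, unit = series$unit,
                    label = series$label)
  p <- estimate_psd(det, nperseg = nperseg)
  keep <- p$freqs > 0
  f <- p$freqs[keep][which.max(p$psd[keep])]
  list(freq = f, period = 1 / f)
}

#' Coefficient of variation
#'
#' Ratio of the sample standard deviation (n - 1 denominator) to the mean.
#'
#' @param values Numeric vector with non-zero mean.
#' @return Dimensionless CV.
#' @export
coefficient_of_variation <- function(values) {
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean", call. = FALSE)
  s <- stats::sd(values)
  s / m
}

#' Descriptive and oscillation summary of a recording
#'
#' The summary-table layout used for comparing recordings: count, mean,
#' SD, minimum, quartiles, maximum, peak-to-peak amplitude (max - min),
#' dominant frequency and period from the PSD, and the coefficient of
#' variation (0 for a constant series).
#'
#' @param series A [timeseries()] with at least 16 samples.
#' @return A list of class `oscillation_summary` with fields `count`,
#'   `mean`, `sd`, `min`, `q25`, `median`, `q75`, `max`, `amplitude`,
#'   `dominant_freq`, `period`, `cv`.
#' @export
summarize_oscillation <- function(series) {
  stopifnot_ts(series)
  v <- series$values
  if (length(v) < 16L) stop("need at least 16 samples", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  s <- stats::sd(v)
  domf <- if (s == 0) list(freq = NA_real_, period = NA_real_)
          else dominant_frequency(series)
  structure(
    list(count = length(v), mean = mean(v), sd = s,
         min = min(v), q25 = q[1], median = q[2], q75 = q[3], max = max(v),
         amplitude = max(v) - min(v),
         dominant_freq = domf$freq, period = domf$period,
         cv = if (s == 0) 0 else s / mean(v)),
    class = "oscillation_summary"
  )
}

#' @export
print.oscillation_summary <- function(x, ...) {
  cat(sprintf(paste0("n=%d mean=%.4f sd=%.4f min=%.4f q25=%.4f med=%.4f ",
                     "q75=%.4f max=%.4f amp=%.4f f=%.6g Hz T=%.6g s cv=%.4f\n"),
              x$count, x$mean, x$sd, x$min, x$q25, x$median, x$q75, x$max,
              x$amplitude, x$dominant_freq, x$period, x$cv))
  invisible(x)
}

#' Amplitude amplification factor between two systems
#'
#' Ratio of a test amplitude to a reference amplitude, e.g. the
#' conjugate-network amplitude over the bare-polymer amplitude.
#'
#' @param a_ref Reference peak-to-peak amplitude (> 0), mV.
#' @param a_test Test peak-to-peak amplitude, mV.
#' @return Dimensionless factor `a_test / a_ref`.
#' @export
#' @examples
#' amplification_factor(48.803786, 1999.128103)  # about 41
amplification_factor <- function(a_ref, a_test) {
  if (a_ref <= 0) stop("reference amplitude must be > 0", call. = FALSE)
  a_test / a_ref
}
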