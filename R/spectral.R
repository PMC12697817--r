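## Welch-style spectral estimation on stats::fft. One internal engine
## produces per-segment tapered FFTs; PSD, cross-spectra (for coherence)
## and the spectrogram all share its segmentation and scaling, so Parseval
## holds with the same constants everywhere.

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

linear_detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), x)$residuals
}

# Segment, detrend, taper and FFT a signal. Returns the one-sided
# frequency grid and a (n_freq x n_segments) complex matrix scaled so
# that Mod(.)^2 summed one-sided is a density in (unit^2)/Hz.
welch_segments <- function(x, fs, nperseg, overlap = 0.5, detrend = TRUE) {
  n <- length(x)
  nperseg <- as.integer(nperseg)
  if (nperseg < 8L) stop("segment length too short", call. = FALSE)
  if (n < nperseg)
    stop("series shorter than one segment", call. = FALSE)
  hop <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = hop)
  w <- hann_window(nperseg)
  norm <- fs * sum(w^2)
  nf <- nperseg %/% 2L
  freqs <- (0:nf) * fs / nperseg
  mat <- vapply(starts, function(s) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- linear_detrend(seg)
    X <- stats::fft(seg * w)[1:(nf + 1L)]
    X / sqrt(norm)
  }, complex(nf + 1L))
  mat <- matrix(mat, nrow = nf + 1L)
  list(freqs = freqs, coef = mat, nperseg = nperseg, hop = hop,
       n_segments = length(starts))
}

one_sided_scale <- function(nf_plus_1, nperseg) {
  s <- rep(2, nf_plus_1)
  s[1] <- 1
  if (nperseg %% 2L == 0L) s[nf_plus_1] <- 1
  s
}

#' Welch power spectral density estimate
#'
#' One-sided averaged periodogram: the series is split into overlapping
#' Hann-tapered segments, each linearly detrended, and the squared FFT
#' magnitudes are averaged. Scaling is such that `sum(psd) * df` equals
#' the variance of the tapered, detrended signal (Parseval within a few
#' percent for stationary inputs).
#'
#' @param series A [timeseries()] object.
#' @param nperseg Segment length in samples; default `min(1024, n)` clipped
#'   so at least one full segment fits.
#' @param overlap Fractional segment overlap (0.5 = 50%).
#' @param detrend Linearly detrend each segment before tapering.
#' @return A list of class `spectral_estimate` with `freqs` (Hz), `psd`
#'   ((unit)^2/Hz), `df`, `nperseg`, `overlap`, `n_segments`, `taper`.
#' @export
#' @examples
#' x <- gen_colored_noise(4096, fs = 1, beta = 0, sd = 1, seed = 1)
#' p <- estimate_psd(x)
estimate_psd <- function(series, nperseg = NULL, overlap = 0.5,
                         detrend = TRUE) {
  stopifnot_ts(series)
  n <- length(series$values)
  if (is.null(nperseg)) nperseg <- min(1024L, n)
  ws <- welch_segments(series$values, series$fs, nperseg, overlap, detrend)
  scale <- one_sided_scale(length(ws$freqs), ws$nperseg)
  psd <- rowMeans(Mod(ws$coef)^2) * scale
  structure(
    list(freqs = ws$freqs, psd = psd, df = series$fs / ws$nperseg,
         nperseg = ws$nperseg, overlap = overlap,
         n_segments = ws$n_segments, taper = "hann"),
    class = "spectral_estimate"
  )
}

#' Fit a power law to a PSD on log-log axes
#'
#' Ordinary least squares of `log10(psd)` on `log10(f)` restricted to a
#' frequency band, giving the spectral exponent: slope -1 is pink noise,
#' -2 brown, 0 white. Zero-power and zero-frequency bins are excluded.
#'
#' @param spec A `spectral_estimate` (from [estimate_psd()]) or any list
#'   with `freqs` and `psd`.
#' @param band Two-element frequency band `[f_lo, f_hi]` in Hz.
#' @return A list of class `slope_fit`: `slope`, `intercept`, `stderr`
#'   (OLS standard error of the slope), `band`, `n_points`.
#' @export
fit_psd_slope <- function(spec, band = c(0.01, 0.5)) {
  keep <- spec$freqs >= band[1] & spec$freqs <= band[2] &
    spec$freqs > 0 & spec$psd > 0
  if (sum(keep) < 3L)
    stop("need at least 3 in-band points with positive power", call. = FALSE)
  lf <- log10(spec$freqs[keep])
  lp <- log10(spec$psd[keep])
  fit <- stats::lm(lp ~ lf)
  sm <- summary(fit)$coefficients
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         stderr = unname(sm["lf", "Std. Error"]),
         band = band, n_points = sum(keep)),
    class = "slope_fit"
  )
}

#' Short-time Fourier spectrogram in dB
#'
#' Magnitude-squared STFT with the Welch segmentation (Hann taper, 50%
#' overlap by default), converted to decibels relative to a reference
#' power of 1 (unit)^2/Hz. Frequency resolution is `fs/window`.
#'
#' @param series A [timeseries()] object.
#' @param window Segment length in samples (1024 gives about 0.001 Hz
#'   resolution at 1 Hz sampling).
#' @param overlap Fractional overlap between segments.
#' @param floor_db Guard value replacing `-Inf` for zero-power cells.
#' @return A list of class `protodyn_spectrogram`: `times` (segment
#'   centers, s), `freqs` (Hz), `psd_db` (freq x time matrix), `psd`
#'   (linear), `window`, `dt` (segment spacing, s), `df`.
#' @export
spectrogram <- function(series, window = 1024L, overlap = 0.5,
                        floor_db = -120) {
  stopifnot_ts(series)
  n <- length(series$values)
  if (window > n) stop("window longer than the series", call. = FALSE)
  ws <- welch_segments(series$values, series$fs, window, overlap,
                       detrend = TRUE)
  scale <- one_sided_scale(length(ws$freqs), ws$nperseg)
  psd <- Mod(ws$coef)^2 * scale
  db <- 10 * log10(psd)
  db[!is.finite(db)] <- floor_db
  db[db < floor_db] <- floor_db
  centers <- series$times[1] +
    (seq_len(ws$n_segments) - 1L) * ws$hop / series$fs +
    (ws$nperseg - 1L) / (2 * series$fs)
  structure(
    list(times = centers, freqs = ws$freqs, psd_db = db, psd = psd,
         window = ws$nperseg, dt = ws$hop / series$fs,
         df = series$fs / ws$nperseg),
    class = "protodyn_spectrogram"
  )
}

#' Total signal energy from a spectrogram
#'
#' Double Riemann sum of the linear-scale PSD over the time-frequency
#' grid with `df * dt` cell weights. Quadratic in signal amplitude.
#'
#' @param sgram A [spectrogram()] result.
#' @return Scalar energy, (unit)^2 * s / Hz * Hz * s collapsed to
#'   (unit)^2 * s.
#' @export
total_energy <- function(sgram) {
  stopifnot(inherits(sgram, "protodyn_spectrogram"))
  sum(sgram$psd) * sgram$df * sgram$dt
}

#' Magnitude-squared coherence of two signals
#'
#' `C_xy(f) = |G_xy|^2 / (G_xx * G_yy)` with Welch cross- and auto-spectra
#' sharing the same segmentation. Values lie in [0, 1]; 1 means perfect
#' linear frequency-domain synchronization. A single segment would give
#' identically 1 and is refused; with `m` independent segments the noise
#' floor of the estimate is about `1/m`.
#'
#' @param x,y [timeseries()] objects on a common time axis.
#' @param nperseg Segment length in samples; default chooses
#'   `min(1024, 2^floor(log2(n/4)))` so at least ~8 half-overlapping
#'   segments average.
#' @param overlap Fractional overlap.
#' @return A list of class `coherence_result`: `freqs`, `msc`,
#'   `n_segments`.
#' @export
msc <- function(x, y, nperseg = NULL, overlap = 0.5) {
  stopifnot_ts(x); stopifnot_ts(y)
  if (length(x) != length(y) || max(abs(x$times - y$times)) > 1e-9)
    stop("series must share a common time axis (align first)", call. = FALSE)
  n <- length(x$values)
  if (is.null(nperseg))
    nperseg <- max(8L, min(1024L, 2^floor(log2(n / 4))))
  wx <- welch_segments(x$values, x$fs, nperseg, overlap)
  wy <- welch_segments(y$values, y$fs, nperseg, overlap)
  if (wx$n_segments < 2L)
    stop("coherence needs at least 2 averaging segments", call. = FALSE)
  gxx <- rowMeans(Mod(wx$coef)^2)
  gyy <- rowMeans(Mod(wy$coef)^2)
  gxy <- rowMeans(wx$coef * Conj(wy$coef))
  denom <- gxx * gyy
  c2 <- ifelse(denom > 0, Mod(gxy)^2 / denom, 0)
  c2 <- pmin(pmax(c2, 0), 1)
  structure(list(freqs = wx$freqs, msc = c2, n_segments = wx$n_segments),
            class = "coherence_result")
}

#' Normalized cross-correlation over lags
#'
#' Discrete correlation `R(tau) = sum_t x(t) * y(t - tau)` over the
#' overlapping samples at each lag, normalized by the overlap length, for
#' lags up to +/- n/2 samples. The lag of the maximum identifies the
#' delay of `y` relative to `x`.
#'
#' @param input,response [timeseries()] objects on a common axis.
#' @param max_lag Maximum lag in samples (default `n %/% 2`).
#' @return A list with `table` (data frame: `lag_samples`, `lag_s`,
#'   `value`) and `peak_lag_s` (lag of the maximum, seconds).
#' @export
cross_correlation <- function(input, response, max_lag = NULL) {
  stopifnot_ts(input); stopifnot_ts(response)
  if (length(input) != length(response) ||
      max(abs(input$times - response$times)) > 1e-9)
    stop("series must share a common time axis (align first)", call. = FALSE)
  x <- input$values; y <- response$values
  n <- length(x)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  lags <- (-max_lag):max_lag
  # positive lag = response delayed relative to input
  vals <- vapply(lags, function(L) {
    if (L >= 0) {
      idx <- 1L:(n - L)
      mean(x[idx] * y[idx + L])
    } else {
      idx <- (1L - L):n
      mean(x[idx] * y[idx + L])
    }
  }, numeric(1))
  tab <- data.frame(lag_samples = lags, lag_s = lags / input$fs,
                    value = vals)
  list(table = tab, peak_lag_s = tab$lag_s[which.max(tab$value)])
}
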