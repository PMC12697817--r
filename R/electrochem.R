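## Electrochemical model fits: exponential decay of SWV peak current with
## pulse frequency, Randles equivalent-circuit impedance, capacitance
## memory (autocorrelation time constant and dynamic decay), and the
## early/late two-sample t-test on a capacitance trace.

new_decay_fit <- function(y0, rate, offset, r2, se = c(NA_real_, NA_real_),
                          degenerate = FALSE) {
  structure(
    list(y0 = y0, rate = rate, offset = offset, r2 = r2,
         characteristic = if (rate > 0) 1 / rate else Inf,
         se_y0 = se[1], se_rate = se[2], degenerate = degenerate),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y0=%.6g rate=%.6g (1/rate=%.6g) offset=%.6g R2=%.4f\n",
              x$y0, x$rate, x$characteristic, x$offset, x$r2))
  invisible(x)
}

#' Fit an exponential decay
#'
#' Nonlinear least squares of `y = y0 * exp(-rate * x) [+ offset]`
#' (Levenberg-Marquardt). The same shape serves the peak-current vs
#' frequency relation (`I0`, `alpha`; characteristic frequency
#' `fc = 1/alpha`), the capacitance decay (`C0`, `k`; memory duration
#' `tau = 1/k`) and the autocorrelation fit. Initialization: offset from
#' `min(y)` (offset variant, else 0), `y0` from `max(y) - offset`, and
#' the rate from a log-linear regression on the positive part of
#' `y - offset`.
#'
#' @param x Grid values (frequency in Hz or time in s).
#' @param y Observed values.
#' @param with_offset Add a constant offset term (needs >= 4 points).
#' @return A list of class `decay_fit`: `y0`, `rate`, `offset`, `r2`,
#'   `characteristic` (`1/rate`), `se_y0`, `se_rate`, `degenerate`.
#' @export
#' @examples
#' d <- gen_decay_series(decay_spec(179.54, 0.0032, seq(5, 50, 5)))
#' fit_exponential_decay(d$x, d$y)$characteristic  # 312.5
fit_exponential_decay <- function(x, y, with_offset = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  need <- if (with_offset) 4L else 3L
  if (length(x) < need)
    stop(sprintf("need at least %d points", need), call. = FALSE)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (max(y) == min(y)) {
    warning("constant response: degenerate fit with rate 0")
    return(new_decay_fit(y[1], 0, if (with_offset) 0 else 0, 1,
                         degenerate = TRUE))
  }
  off0 <- if (with_offset) min(y) else 0
  pos <- y - off0 > 0
  rate0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(y[pos] - off0 + 1e-12 * max(abs(y))) ~
                                  x[pos]))[2]
    max(abs(sl), 1e-12)
  } else 1 / (max(x) - min(x) + 1e-12)
  y00 <- max(y) - off0
  df <- data.frame(x = x, y = y)
  fit <- NULL
  dx <- min(diff(sort(unique(x))))
  starts <- list(c(y00, rate0, off0), c(y00, rate0 / 10, off0),
                 c(y00, rate0 * 10, off0), c(y00, 1 / dx, off0),
                 c(y00, 5 / dx, off0))
  for (st in starts) {
    fit <- tryCatch({
      if (with_offset)
        minpack.lm::nlsLM(y ~ y0 * exp(-rate * x) + offset, data = df,
                          start = list(y0 = st[1], rate = st[2],
                                       offset = st[3]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      else
        minpack.lm::nlsLM(y ~ y0 * exp(-rate * x), data = df,
                          start = list(y0 = st[1], rate = st[2]),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
    }, error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential fit did not converge after bounded restarts",
         call. = FALSE)
  co <- stats::coef(fit)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  se <- if (is.null(sm)) c(NA_real_, NA_real_)
        else c(sm["y0", "Std. Error"], sm["rate", "Std. Error"])
  resid <- stats::resid(fit)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  rate <- unname(co["rate"])
  if (rate < 0) {
    # growing response: report as degenerate decay
    warning("fitted rate is negative: not a decay")
  }
  if (abs(rate) < 1e-15) warning("rate pinned at 0: degenerate fit")
  new_decay_fit(unname(co["y0"]), rate,
                if (with_offset) unname(co["offset"]) else 0,
                r2, se, degenerate = abs(rate) < 1e-15)
}

#' Percent attenuation between two peak currents
#'
#' `100 * (i_low_f - i_high_f) / i_low_f`: the relative drop of peak
#' current from the low-frequency to the high-frequency end of a sweep.
#'
#' @param i_low_f Peak current at the low-frequency reference, uA (> 0).
#' @param i_high_f Peak current at the high-frequency end, uA.
#' @return Attenuation in percent.
#' @export
#' @examples
#' percent_attenuation(176.10, 154.30)  # 12.38 -> prints as 12.4%
percent_attenuation <- function(i_low_f, i_high_f) {
  if (i_low_f <= 0) stop("reference current must be > 0", call. = FALSE)
  100 * (i_low_f - i_high_f) / i_low_f
}

#' Randles-circuit impedance at one frequency
#'
#' `Z(w) = Rs + Rct / (1 + j w Rct Cdl) + W / sqrt(j w)` with
#' `w = 2 pi f` and the principal square root. With `W = 0` the spectrum
#' traces a semicircle of diameter `Rct` in the Nyquist plane.
#'
#' @param Rs Solution resistance, Ohm (>= 0).
#' @param Rct Charge transfer resistance, Ohm (>= 0).
#' @param Cdl Double layer capacitance, F (>= 0).
#' @param W Warburg coefficient, Ohm s^(-1/2) (>= 0).
#' @param f Frequency, Hz (> 0).
#' @return Complex impedance, Ohm.
#' @export
randles_impedance <- function(Rs, Rct, Cdl, W, f) {
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  if (any(c(Rs, Rct, Cdl, W) < 0))
    stop("circuit parameters must be >= 0", call. = FALSE)
  w <- 2 * pi * f
  Rs + Rct / (1 + 1i * w * Rct * Cdl) + W / sqrt(1i * w)
}

#' Relaxation frequency of the charge-transfer arc
#'
#' `f0 = 1 / (2 pi Rct Cdl)`: the frequency at the apex of the Nyquist
#' semicircle, separating the capacitive and resistive regimes.
#'
#' @param Rct Charge transfer resistance, Ohm (> 0).
#' @param Cdl Double layer capacitance, F (> 0).
#' @return Frequency in Hz.
#' @export
relaxation_frequency <- function(Rct, Cdl) {
  if (Rct <= 0 || Cdl <= 0)
    stop("Rct and Cdl must be > 0", call. = FALSE)
  1 / (2 * pi * Rct * Cdl)
}

#' Descriptive summary of an impedance spectrum
#'
#' Means, SDs and 95% confidence intervals (mean +/- 1.96 sd/sqrt(n)) of
#' the real part, imaginary part, log10 impedance magnitude and phase
#' angle (degrees) across the spectrum rows.
#'
#' @param spectrum Data frame with columns `f_Hz`, `Zre_ohm`, `Zim_ohm`
#'   (as produced by [gen_randles_spectrum()]).
#' @return A list of class `eis_summary` with `mean_zre`, `sd_zre`,
#'   `ci95_zre`, `mean_zim`, `sd_zim`, `mean_logmag`, `sd_logmag`,
#'   `ci95_logmag`, `mean_phase`, `sd_phase`, `n`.
#' @export
eis_summary <- function(spectrum) {
  need <- c("f_Hz", "Zre_ohm", "Zim_ohm")
  if (!all(need %in% names(spectrum)))
    stop("spectrum must have columns f_Hz, Zre_ohm, Zim_ohm", call. = FALSE)
  n <- nrow(spectrum)
  if (n < 2L) stop("need at least 2 spectrum rows", call. = FALSE)
  z <- complex(real = spectrum$Zre_ohm, imaginary = spectrum$Zim_ohm)
  logmag <- log10(Mod(z))
  phase <- Arg(z) * 180 / pi
  ci <- function(v) mean(v) + c(-1, 1) * 1.96 * stats::sd(v) / sqrt(n)
  structure(
    list(mean_zre = mean(spectrum$Zre_ohm), sd_zre = stats::sd(spectrum$Zre_ohm),
         ci95_zre = ci(spectrum$Zre_ohm),
         mean_zim = mean(spectrum$Zim_ohm), sd_zim = stats::sd(spectrum$Zim_ohm),
         mean_logmag = mean(logmag), sd_logmag = stats::sd(logmag),
         ci95_logmag = ci(logmag),
         mean_phase = mean(phase), sd_phase = stats::sd(phase), n = n),
    class = "eis_summary"
  )
}

#' Memory time constant from the autocorrelation function
#'
#' Biased sample autocorrelation (n denominator) of the mean-removed
#' series over lags 0..n/4, fitted with `R(lag) = A exp(-lag/tau) + C`.
#' `tau` (the `characteristic` field) is the memory duration: how long
#' the signal remains correlated with its past.
#'
#' @param series A [timeseries()] with at least 256 samples.
#' @return A `decay_fit` whose `rate` is `1/tau` (per second) and
#'   `characteristic` is `tau` (s), plus the fitted `A` (`y0`) and
#'   offset `C`.
#' @export
memory_from_autocorrelation <- function(series) {
  stopifnot_ts(series)
  n <- length(series$values)
  if (n < 256L) stop("need at least 256 samples", call. = FALSE)
  lag_max <- n %/% 4L
  ac <- stats::acf(series$values, lag.max = lag_max, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags_s <- (0:lag_max) / series$fs
  fit_exponential_decay(lags_s, ac, with_offset = TRUE)
}

#' Fit the dynamic capacitance decay
#'
#' Fits `C(t) = C0 * exp(-k t)` (pure decay, no offset) to a capacitance
#' trace; the memory duration is `tau = 1/k`.
#'
#' @param series A capacitance [timeseries()] (unit `"F"`) with at least
#'   16 samples, predominantly positive values.
#' @return A `decay_fit` with `y0 = C0`, `rate = k`,
#'   `characteristic = tau`.
#' @export
fit_dynamic_decay <- function(series) {
  stopifnot_ts(series)
  if (length(series$values) < 16L)
    stop("need at least 16 samples", call. = FALSE)
  if (mean(series$values > 0) < 0.5)
    stop("capacitance trace must be predominantly positive", call. = FALSE)
  fit_exponential_decay(series$times - series$times[1], series$values,
                        with_offset = FALSE)
}

#' Early/late two-sample t-test on a recording
#'
#' Splits the series at `split_fraction` of its length and compares the
#' early and late segment means with a two-sided pooled-variance
#' two-sample t-test. `delta` is `mean(late) - mean(early)`, e.g. the
#' capacitance change over the recording.
#'
#' @param series A [timeseries()] object.
#' @param split_fraction Fraction of samples in the early segment.
#' @return A list of class `ttest_result`: `t_stat`, `p_value`, `n1`,
#'   `n2`, `delta`.
#' @export
early_late_ttest <- function(series, split_fraction = 0.5) {
  stopifnot_ts(series)
  n <- length(series$values)
  n1 <- floor(n * split_fraction)
  if (n1 < 2L || n - n1 < 2L)
    stop("each segment needs at least 2 samples", call. = FALSE)
  early <- series$values[1:n1]
  late <- series$values[(n1 + 1L):n]
  if (stats::sd(early) == 0 && stats::sd(late) == 0 &&
      mean(early) == mean(late))
    return(structure(list(t_stat = 0, p_value = 1, n1 = n1, n2 = n - n1,
                          delta = 0), class = "ttest_result"))
  tt <- stats::t.test(late, early, var.equal = TRUE)
  structure(
    list(t_stat = unname(tt$statistic), p_value = tt$p.value,
         n1 = n1, n2 = n - n1, delta = mean(late) - mean(early)),
    class = "ttest_result"
  )
}
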