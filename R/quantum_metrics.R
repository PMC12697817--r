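## Coherence statistics: binned Shannon entropy of the voltage
## distribution, the variance-based quantum Fisher information proxy
## F_Q = 4 Var(V) S(f) with spectral sensitivity S(f) = 1/(2 pi f)^2,
## and Hilbert-transform envelope/phase analysis.

#' Binned Shannon entropy of a signal's value distribution
#'
#' Histogram over `[min, max]` with `bins` equal-width bins; cell
#' probabilities are counts over n; entropy is `-sum(p log2 p)` in bits,
#' with empty bins contributing zero. Maximum is `log2(bins)` for a
#' uniform distribution. The result is invariant under affine transforms
#' of the data because the bin edges move with it.
#'
#' @param values Numeric vector (at least 2 samples; at least `bins`
#'   recommended for a stable estimate).
#' @param bins Number of histogram bins.
#' @return A list of class `entropy_result`: `entropy` (bits), `bins`,
#'   `bin_edges`, `probs`.
#' @export
#' @examples
#' shannon_entropy(rep(c(0, 1), 50), bins = 2)$entropy  # 1 bit
shannon_entropy <- function(values, bins = 50L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    warning("degenerate range: constant input has zero entropy")
    edges <- c(rng[1], rng[2])
    return(structure(list(entropy = 0, bins = as.integer(bins),
                          bin_edges = edges, probs = 1),
                     class = "entropy_result"))
  }
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  counts <- graphics::hist(values, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  p <- counts / length(values)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  structure(list(entropy = h, bins = as.integer(bins), bin_edges = edges,
                 probs = p),
            class = "entropy_result")
}

#' Quantum Fisher information proxy
#'
#' Classical surrogate for frequency sensitivity:
#' `F_Q = 4 * Var(V) * S(f)` with `S(f) = 1/(2 pi f)^2`, so larger
#' signal variance and lower frequency both raise the proxy. Units are
#' mV^2 s^2 when the variance is in mV^2 and f in Hz.
#'
#' @param variance Signal variance, mV^2 (>= 0).
#' @param f Frequency, Hz (> 0).
#' @return The proxy value `4 * variance / (2 pi f)^2`.
#' @export
#' @examples
#' qfi(68.42^2, 0.063)  # about 1.19e5
qfi <- function(variance, f) {
  if (any(f <= 0)) stop("frequency must be > 0", call. = FALSE)
  if (any(variance < 0)) stop("variance must be >= 0", call. = FALSE)
  4 * variance / (2 * pi * f)^2
}

#' QFI curves over a frequency grid, normalized across a compared set
#'
#' Evaluates the proxy for each series (or supplied variance) on a shared
#' frequency grid, then divides every curve by the single global maximum
#' across the whole set. Because each curve is `4 var / (2 pi f)^2`, the
#' normalized peak of series i equals `var_i / max_j var_j`: the peaks
#' reproduce the variance ratios exactly, independent of the grid.
#'
#' @param series_set A named list of [timeseries()] objects, or a named
#'   numeric vector of variances (mV^2).
#' @param freqs Frequency grid, Hz, all > 0 (default 0.01 to 0.5 Hz).
#' @return A list of class `qfi_result`: `freqs`, `variance` (named),
#'   `qfi` (matrix, frequency x series), `qfi_normalized` (same shape,
#'   global max 1), `peaks` (named normalized peak per series),
#'   `mean_normalized` (named mean of each normalized curve).
#' @export
#' @examples
#' qfi_curve(c(exp1 = 102.72^2, exp2 = 80.69^2, exp3 = 68.42^2))$peaks
qfi_curve <- function(series_set, freqs = seq(0.01, 0.5, by = 0.005)) {
  if (length(series_set) == 0L) stop("empty series set", call. = FALSE)
  if (any(freqs <= 0)) stop("all grid frequencies must be > 0",
                            call. = FALSE)
  if (is.list(series_set)) {
    vars <- vapply(series_set, function(s) {
      stopifnot_ts(s); stats::var(s$values)
    }, numeric(1))
  } else {
    vars <- as.numeric(series_set)
    names(vars) <- names(series_set)
  }
  if (is.null(names(vars)) || any(!nzchar(names(vars))))
    names(vars) <- paste0("series", seq_along(vars))
  q <- outer(freqs, vars, function(f, v) qfi(v, f))
  colnames(q) <- names(vars)
  qn <- q / max(q)
  structure(
    list(freqs = freqs, variance = vars, qfi = q, qfi_normalized = qn,
         peaks = apply(qn, 2, max), mean_normalized = colMeans(qn)),
    class = "qfi_result"
  )
}

# Discrete analytic signal: FFT, zero the negative frequencies, double
# the positive ones, inverse FFT.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert-transform envelope and instantaneous phase
#'
#' Forms the analytic signal via the discrete Hilbert transform; the
#' envelope is its modulus and the instantaneous phase the unwrapped
#' argument. The phase variance is computed on the linearly detrended
#' unwrapped phase (the raw phase of any oscillation grows linearly and
#' would otherwise dominate); small values indicate phase-stable,
#' narrowband oscillation.
#'
#' @param series A baseline-subtracted [timeseries()] with at least 64
#'   samples.
#' @return A list of class `hilbert_result`: `envelope` ([timeseries()]),
#'   `phase` (radians, unwrapped, [timeseries()]), `phase_variance`
#'   (rad^2), `phase_slope` (rad/s, the linear trend, `2 pi f0` for a
#'   pure tone).
#' @export
hilbert_analysis <- function(series) {
  stopifnot_ts(series)
  n <- length(series$values)
  if (n < 64L) stop("need at least 64 samples", call. = FALSE)
  z <- analytic_signal(series$values)
  env <- Mod(z)
  ph <- signal::unwrap(Arg(z))
  fit <- stats::lm.fit(cbind(1, series$times), ph)
  structure(
    list(envelope = timeseries(series$times, env, unit = series$unit,
                               label = paste0(series$label, " envelope")),
         phase = timeseries(series$times, ph, unit = "rad",
                            label = paste0(series$label, " phase")),
         phase_variance = stats::var(fit$residuals),
         phase_slope = unname(fit$coefficients[2])),
    class = "hilbert_result"
  )
}
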