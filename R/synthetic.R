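## Seeded synthetic inputs with the statistical structure the analysis
## assumes: baseline-offset sinusoids on 1/f^beta noise, exponential
## decays, and Randles impedance spectra.

# Run `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Generate seeded 1/f^beta colored noise
#'
#' Spectral synthesis: independent Gaussian Fourier coefficients are scaled
#' by `f^(-beta/2)`, the DC bin is zeroed (zero mean by construction), the
#' spectrum is inverted and the result rescaled to the target standard
#' deviation. The one-sided PSD therefore follows `f^(-beta)` in
#' expectation, which is exactly what the power-law slope fit assumes.
#'
#' @param n Number of samples (at least 16).
#' @param fs Sampling rate, Hz.
#' @param beta Spectral exponent (0 = white, 2 = brown); must be >= 0.
#' @param sd Target standard deviation of the series, signal units.
#' @param seed Integer seed; the same seed gives a bit-identical series.
#' @param unit Unit tag for the output series.
#' @return A [timeseries()] object of length `n` starting at t = 0.
#' @export
#' @examples
#' x <- gen_colored_noise(1024, fs = 1, beta = 2, sd = 10, seed = 1)
gen_colored_noise <- function(n, fs = 1, beta = 0, sd = 1, seed = 1,
                              unit = "mV") {
  n <- as.integer(n)
  if (n < 16L) stop("need n >= 16", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  x <- with_seed(seed, {
    nf <- n %/% 2L
    f <- (1:nf) * fs / n
    amp <- f^(-beta / 2)
    # positive-frequency coefficients; Nyquist bin (even n) kept real
    re <- stats::rnorm(nf) * amp
    im <- stats::rnorm(nf) * amp
    if (n %% 2L == 0L) im[nf] <- 0
    half <- complex(real = re, imaginary = im)
    spec <- complex(length.out = n)
    spec[2:(nf + 1L)] <- half
    if (n %% 2L == 0L) {
      if (nf > 1L) spec[n:(n - nf + 2L)] <- Conj(half[1:(nf - 1L)])
    } else {
      spec[n:(n - nf + 1L)] <- Conj(half)
    }
    Re(stats::fft(spec, inverse = TRUE)) / n
  })
  s <- stats::sd(x)
  if (s > 0 && sd > 0) x <- x * (sd / s) else x <- x * 0
  timeseries(seq(0, by = 1 / fs, length.out = n), x, unit = unit,
             label = sprintf("colored noise beta=%g", beta))
}

#' Specification of a synthetic oscillation recording
#'
#' Defaults emulate the spontaneous oscillations of the conjugate
#' recordings: a dominant component in the 0.03-0.11 Hz band with
#' hundreds-of-mV peak-to-peak amplitude, a tens-of-mV baseline offset,
#' slow linear drift, and steep (`beta` around 3-4) colored background
#' noise, all sampled at 1 Hz.
#'
#' @param fs Sampling rate, Hz.
#' @param duration Recording length, seconds.
#' @param f0 Dominant frequency, Hz; must satisfy `0 < f0 < fs/2`.
#' @param amp Peak-to-peak amplitude of the sinusoid, mV.
#' @param baseline Constant offset, mV.
#' @param drift_rate Linear drift, mV per second.
#' @param noise_beta Spectral exponent of the background noise.
#' @param noise_sd Standard deviation of the background noise, mV.
#' @param seed Integer seed.
#' @return A list of class `oscillation_spec`.
#' @export
oscillation_spec <- function(fs = 1, duration = 4096, f0 = 0.063,
                             amp = 325, baseline = 24, drift_rate = 0,
                             noise_beta = 3.5, noise_sd = 20, seed = 1) {
  if (!(f0 > 0 && f0 < fs / 2))
    stop("need 0 < f0 < fs/2", call. = FALSE)
  if (amp < 0) stop("amp must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (noise_beta < 0) stop("noise_beta must be >= 0", call. = FALSE)
  structure(list(fs = fs, duration = duration, f0 = f0, amp = amp,
                 baseline = baseline, drift_rate = drift_rate,
                 noise_beta = noise_beta, noise_sd = noise_sd, seed = seed),
            class = "oscillation_spec")
}

#' Generate a synthetic oscillation recording
#'
#' Realizes `baseline + drift_rate*t + (amp/2)*sin(2*pi*f0*t)` plus
#' seeded colored noise per the spec.
#'
#' @param spec An [oscillation_spec()].
#' @return A [timeseries()] in mV.
#' @export
#' @examples
#' ts <- gen_oscillation(oscillation_spec(f0 = 0.1, noise_sd = 0, seed = 2))
gen_oscillation <- function(spec) {
  if (!inherits(spec, "oscillation_spec"))
    stop("expected an oscillation_spec", call. = FALSE)
  n <- max(2L, as.integer(round(spec$duration * spec$fs)))
  t <- seq(0, by = 1 / spec$fs, length.out = n)
  x <- spec$baseline + spec$drift_rate * t +
    (spec$amp / 2) * sin(2 * pi * spec$f0 * t)
  if (spec$noise_sd > 0) {
    noise <- gen_colored_noise(n, fs = spec$fs, beta = spec$noise_beta,
                               sd = spec$noise_sd, seed = spec$seed)
    x <- x + noise$values
  }
  timeseries(t, x, unit = "mV",
             label = sprintf("synthetic oscillation f0=%g Hz", spec$f0))
}

#' Specification of a noisy exponential decay
#'
#' Houses the initial value and decay constant of the two exponential
#' relationships in the pipeline: peak current vs pulse frequency
#' (`I0`, `alpha`) and capacitance vs time (`C0`, `k`).
#'
#' @param y0 Initial value (uA or F); must be > 0.
#' @param rate Decay constant (per Hz or per s); must be >= 0.
#' @param grid Numeric vector of sample points (frequencies or times).
#' @param noise_sd Gaussian noise SD in the units of `y0`.
#' @param seed Integer seed.
#' @return A list of class `decay_spec`.
#' @export
decay_spec <- function(y0, rate, grid, noise_sd = 0, seed = 1) {
  if (y0 <= 0) stop("y0 must be > 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(y0 = y0, rate = rate, grid = as.numeric(grid),
                 noise_sd = noise_sd, seed = seed),
            class = "decay_spec")
}

#' Generate samples of an exponential decay
#'
#' `y_i = y0 * exp(-rate * x_i) + N(0, noise_sd)`, seeded.
#'
#' @param spec A [decay_spec()].
#' @return A data frame with columns `x` and `y`.
#' @export
gen_decay_series <- function(spec) {
  if (!inherits(spec, "decay_spec"))
    stop("expected a decay_spec", call. = FALSE)
  y <- spec$y0 * exp(-spec$rate * spec$grid)
  if (spec$noise_sd > 0)
    y <- y + with_seed(spec$seed,
                       stats::rnorm(length(spec$grid), 0, spec$noise_sd))
  data.frame(x = spec$grid, y = y)
}

#' Forward Randles-circuit impedance spectrum
#'
#' Solution resistance in series with a charge-transfer resistance in
#' parallel with the double-layer capacitance, plus a Warburg diffusion
#' element: `Z(w) = Rs + Rct/(1 + j*w*Rct*Cdl) + W/sqrt(j*w)`, `w = 2*pi*f`.
#'
#' @param Rs Solution resistance, Ohm.
#' @param Rct Charge transfer resistance, Ohm.
#' @param Cdl Double layer capacitance, F.
#' @param W Warburg coefficient, Ohm s^(-1/2); 0 disables diffusion.
#' @param freqs Vector of frequencies, Hz, all > 0.
#' @return A data frame with columns `f_Hz`, `Zre_ohm`, `Zim_ohm`.
#' @export
#' @examples
#' gen_randles_spectrum(100, 5000, 1e-6, 0, 10^seq(-1, 4, length.out = 5))
gen_randles_spectrum <- function(Rs, Rct, Cdl, W = 0, freqs) {
  z <- vapply(freqs, function(f) randles_impedance(Rs, Rct, Cdl, W, f),
              complex(1))
  data.frame(f_Hz = freqs, Zre_ohm = Re(z), Zim_ohm = Im(z))
}
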