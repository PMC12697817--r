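test_that("Welch PSD satisfies Parseval and flags short input", {
  x <- gen_colored_noise(2^14, fs = 1, beta = 0, sd = 1, seed = 2)
  p <- estimate_psd(x)
  expect_true(all(p$psd >= 0))
  expect_true(all(diff(p$freqs) > 0))
  # white noise: integrated PSD equals the variance within 5%
  expect_equal(sum(p$psd) * p$df, var(x$values), tolerance = 0.05)
  # flat spectrum
  expect_lt(abs(fit_psd_slope(p, c(0.01, 0.5))$slope), 0.15)

  # sinusoid: spectral peak integrates to A^2/2
  tone <- make_tone(8192, f0 = 0.1, amp = 3)
  pt <- estimate_psd(tone)
  expect_equal(sum(pt$psd) * pt$df, 3^2 / 2, tolerance = 0.05)

  # constant series: essentially no power after detrending
  flat <- estimate_psd(timeseries(0:2047, rep(5, 2048)))
  expect_lt(sum(flat$psd) * flat$df, 1e-18)

  expect_error(estimate_psd(make_tone(100), nperseg = 256), "shorter")
})

test_that("power-law slope fit matches closed form and recovers beta", {
  # exact power law: slope -2 with ~zero stderr
  f <- seq(0.01, 0.5, by = 0.005)
  sf <- suppressWarnings(  # lm flags the residual-free fit
    fit_psd_slope(list(freqs = f, psd = f^(-2)), c(0.01, 0.5)))
  expect_equal(sf$slope, -2, tolerance = 1e-10)
  expect_lt(sf$stderr, 1e-10)
  expect_gte(sf$n_points, 3)

  x <- gen_colored_noise(2^15, fs = 1, beta = 3.5, sd = 1, seed = 5)
  sl <- fit_psd_slope(estimate_psd(x), c(0.01, 0.5))$slope
  expect_lt(abs(sl + 3.5), 0.3)

  # scale invariance: multiplying the signal shifts only the intercept
  x2 <- timeseries(x$times, 10 * x$values)
  f1 <- fit_psd_slope(estimate_psd(x), c(0.01, 0.5))
  f2 <- fit_psd_slope(estimate_psd(x2), c(0.01, 0.5))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-9)
  expect_equal(f2$intercept - f1$intercept, 2, tolerance = 1e-9)

  expect_error(fit_psd_slope(list(freqs = f[1:2], psd = f[1:2]^-1)),
               "at least 3")
})

test_that("spectrogram shows stationary noise, tone ridges, and a dB floor", {
  x <- gen_colored_noise(2^13, fs = 1, beta = 0, sd = 1, seed = 3)
  sg <- spectrogram(x, window = 1024)
  expect_equal(sg$df, 1 / 1024)
  # stationary: per-frequency mean dB similar across early vs late halves
  halves <- ncol(sg$psd_db) %/% 2
  d <- mean(sg$psd_db[, 1:halves]) - mean(sg$psd_db[, -(1:halves)])
  expect_lt(abs(d), 1)

  tone <- make_tone(4096, f0 = 0.1, amp = 5)
  sgt <- spectrogram(tone, window = 1024)
  ridge <- apply(sgt$psd, 2, function(col) sgt$freqs[which.max(col)])
  expect_true(all(abs(ridge - 0.1) < 1 / 1024))

  silent <- timeseries(0:2047, rep(0, 2048))
  sgs <- spectrogram(silent, window = 1024)
  expect_true(all(sgs$psd_db == -120))

  expect_error(spectrogram(make_tone(100), window = 1024), "longer")
})

test_that("total energy scales quadratically with amplitude", {
  base <- make_tone(4096, f0 = 0.1, amp = 1)
  energies <- sapply(c(1, 2, 4), function(a) {
    ts <- timeseries(base$times, a * base$values)
    total_energy(spectrogram(ts, window = 1024))
  })
  expect_equal(energies[2] / energies[1], 4, tolerance = 1e-9)
  expect_equal(energies[3] / energies[1], 16, tolerance = 1e-9)
  expect_equal(total_energy(spectrogram(timeseries(0:2047, rep(0, 2048)),
                                        window = 1024)), 0)
})

test_that("energy of disjoint halves adds up within taper edge effects", {
  x <- gen_colored_noise(2^13, fs = 1, beta = 1, sd = 1, seed = 9)
  full <- total_energy(spectrogram(x, window = 512))
  h1 <- timeseries(x$times[1:4096], x$values[1:4096])
  h2 <- timeseries(x$times[4097:8192], x$values[4097:8192])
  parts <- total_energy(spectrogram(h1, window = 512)) +
    total_energy(spectrogram(h2, window = 512))
  expect_equal(parts, full, tolerance = 0.1)
})

test_that("MSC is bounded, symmetric, 1 for identical signals, low for independent ones", {
  x <- gen_colored_noise(2^13, fs = 1, beta = 0, sd = 1, seed = 1)
  y <- gen_colored_noise(2^13, fs = 1, beta = 0, sd = 1, seed = 2)

  self <- msc(x, x, nperseg = 512)
  expect_true(all(abs(self$msc - 1) < 1e-9))

  m1 <- msc(x, y, nperseg = 256)
  m2 <- msc(y, x, nperseg = 256)
  expect_equal(m1$msc, m2$msc, tolerance = 1e-12)
  expect_true(all(m1$msc >= 0 & m1$msc <= 1))
  # independent signals: mean coherence near the 1/m bias floor
  expect_lt(mean(m1$msc), 2.5 / m1$n_segments)

  # delayed copy stays coherent
  lagged <- timeseries(x$times, c(rep(0, 5), x$values[1:(8192 - 5)]))
  md <- msc(x, lagged, nperseg = 512)
  band <- md$freqs > 0.02 & md$freqs < 0.4
  expect_gt(median(md$msc[band]), 0.95)

  short <- timeseries(0:599, rnorm(600))
  expect_error(msc(short, short, nperseg = 512), "2 averaging segments")
  expect_error(msc(x, make_tone(8192, fs = 2)), "common time axis")
})

test_that("cross-correlation peaks at the injected delay", {
  x <- gen_colored_noise(2^11, fs = 1, beta = 2, sd = 1, seed = 4)
  cc <- cross_correlation(x, x)
  expect_equal(cc$peak_lag_s, 0)

  shifted <- timeseries(x$times, c(rep(0, 10), x$values[1:(2048 - 10)]))
  expect_equal(cross_correlation(x, shifted, max_lag = 50)$peak_lag_s, 10)

  # orthogonal sinusoids over integer periods: R(0) ~ 0
  t <- 0:999
  s1 <- timeseries(t, sin(2 * pi * 0.01 * t))
  s2 <- timeseries(t, cos(2 * pi * 0.01 * t))
  r0 <- cross_correlation(s1, s2, max_lag = 0)$table$value
  expect_lt(abs(r0), 1e-3)
})
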