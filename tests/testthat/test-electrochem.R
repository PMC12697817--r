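test_that("exponential fit recovers noiseless parameters and two-point closed form", {
  d <- gen_decay_series(decay_spec(179.54, 0.0032, seq(5, 50, 5)))
  fit <- fit_exponential_decay(d$x, d$y)
  expect_equal(fit$y0, 179.54, tolerance = 1e-6)
  expect_equal(fit$rate, 0.0032, tolerance = 1e-6)
  expect_equal(fit$characteristic, 312.5, tolerance = 1e-4)
  expect_equal(fit$characteristic * fit$rate, 1, tolerance = 1e-12)
  expect_gt(fit$r2, 0.9999)

  # closed form through two SWV endpoints
  rate2 <- log(176.10 / 154.30) / 45
  fit2 <- fit_exponential_decay(c(5, 50, 27.5),
                                c(176.10, 154.30,
                                  176.10 * (154.30 / 176.10)^0.5))
  expect_equal(fit2$rate, rate2, tolerance = 1e-6)

  expect_warning(flat <- fit_exponential_decay(1:10, rep(3, 10)),
                 "degenerate")
  expect_equal(flat$rate, 0)
  expect_error(fit_exponential_decay(1:2, c(2, 1)), "at least 3")
})

test_that("offset variant fits A exp(-t/tau) + C", {
  x <- seq(0, 200, by = 2)
  y <- 0.8 * exp(-x / 25) + 0.1
  fit <- fit_exponential_decay(x, y, with_offset = TRUE)
  expect_equal(fit$y0, 0.8, tolerance = 1e-6)
  expect_equal(fit$characteristic, 25, tolerance = 1e-6)
  expect_equal(fit$offset, 0.1, tolerance = 1e-6)
})

test_that("noisy recovery stays within the fit's own standard errors", {
  grid <- seq(5, 50, 5)
  ok_y0 <- ok_rate <- logical(20)
  for (s in 1:20) {
    d <- gen_decay_series(decay_spec(179.54, 0.0032, grid,
                                     noise_sd = 0.02 * 179.54, seed = s))
    f <- fit_exponential_decay(d$x, d$y)
    ok_y0[s] <- abs(f$y0 - 179.54) <= 3 * f$se_y0
    ok_rate[s] <- abs(f$rate - 0.0032) <= 3 * f$se_rate
  }
  expect_gte(mean(ok_y0), 0.95)
  expect_gte(mean(ok_rate), 0.95)
})

test_that("percent attenuation and relaxation frequency are the stated ratios", {
  expect_equal(round(percent_attenuation(176.10, 154.30), 1), 12.4)
  expect_equal(percent_attenuation(7, 7), 0)
  expect_equal(percent_attenuation(100, 50), 50)
  expect_error(percent_attenuation(0, 1), "> 0")

  expect_equal(relaxation_frequency(1, 1 / (2 * pi)), 1)
  expect_equal(relaxation_frequency(5250, 5.08e-8),
               1 / (2 * pi * 5250 * 5.08e-8))
  expect_equal(relaxation_frequency(100, 2e-6),
               relaxation_frequency(100, 1e-6) / 2)
  expect_error(relaxation_frequency(0, 1), "> 0")
})

test_that("Randles impedance limits and apex identity hold", {
  Rs <- 100; Rct <- 5000; Cdl <- 1e-6
  expect_equal(Re(randles_impedance(Rs, Rct, Cdl, 0, 1e9)), Rs,
               tolerance = 1e-3)
  expect_equal(Re(randles_impedance(Rs, Rct, Cdl, 0, 1e-9)), Rs + Rct,
               tolerance = 1e-3)
  z <- randles_impedance(Rs, Rct, Cdl, 0, 1 / (2 * pi * Rct * Cdl))
  expect_equal(Re(z), Rs + Rct / 2, tolerance = 1e-9)
  expect_equal(-Im(z), Rct / 2, tolerance = 1e-9)
  # Warburg adds a 45-degree low-frequency tail
  zw <- randles_impedance(Rs, Rct, Cdl, 50, 1e-4)
  expect_lt(Im(zw), Im(randles_impedance(Rs, Rct, Cdl, 0, 1e-4)))
  expect_error(randles_impedance(Rs, Rct, Cdl, 0, 0), "> 0")
})

test_that("EIS summary reports moments, CIs and degenerate spectra", {
  spec <- gen_randles_spectrum(100, 5000, 1e-6, 0,
                               10^seq(-1, 4, length.out = 30))
  s <- eis_summary(spec)
  expect_equal(s$mean_zre, mean(spec$Zre_ohm))
  expect_equal(s$sd_zim, sd(spec$Zim_ohm))
  expect_true(s$ci95_zre[1] <= s$mean_zre && s$mean_zre <= s$ci95_zre[2])
  expect_equal(s$mean_logmag,
               mean(log10(Mod(complex(real = spec$Zre_ohm,
                                      imaginary = spec$Zim_ohm)))))

  dup <- spec[c(1, 1), ]
  sd0 <- eis_summary(dup)
  expect_equal(sd0$sd_zre, 0)
  expect_equal(sd0$ci95_zre, rep(sd0$mean_zre, 2))

  # pure resistor: zero phase, constant magnitude
  res <- data.frame(f_Hz = c(1, 10, 100), Zre_ohm = 250, Zim_ohm = 0)
  sr <- eis_summary(res)
  expect_equal(sr$mean_phase, 0)
  expect_equal(sr$sd_logmag, 0)
  expect_error(eis_summary(spec[1, ]), "at least 2")
})

test_that("autocorrelation memory fit recovers AR(1) and white-noise limits", {
  set.seed(31)
  n <- 1e4; phi <- 0.95
  ar <- timeseries(seq_len(n) - 1, as.numeric(arima.sim(list(ar = phi), n)))
  fit <- memory_from_autocorrelation(ar)
  expect_equal(fit$characteristic, -1 / log(phi), tolerance = 0.1)

  wn <- timeseries(0:4095, rnorm(4096))
  wfit <- memory_from_autocorrelation(wn)
  expect_lt(wfit$characteristic, 2)
  expect_equal(wfit$y0 + wfit$offset, 1, tolerance = 0.1)

  expect_error(memory_from_autocorrelation(make_tone(100)), "256")
})

test_that("dynamic decay fit recovers the capacitance model exactly", {
  tt <- seq(0, 2e6, by = 4000)
  k <- 3.103103e-6
  cs <- timeseries(tt, 5.273669e-8 * exp(-k * tt), unit = "F")
  fit <- fit_dynamic_decay(cs)
  expect_equal(fit$y0, 5.273669e-8, tolerance = 1e-6)
  expect_equal(fit$rate, k, tolerance = 1e-6)
  expect_equal(fit$characteristic, 1 / k, tolerance = 1e-6)

  expect_warning(const <- fit_dynamic_decay(timeseries(0:19, rep(1e-8, 20),
                                                       unit = "F")),
                 "degenerate")
  expect_equal(const$rate, 0)
})

test_that("memory fit on a decaying trace is consistent with 1/k", {
  set.seed(17)
  tt <- seq(0, 4000)
  k <- 1 / 500
  x <- exp(-k * tt) + rnorm(length(tt), 0, 0.005)
  fit <- memory_from_autocorrelation(timeseries(tt, x))
  expect_equal(fit$characteristic, 1 / k, tolerance = 0.15)
})

test_that("early/late pooled t-test detects shifts with the right sign", {
  same <- timeseries(0:199, rep(c(1, 2), 100))
  r <- early_late_ttest(same)
  expect_lt(abs(r$t_stat), 1e-9)
  expect_gt(r$p_value, 0.99)
  expect_equal(r$n1 + r$n2, 200)

  set.seed(6)
  shifted <- timeseries(0:199, c(rnorm(100, 0, 0.1), rnorm(100, 5, 0.1)))
  rs <- early_late_ttest(shifted)
  expect_lt(rs$p_value, 1e-6)
  expect_gt(rs$delta, 0)
  expect_gt(rs$t_stat, 0)

  down <- timeseries(0:199, c(rnorm(100, 5, 0.1), rnorm(100, 0, 0.1)))
  expect_lt(early_late_ttest(down)$delta, 0)

  # matches the pooled-variance oracle from stats::t.test
  x <- rnorm(60); y <- rnorm(140, 0.3)
  ts <- timeseries(0:199, c(x, y))
  r2 <- early_late_ttest(ts, split_fraction = 0.3)
  oracle <- t.test(y, x, var.equal = TRUE)
  expect_equal(r2$t_stat, unname(oracle$statistic))
  expect_equal(r2$p_value, oracle$p.value)
  expect_error(early_late_ttest(timeseries(0:3, 1:4), 0.25), "2 samples")
})
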