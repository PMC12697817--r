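test_that("CSV round trip preserves a clean series and infers fs", {
  path <- write_ts_csv(0:2, c(1, 2, 3))
  ts <- read_timeseries(path)
  expect_equal(ts$fs, 1)
  expect_equal(ts$values, c(1, 2, 3))
  expect_equal(ts$times, c(0, 1, 2))

  # writer emits the same dialect the reader consumes
  out <- tempfile(fileext = ".csv")
  write_timeseries(ts, out)
  expect_equal(read_timeseries(out)$values, ts$values)
})

test_that("non-numeric cells are marked missing and linearly interpolated", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0,1.0", "1,", "2,3.0"), path)
  ts <- read_timeseries(path)
  expect_equal(ts$values[2], 2.0)

  # leading/trailing gaps fill with the nearest finite value
  path2 <- tempfile(fileext = ".csv")
  writeLines(c("time_s,value", "0,", "1,5", "2,7", "3,"), path2)
  ts2 <- read_timeseries(path2)
  expect_equal(ts2$values, c(5, 5, 7, 7))
})

test_that("malformed inputs raise informative errors", {
  path <- write_ts_csv(0:2, c(1, 2, 3))
  expect_error(read_timeseries(path, value_column = "nope"), "column")
  expect_error(read_timeseries(tempfile()), "not found")
  bad <- write_ts_csv(c(0, 1, 1), c(1, 2, 3))
  expect_error(read_timeseries(bad), "index 3")
  one_row <- write_ts_csv(0, 1)
  expect_error(read_timeseries(one_row), "2 rows")
})

test_that("common-axis interpolation clamps, preserves shared points, and is identity for one series", {
  a <- timeseries(0:9, (0:9)^2)
  b <- timeseries(0:4, 2 * (0:4))
  expect_equal(interpolate_common_axis(list(a))[[1]]$values, a$values)

  out <- interpolate_common_axis(list(a, b))
  expect_equal(out[[2]]$times, a$times)
  # shared points exact, extension clamps at B(4) = 8
  expect_equal(out[[2]]$values[1:5], b$values)
  expect_equal(out[[2]]$values[6:10], rep(8, 5))

  # downsampling a 2 Hz series to the 1 Hz axis equals its even samples
  b2 <- timeseries(seq(0, 9, by = 0.5), sin(seq(0, 9, by = 0.5)))
  a1 <- timeseries(0:9, rep(0, 10))
  out2 <- interpolate_common_axis(list(b2, a1))
  # longest series (b2) defines the axis; check direct interpolation oracle
  oracle <- approx(b2$times, b2$values, xout = b2$times)$y
  expect_equal(out2[[1]]$values, oracle)
  expect_error(interpolate_common_axis(list()), "non-empty")
})

test_that("baseline subtraction averages the initial window and is idempotent", {
  const <- timeseries(0:29, rep(24, 30))
  rep1 <- subtract_baseline(const)
  expect_equal(rep1$baseline, 24)
  expect_equal(rep1$adjusted$values, rep(0, 30))

  ramp <- timeseries(0:29, 0:29)
  expect_equal(subtract_baseline(ramp)$baseline, 4.5)

  # mean of the first window of the adjusted series is 0
  ts <- make_tone(100, 0.07, offset = 12)
  adj <- subtract_baseline(ts)$adjusted
  expect_lt(abs(mean(adj$values[ts$times < 10])), 1e-9)

  # idempotent
  twice <- subtract_baseline(adj)
  expect_equal(twice$adjusted$values, adj$values)
  expect_error(subtract_baseline(timeseries(0:5, 0:5), 10), "shorter")
})

test_that("baseline ignores marked-missing values in the window", {
  v <- c(0:9, rnorm(20))
  v[3] <- NA
  ts <- structure(list(times = as.numeric(0:29), values = v, unit = "mV",
                       label = "", fs = 1), class = "protodyn_ts")
  expect_equal(subtract_baseline(ts)$baseline, mean(v[1:10], na.rm = TRUE))
})

test_that("IQR outlier flags match a hand-computed oracle and are affine invariant", {
  expect_equal(iqr_outlier_flags(c(1, 2, 3, 4, 5)), rep(FALSE, 5))
  # type-7 quartiles of [1,2,3,4,100]: Q1=2, Q3=4, fences [-1, 7]
  expect_equal(iqr_outlier_flags(c(1, 2, 3, 4, 100)),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(iqr_outlier_flags(rep(3, 6)), rep(FALSE, 6))
  expect_error(iqr_outlier_flags(1:3), "at least 4")

  set.seed(42)
  for (i in 1:10) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- rnorm(1)
    expect_equal(iqr_outlier_flags(a * x + b), iqr_outlier_flags(x))
  }
})
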