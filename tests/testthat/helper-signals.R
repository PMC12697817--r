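# Shared fixture builders: everything is generated in code at test time.

make_tone <- function(n = 1024, f0 = 0.05, fs = 1, amp = 5, phase = 0,
                      offset = 0) {
  t <- seq(0, by = 1 / fs, length.out = n)
  timeseries(t, offset + amp * sin(2 * pi * f0 * t + phase), unit = "mV",
             label = sprintf("tone %g Hz", f0))
}

write_ts_csv <- function(times, values, path = tempfile(fileext = ".csv"),
                         time_col = "time_s", value_col = "value") {
  df <- data.frame(times, values)
  names(df) <- c(time_col, value_col)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

random_ascii <- function(len, printable_only = TRUE) {
  pool <- if (printable_only) 32:126 else 1:127
  intToUtf8(sample(pool, len, replace = TRUE))
}
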