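## ASCII pulse-train stimulus: each character is transmitted as its 8-bit
## code (MSB first), one 10 s pulse slot per bit, followed by a 10 s pause
## slot, so one character occupies a 90 s cycle.

#' Define a binary pulse-train stimulus program
#'
#' @param message Non-empty 7-bit ASCII text to transmit.
#' @param pulse_ms Duration of one bit slot, milliseconds.
#' @param pause_ms Pause appended after each character, milliseconds.
#' @param v_high,v_low Voltage levels for bit 1 / bit 0 and pauses, volts.
#' @param repeats Number of times the whole message is repeated.
#' @return A list of class `stimulus_program`.
#' @export
#' @examples
#' p <- stimulus_program("To be")
#' total_duration_ms(p)
stimulus_program <- function(message, pulse_ms = 10000, pause_ms = 10000,
                             v_high = 5, v_low = 0, repeats = 1L) {
  if (!is.character(message) || length(message) != 1L || !nzchar(message))
    stop("message must be a non-empty string", call. = FALSE)
  codes <- utf8ToInt(message)
  if (any(codes > 127L))
    stop("message must be 7-bit ASCII", call. = FALSE)
  if (pulse_ms <= 0 || pause_ms <= 0)
    stop("pulse_ms and pause_ms must be > 0", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  structure(list(message = message, pulse_ms = pulse_ms, pause_ms = pause_ms,
                 v_high = v_high, v_low = v_low, repeats = as.integer(repeats)),
            class = "stimulus_program")
}

#' Encode one ASCII character as 8 bits, MSB first
#'
#' @param c A single 7-bit ASCII character.
#' @return Integer vector of 8 bits, most significant first.
#' @export
#' @examples
#' char_to_bits("T")  # 0 1 0 1 0 1 0 0
char_to_bits <- function(c) {
  if (!is.character(c) || length(c) != 1L || nchar(c) != 1L)
    stop("expected a single character", call. = FALSE)
  code <- utf8ToInt(c)
  if (code > 127L) stop("non-ASCII character", call. = FALSE)
  as.integer(bitwAnd(bitwShiftR(code, 7:0), 1L))
}

bits_to_char <- function(bits) {
  intToUtf8(sum(bits * 2L^(7:0)))
}

#' Total stimulus duration in milliseconds
#'
#' `repeats * nchar(message) * (8 * pulse_ms + pause_ms)`: eight bit slots
#' plus one pause slot per character, including after the last character.
#'
#' @param program A [stimulus_program()].
#' @return Duration in milliseconds.
#' @export
total_duration_ms <- function(program) {
  stopifnot(inherits(program, "stimulus_program"))
  program$repeats * nchar(program$message) *
    (8 * program$pulse_ms + program$pause_ms)
}

#' Effective per-character cycle frequency
#'
#' One character occupies `8 * pulse_ms + pause_ms` milliseconds; the
#' reciprocal of that cycle is the effective input frequency (about
#' 0.0111 Hz at the default 10 s slots).
#'
#' @param program A [stimulus_program()].
#' @return Frequency in Hz.
#' @export
character_cycle_frequency <- function(program) {
  stopifnot(inherits(program, "stimulus_program"))
  1000 / (8 * program$pulse_ms + program$pause_ms)
}

#' Sample the stimulus waveform
#'
#' Piecewise-constant voltage: for each character, eight bit slots at
#' `v_high` (bit 1) or `v_low` (bit 0), then one pause slot at `v_low`.
#' Each slot contributes `slot_ms * fs / 1000` samples, which must be a
#' whole number.
#'
#' @param program A [stimulus_program()].
#' @param fs Sampling rate, Hz.
#' @return A [timeseries()] in volts starting at t = 0.
#' @export
stimulus_waveform <- function(program, fs = 1) {
  stopifnot(inherits(program, "stimulus_program"))
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  n_pulse <- program$pulse_ms * fs / 1000
  n_pause <- program$pause_ms * fs / 1000
  if (abs(n_pulse - round(n_pulse)) > 1e-9 ||
      abs(n_pause - round(n_pause)) > 1e-9)
    stop("slot durations must be whole numbers of samples at this fs",
         call. = FALSE)
  n_pulse <- round(n_pulse); n_pause <- round(n_pause)
  chars <- strsplit(program$message, "", fixed = TRUE)[[1]]
  one_pass <- unlist(lapply(chars, function(ch) {
    bits <- char_to_bits(ch)
    c(rep(ifelse(bits == 1L, program$v_high, program$v_low),
          each = n_pulse),
      rep(program$v_low, n_pause))
  }))
  v <- rep(one_pass, program$repeats)
  timeseries(seq(0, by = 1 / fs, length.out = length(v)), v, unit = "V",
             label = sprintf("stimulus '%s'", program$message))
}

#' Decode a pulse-train waveform back to text
#'
#' Inverse of [stimulus_waveform()] for waveforms sampled on the slot
#' grid. Each slot is read as its mean level and thresholded at
#' `(v_high + v_low)/2`; a slot mean exactly at the threshold is a format
#' error rather than a guess.
#'
#' @param series A [timeseries()] waveform in volts.
#' @param pulse_ms,pause_ms,v_high,v_low Timing and level parameters of the
#'   program that generated the waveform.
#' @return The decoded message (one repeat's worth per frame; repeats
#'   decode to the repeated text).
#' @export
decode_waveform <- function(series, pulse_ms = 10000, pause_ms = 10000,
                            v_high = 5, v_low = 0) {
  stopifnot_ts(series)
  fs <- series$fs
  n_pulse <- round(pulse_ms * fs / 1000)
  n_pause <- round(pause_ms * fs / 1000)
  frame <- 8L * n_pulse + n_pause
  n <- length(series$values)
  if (n %% frame != 0L)
    stop("waveform length is not a whole number of character frames",
         call. = FALSE)
  thr <- (v_high + v_low) / 2
  nchars <- n %/% frame
  out <- character(nchars)
  for (i in seq_len(nchars)) {
    off <- (i - 1L) * frame
    bits <- integer(8)
    for (b in 1:8) {
      slot <- series$values[(off + (b - 1L) * n_pulse + 1L):(off + b * n_pulse)]
      m <- mean(slot)
      if (m == thr)
        stop(sprintf("ambiguous slot level %.3g V at character %d bit %d",
                     m, i, b), call. = FALSE)
      bits[b] <- as.integer(m > thr)
    }
    out[i] <- bits_to_char(bits)
  }
  paste(out, collapse = "")
}

#' Amplitude-modulate a natural signal by an input waveform
#'
#' `output(t) = natural(t) * (1 + k_mod * input(t))`: the stimulus voltage
#' multiplicatively modulates the natural oscillation amplitude.
#'
#' @param natural Natural-oscillation [timeseries()] (mV).
#' @param input_wave Stimulus [timeseries()] (V) on the same time axis.
#' @param k_mod Dimensionless modulation coefficient.
#' @return Modulated [timeseries()] in the units of `natural`.
#' @export
modulate_response <- function(natural, input_wave, k_mod) {
  stopifnot_ts(natural); stopifnot_ts(input_wave)
  if (length(natural) != length(input_wave) ||
      max(abs(natural$times - input_wave$times)) > 1e-9)
    stop("series must share a common time axis (align first)", call. = FALSE)
  out <- natural
  out$values <- natural$values * (1 + k_mod * input_wave$values)
  out$label <- paste0(natural$label, " (modulated)")
  out
}
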