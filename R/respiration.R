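#' Band-pass filter for the respiration component
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The
#' default corner frequencies 0.07 Hz and 0.7 Hz correspond to a
#' respiratory range of roughly 4--40 breaths per minute.
#'
#' @param d Displacement series in mm.
#' @param fs Sampling rate in Hz (> `2 * high`).
#' @param low,high Corner frequencies in Hz.
#' @param order Filter design order (doubled effectively by the
#'   forward-backward pass).
#' @return Filtered series of the same length.
#' @export
bandpass_respiration <- function(d, fs, low = 0.07, high = 0.7, order = 4) {
  if (fs <= 2 * high) {
    rv_abort("fs must exceed twice the upper corner frequency",
             "radarvitals_invalid_argument")
  }
  if (length(d) / fs < 45) {
    rv_warn("section shorter than ~3 filter time constants; edge transients will dominate",
            "radarvitals_short_section")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, d))
}

#' Positive-to-negative zero crossings
#'
#' Emits a linearly interpolated crossing time for every adjacent sample
#' pair with `x[k] >= 0` and `x[k+1] < 0`.
#'
#' @param x Signal values.
#' @param t Sample times in seconds (defaults to a unit-step index).
#' @return Crossing times in seconds.
#' @export
zero_crossings_pos_neg <- function(x, t = seq_along(x) - 1) {
  k <- which(x[-length(x)] >= 0 & x[-1] < 0)
  if (!length(k)) return(numeric(0))
  t[k] + (t[k + 1] - t[k]) * x[k] / (x[k] - x[k + 1])
}

#' Breath-to-breath intervals from a displacement section
#'
#' The respiration chain: block-mean decimation to `target_fs` (numerical
#' conditioning of the very-low-frequency IIR design), zero-phase band-pass,
#' positive-to-negative zero-crossing detection, and interval conditioning
#' ([condition_intervals()]).
#'
#' @param d Displacement in mm, or a `displacement_signal`.
#' @param fs Sampling rate in Hz (taken from the object if `d` is a
#'   `displacement_signal`).
#' @param t0 Time of the first sample in seconds.
#' @param low,high,order Band-pass parameters, see [bandpass_respiration()].
#' @param target_fs Decimation target in Hz.
#' @return An [interval_series()] of breath-to-breath intervals.
#' @export
respiration_intervals <- function(d, fs = NULL, t0 = 0,
                                  low = 0.07, high = 0.7, order = 4,
                                  target_fs = 10) {
  if (inherits(d, "displacement_signal")) {
    fs <- d$fs
    t0 <- d$t[1]
    d <- d$d
  }
  if (is.null(fs)) {
    rv_abort("fs is required", "radarvitals_invalid_argument")
  }
  q <- max(1L, round(fs / target_fs))
  dd <- block_decimate(d, q)
  fsd <- fs / q
  t <- t0 + (seq_along(dd) - 0.5) * q / fs  # block centres
  filt <- suppressWarnings(bandpass_respiration(dd, fsd, low, high, order))
  events <- zero_crossings_pos_neg(filt, t)
  condition_intervals(events)
}
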