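# Signal-processing front end shared by the pulse detector, the TDOA
# estimator and the spectral measurements: band-pass filtering in the
# analysis band and the analytic-signal envelope.

#' Band-pass filter a waveform
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The
#' default band matches the spectral analysis band of the recording chain
#' (6-170 kHz): below ~5 kHz the ambient noise floor is elevated, above
#' 170 kHz the hydrophone response rolls off.
#'
#' @param x numeric waveform.
#' @param fs sampling rate in Hz.
#' @param band length-2 numeric, band edges in Hz.
#' @param order filter order (per pass).
#' @return filtered waveform, same length as `x`.
#' @export
band_pass <- function(x, fs, band = c(6e3, 170e3), order = 4) {
  stopifnot(length(band) == 2, band[1] > 0, band[2] > band[1])
  if (band[2] >= fs / 2) stop_arg("upper band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Analytic-signal envelope
#'
#' Magnitude of the analytic signal computed via the frequency domain
#' (one-sided spectrum doubling). The input is zero-padded to a
#' 2-3-5-smooth length for the FFT and truncated back.
#'
#' @param x numeric waveform (typically band-passed first).
#' @return non-negative envelope, same length as `x`.
#' @export
envelope <- function(x) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  n2 <- stats::nextn(n, c(2, 3, 5))
  xp <- c(x, numeric(n2 - n))
  X <- stats::fft(xp)
  h <- numeric(n2)
  if (n2 %% 2 == 0) {
    h[1] <- 1; h[n2 / 2 + 1] <- 1
    if (n2 > 2) h[2:(n2 / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n2 + 1) / 2)] <- 2
  }
  a <- stats::fft(X * h, inverse = TRUE) / n2
  Mod(a[seq_len(n)])
}

# local maxima indices of a numeric vector (strict on the right to break
# flat-top ties toward the earliest sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
}
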