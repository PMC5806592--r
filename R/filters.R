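#' Butterworth filtering with an explicit direction convention
#'
#' ABR work is sensitive to filter delays: causal filters preserve response
#' latencies at the cost of a small lag, zero-phase filters preserve peak
#' positions but smear energy backwards in time, and anti-causal filters are
#' appropriate only for stimulus audio (where pre-ringing ends up at positive
#' response lags, outside the region of interest). These helpers make the
#' direction an explicit argument everywhere instead of an implicit property
#' of the filtering routine used.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff corner frequency or frequencies (Hz).
#' @param order filter order.
#' @param type `"high"` or `"low"`.
#' @param direction `"causal"`, `"anticausal"`, or `"zerophase"`.
#' @return filtered numeric vector, same length as `x`.
#' @keywords internal
butter_apply <- function(x, fs, cutoff, order = 1L, type = c("high", "low"),
                         direction = c("causal", "anticausal", "zerophase")) {
  type <- match.arg(type)
  direction <- match.arg(direction)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2)) {
    stop("filter cutoff must lie strictly between 0 and the Nyquist frequency (",
         fs / 2, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = type)
  apply_iir(x, bf$b, bf$a, direction)
}

#' Apply an IIR filter in a given direction
#' @keywords internal
#' @noRd
apply_iir <- function(x, b, a, direction) {
  causal <- function(v) as.numeric(signal::filter(b, a, v))
  switch(direction,
    causal = causal(x),
    anticausal = rev(causal(rev(x))),
    zerophase = rev(causal(rev(causal(x))))
  )
}

#' Second-order IIR notch filter coefficients
#'
#' Standard biquad notch with a unit-circle zero at the notch frequency; the
#' `bandwidth` argument is the -3 dB bandwidth, i.e. quality factor
#' `Q = f0 / bandwidth`.
#'
#' @param f0 notch center frequency (Hz).
#' @param fs sampling rate (Hz).
#' @param bandwidth -3 dB bandwidth (Hz), default 5.
#' @return list with `b` and `a` coefficient vectors (length 3 each).
#' @export
iir_notch <- function(f0, fs, bandwidth = 5) {
  if (f0 <= 0 || f0 >= fs / 2) {
    stop("notch frequency must lie strictly between 0 and Nyquist", call. = FALSE)
  }
  w0 <- 2 * pi * f0 / fs
  q <- f0 / bandwidth
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

#' Magnitude response of a rational IIR filter
#'
#' @param b,a coefficient vectors.
#' @param f frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return magnitude (linear) at each frequency.
#' @export
iir_magnitude <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- outer(z, seq_along(b) - 1, `^`) %*% b
  den <- outer(z, seq_along(a) - 1, `^`) %*% a
  abs(as.vector(num / den))
}

#' Raised-cosine (Hann-flank) ramp
#' @keywords internal
#' @noRd
raised_cosine_ramp <- function(n) {
  if (n <= 0) return(numeric(0))
  0.5 * (1 - cos(pi * (seq_len(n) - 0.5) / n))
}

#' Periodic-symmetric Hann window of length n
#' @keywords internal
#' @noRd
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

# Next FFT-friendly length (5-smooth) at least n
#' @noRd
fft_length <- function(n) stats::nextn(n, c(2, 3, 5))
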