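#' Headphone-leakage impulse-response kernel
#'
#' Electromagnetic leakage from the headphone driver contaminates the EEG at
#' a fixed lag relative to the audio. Because acoustic time zero is defined
#' at the eardrum after the earphone sound-tube delay, the electrical
#' artifact *precedes* it: it sits near -0.9 ms. The kernel is a 10-ms window
#' of lags centered there (-5.9 to +4.1 ms), Hann-windowed so its endpoints
#' vanish.
#'
#' @param impulse_response numeric vector, `round(0.010 * fs)` samples.
#' @param fs sampling rate (Hz).
#' @param center_ms window center lag (ms), default -0.9.
#' @param polynomial_order detrend order used during estimation.
#' @return an object of class `leakage_kernel` with a `lags_ms` grid.
#' @export
leakage_kernel <- function(impulse_response, fs, center_ms = -0.9,
                           polynomial_order = 6L) {
  n_win <- round(0.010 * fs)
  stopifnot(length(impulse_response) == n_win)
  l0 <- round((center_ms - 5) / 1000 * fs)
  structure(
    list(impulse_response = as.numeric(impulse_response), fs = fs,
         lags_ms = (l0 + seq_len(n_win) - 1) / fs * 1000,
         center_ms = center_ms, polynomial_order = polynomial_order),
    class = "leakage_kernel"
  )
}

#' @export
print.leakage_kernel <- function(x, ...) {
  cat(sprintf("<leakage_kernel> 10-ms window centered %.1f ms @ %g Hz, peak %.3g uV\n",
              x$center_ms, x$fs, max(abs(x$impulse_response))))
  invisible(x)
}

#' Estimate the leakage kernel by spectral division
#'
#' Per epoch, the EEG DFT is divided by the DFT of the raw *signed* audio
#' (not the rectified regressor) and inverse-transformed — an unregularized
#' estimate of the impulse response of the leakage path. That estimate is
#' cropped to the 10-ms window centered at -0.9 ms; speech has very little
#' energy below ~100 Hz, so the crop is dominated by low-frequency noise,
#' which is removed by fitting and subtracting a sixth-order polynomial over
#' the window. Per-epoch kernels are then averaged and the average multiplied
#' by a 10-ms Hann window. Frequency bins where the stimulus magnitude falls
#' below `1e-8` of its maximum are excluded from the division (with a
#' warning) rather than amplified.
#'
#' @param epochs an [eeg_epochs()] object (speech trials).
#' @param audio_epochs list of signed audio vectors at the EEG rate, one per
#'   epoch (e.g. from [resample_waveform()]); shorter-than-epoch audio is
#'   zero-padded.
#' @param center_ms artifact lag (ms), default -0.9.
#' @param poly_order detrend polynomial order, default 6.
#' @return a [leakage_kernel()].
#' @export
estimate_leakage <- function(epochs, audio_epochs, center_ms = -0.9,
                             poly_order = 6L) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  use <- which(epochs$usable)
  stopifnot(length(audio_epochs) == nrow(epochs$data), length(use) >= 1)
  fs <- epochs$fs
  n <- ncol(epochs$data)
  n_win <- round(0.010 * fs)
  l0 <- round((center_ms - 5) / 1000 * fs)
  lag_idx <- ifelse(l0:(l0 + n_win - 1) >= 0,
                    l0:(l0 + n_win - 1) + 1L,
                    n + l0:(l0 + n_win - 1) + 1L)
  tt <- seq_len(n_win) / n_win  # polynomial support over the window
  warned <- FALSE
  acc <- numeric(n_win)
  for (k in use) {
    x <- audio_epochs[[k]]
    if (length(x) > n) stop("audio epoch longer than EEG epoch", call. = FALSE)
    X <- stats::fft(c(x, numeric(n - length(x))))
    Y <- stats::fft(epochs$data[k, ])
    q <- Y / X
    dead <- Mod(X) < 1e-8 * max(Mod(X))
    if (any(dead)) {
      if (!warned) {
        warning("excluded ", sum(dead), " near-zero stimulus bin(s) from the ",
                "spectral division")
        warned <- TRUE
      }
      q[dead] <- 0
    }
    h <- Re(stats::fft(q, inverse = TRUE)) / n
    seg <- h[lag_idx]
    if (poly_order >= 1) {
      design <- cbind(1, stats::poly(tt, poly_order, simple = TRUE))
      seg <- stats::lm.fit(design, seg)$residuals
    }
    acc <- acc + seg
  }
  kern <- (acc / length(use)) * hann_window(n_win)
  leakage_kernel(kern, fs, center_ms = center_ms, polynomial_order = poly_order)
}

#' Subtract the leakage artifact from EEG epochs
#'
#' Convolves each epoch's signed audio with the estimated kernel — honoring
#' the kernel's negative-lag placement (the artifact precedes acoustic time
#' zero) — and subtracts the result from the EEG.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param kernel a [leakage_kernel()] at the same sampling rate.
#' @param audio_epochs the same signed audio epochs used for estimation.
#' @return the corrected `eeg_epochs`.
#' @export
subtract_leakage <- function(epochs, kernel, audio_epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(kernel, "leakage_kernel"))
  if (!isTRUE(all.equal(epochs$fs, kernel$fs))) {
    stop("kernel and epochs sampling rates differ", call. = FALSE)
  }
  stopifnot(length(audio_epochs) == nrow(epochs$data))
  fs <- epochs$fs
  n <- ncol(epochs$data)
  # linear convolution, then shift by the kernel's first (negative) lag so
  # the artifact precedes acoustic time zero; no circular wrap-around
  lag0 <- round(min(kernel$lags_ms) / 1000 * fs)
  prev_x <- NULL; prev_art <- NULL
  for (k in which(epochs$usable)) {
    x <- audio_epochs[[k]]
    if (!identical(x, prev_x)) {
      prev_art <- conv_linear(x, kernel$impulse_response)
      prev_x <- x
    }
    j <- max(1L, 1L + lag0):min(n, length(prev_art) + lag0)
    epochs$data[k, j] <- epochs$data[k, j] - prev_art[j - lag0]
  }
  epochs
}
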