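#' Locate Wave V in a derived response
#'
#' Wave V — the prominent positive ABR peak near 6 ms, principally generated
#' by the lateral lemniscus — is identified by smoothing the waveform with a
#' zero-phase 1-kHz low-pass and taking the maximum inside the search window
#' (default 5-7 ms). Ties break to the earliest lag.
#'
#' @param resp a [response_waveform()].
#' @param window search window (ms), default `c(5, 7)`.
#' @param smooth_lp zero-phase smoothing cutoff (Hz), default 1000; `NULL`
#'   skips smoothing.
#' @return list of class `wave_v` with `latency_ms`, `amplitude_uV` (smoothed
#'   waveform value at the peak, baseline-to-peak), and the settings.
#' @export
find_wave_v <- function(resp, window = c(5, 7), smooth_lp = 1000) {
  stopifnot(inherits(resp, "response_waveform"))
  if (window[1] < min(resp$lags_ms) || window[2] > max(resp$lags_ms)) {
    stop("search window outside the response lag range", call. = FALSE)
  }
  y <- resp$amplitude
  if (!is.null(smooth_lp)) {
    y <- butter_apply(y, resp$fs, smooth_lp, order = 1L, type = "low",
                      direction = "zerophase")
  }
  sel <- which(resp$lags_ms >= window[1] & resp$lags_ms <= window[2])
  peak <- sel[which.max(y[sel])]  # which.max returns the first maximum
  structure(list(latency_ms = resp$lags_ms[peak], amplitude_uV = y[peak],
                 search_window = window, smooth_lp = smooth_lp),
            class = "wave_v")
}

#' @export
print.wave_v <- function(x, ...) {
  cat(sprintf("<wave_v> %.2f ms, %.4g uV (window %g-%g ms)\n",
              x$latency_ms, x$amplitude_uV, x$search_window[1],
              x$search_window[2]))
  invisible(x)
}

#' Pearson morphology correlation between two responses over a lag window
#'
#' @param a,b [response_waveform()]s on identical lag grids over the window.
#' @param window lag window (ms), default `c(0, 20)`.
#' @return Pearson's r (scalar).
#' @export
correlate_window <- function(a, b, window = c(0, 20)) {
  ia <- a$lags_ms >= window[1] & a$lags_ms <= window[2]
  ib <- b$lags_ms >= window[1] & b$lags_ms <= window[2]
  if (!isTRUE(all.equal(a$lags_ms[ia], b$lags_ms[ib]))) {
    stop("responses must share the lag grid over the window", call. = FALSE)
  }
  stats::cor(a$amplitude[ia], b$amplitude[ib])
}

#' Evoked-response SNR from signal and noise lag windows
#'
#' \deqn{SNR = 10 \log_{10}[(\sigma^2_{ABR} - \sigma^2_{noise}) /
#' \sigma^2_{noise}]}
#' where the variances are computed (mean removed) over the response lag
#' window 0-20 ms and the pre-stimulus noise window -125 to -10 ms. Negative
#' lags cannot contain stimulus-driven activity, so their variance estimates
#' the noise remaining in the waveform; subtracting it from the signal-window
#' variance leaves the evoked part. When the signal-window variance does not
#' exceed the noise variance the SNR is undefined and `NA` is returned (not
#' clamped).
#'
#' @param resp a [response_waveform()] whose lags cover both windows.
#' @param signal_window,noise_window lag windows (ms).
#' @return list of class `snr_measurement` with `snr_db`, `var_abr`,
#'   `var_noise`, and the windows.
#' @export
response_snr <- function(resp, signal_window = c(0, 20),
                         noise_window = c(-125, -10)) {
  stopifnot(inherits(resp, "response_waveform"))
  var_win <- function(w) {
    i <- resp$lags_ms >= w[1] & resp$lags_ms <= w[2]
    if (!any(i)) stop("window outside response lags", call. = FALSE)
    stats::var(resp$amplitude[i])
  }
  v_abr <- var_win(signal_window)
  v_noise <- var_win(noise_window)
  snr <- if (v_abr > v_noise) 10 * log10((v_abr - v_noise) / v_noise) else NA_real_
  structure(list(snr_db = snr, var_abr = v_abr, var_noise = v_noise,
                 signal_window = signal_window, noise_window = noise_window),
            class = "snr_measurement")
}

#' @export
print.snr_measurement <- function(x, ...) {
  cat(sprintf("<snr_measurement> %s dB\n",
              if (is.na(x$snr_db)) "undefined (signal below noise floor)"
              else sprintf("%.2f", x$snr_db)))
  invisible(x)
}

#' SNR as a function of accumulated recording epochs
#'
#' Recomputes the deconvolved response from the first `n` epochs for each
#' `n`, and the SNR of each cumulative response. Under stationary noise the
#' curve should climb about 3 dB per doubling of recording time. Spectra are
#' accumulated incrementally, so the whole curve costs little more than the
#' full-data response.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param regressor matching [abr_regressor()].
#' @param lags lag range (ms) for the derived responses.
#' @param at epoch counts to evaluate; default every epoch from 2 up.
#' @param lp post-derivation low-pass (Hz) applied before SNR, default 2000.
#' @param signal_window,noise_window SNR windows (ms), see [response_snr()].
#' @param ... further arguments (e.g. `polarity`) passed to [deconvolve()].
#' @return data frame with `n_epochs`, `snr_db`, `var_abr`, `var_noise`.
#' @export
snr_curve <- function(epochs, regressor, lags = c(-150, 350), at = NULL,
                      lp = 2000, signal_window = c(0, 20),
                      noise_window = c(-125, -10), ...) {
  n_ep <- nrow(epochs$data)
  if (n_ep < 2) stop("need at least two epochs", call. = FALSE)
  if (is.null(at)) at <- 2:n_ep
  at <- sort(unique(as.integer(at)))
  stopifnot(all(at >= 1 & at <= n_ep))
  out <- data.frame(n_epochs = at, snr_db = NA_real_,
                    var_abr = NA_real_, var_noise = NA_real_)
  for (j in seq_along(at)) {
    sub <- subset_epochs(epochs, seq_len(at[j]))
    reg <- subset_regressor(regressor, seq_len(at[j]))
    resp <- postfilter_response(deconvolve(sub, reg, lags, ...), lp = lp)
    s <- response_snr(resp, signal_window, noise_window)
    out$snr_db[j] <- s$snr_db
    out$var_abr[j] <- s$var_abr
    out$var_noise[j] <- s$var_noise
  }
  out
}

#' Select a subset of epochs
#' @param epochs an [eeg_epochs()] object.
#' @param idx epoch indices to keep.
#' @return an `eeg_epochs` with the selected epochs.
#' @export
subset_epochs <- function(epochs, idx) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  out <- epochs
  out$data <- epochs$data[idx, , drop = FALSE]
  out$rejection_mask <- epochs$rejection_mask[idx, , drop = FALSE]
  out$n_rejected <- epochs$n_rejected[idx]
  out$g_r <- epochs$g_r[idx]
  out$usable <- epochs$usable[idx]
  out
}

#' Select a subset of regressor epochs
#' @param regressor an [abr_regressor()].
#' @param idx epoch indices to keep.
#' @return an `abr_regressor` with the selected epochs.
#' @export
subset_regressor <- function(regressor, idx) {
  stopifnot(inherits(regressor, "abr_regressor"))
  abr_regressor(regressor$pos[idx], regressor$neg[idx], regressor$fs_eeg,
                regressor$kind)
}

#' Split-half stability of a derived response
#'
#' Derives the response separately from two halves of the epochs and
#' correlates the two waveforms over a lag window. Splitting by epoch parity
#' (`"odd_even"`, default) balances slow drift across the halves; splitting
#' by session half (`"first_second"`) is sensitive to drift; an explicit
#' grouping vector supports condition splits such as narrator.
#'
#' @param epochs an [eeg_epochs()] object.
#' @param regressor matching [abr_regressor()].
#' @param split `"odd_even"`, `"first_second"`, or a length-`n_epochs` vector
#'   with two distinct values.
#' @param lags,lp,window response lags (ms), post low-pass (Hz), and
#'   correlation window (ms).
#' @param ... further arguments (e.g. `polarity`) passed to [deconvolve()].
#' @return list with `r`, the two [response_waveform()]s, and the split
#'   labels.
#' @export
split_half <- function(epochs, regressor, split = "odd_even",
                       lags = c(-150, 350), lp = 2000, window = c(0, 20),
                       ...) {
  n_ep <- nrow(epochs$data)
  groups <- if (is.character(split) && length(split) == 1) {
    switch(split,
      odd_even = (seq_len(n_ep) - 1) %% 2,
      first_second = as.integer(seq_len(n_ep) > n_ep / 2),
      stop("unknown split: ", split, call. = FALSE)
    )
  } else {
    as.integer(factor(split))
  }
  lev <- sort(unique(groups))
  if (length(lev) != 2) stop("split must produce exactly two groups", call. = FALSE)
  halves <- lapply(lev, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) stop("need at least two epochs per split", call. = FALSE)
    postfilter_response(
      deconvolve(subset_epochs(epochs, idx), subset_regressor(regressor, idx),
                 lags, ...),
      lp = lp)
  })
  list(r = correlate_window(halves[[1]], halves[[2]], window),
       responses = halves, groups = groups, window = window)
}
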