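#' Continuous single-channel EEG recording
#'
#' @param potential numeric vector of scalp potential in microvolts.
#' @param fs sampling rate (Hz), default 10000.
#' @param markers integer sample indices (1-based) of stimulus-epoch onsets.
#' @param channel_label free-text channel description.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(potential, fs = 10000, markers = integer(0),
                          channel_label = "EEG") {
  potential <- as.numeric(potential)
  if (anyNA(potential) || !all(is.finite(potential))) {
    stop("EEG contains NaN/Inf; refusing to load (excursion zeroing is the ",
         "only rejection mechanism in this pipeline)", call. = FALSE)
  }
  markers <- as.integer(markers)
  if (is.unsorted(markers)) stop("markers must be sorted", call. = FALSE)
  if (length(markers) && (min(markers) < 1 || max(markers) > length(potential))) {
    stop("markers outside the recording", call. = FALSE)
  }
  structure(
    list(potential = potential, fs = fs, markers = markers,
         channel_label = channel_label),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s: %.1f s @ %g Hz, %d marker(s)\n",
              x$channel_label, length(x$potential) / x$fs, x$fs,
              length(x$markers)))
  invisible(x)
}

#' Condition continuous EEG: causal high-pass and line-noise notches
#'
#' First-order Butterworth high-pass (default 1 Hz) followed by second-order
#' IIR notches at the line frequency and its odd harmonics (default 60, 180,
#' 300 Hz; -3 dB bandwidth 5 Hz). All filters are causal so that response
#' latencies are never smeared backwards in time.
#'
#' @param rec an [eeg_recording()].
#' @param hp high-pass cutoff (Hz); `NULL` skips the high-pass.
#' @param hp_order high-pass order, default 1.
#' @param notches notch center frequencies (Hz); `NULL` skips notching.
#' @param notch_bw -3 dB notch bandwidth (Hz), default 5.
#' @return filtered `eeg_recording`.
#' @export
filter_eeg <- function(rec, hp = 1, hp_order = 1L, notches = c(60, 180, 300),
                       notch_bw = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$potential
  if (!is.null(hp)) {
    x <- butter_apply(x, rec$fs, hp, order = hp_order, type = "high",
                      direction = "causal")
  }
  for (f0 in notches) {
    if (f0 >= rec$fs / 2) {
      stop("sampling rate too low for a ", f0, " Hz notch", call. = FALSE)
    }
    nf <- iir_notch(f0, rec$fs, bandwidth = notch_bw)
    x <- apply_iir(x, nf$b, nf$a, "causal")
  }
  out <- rec
  out$potential <- x
  out
}

#' Segment a recording into stimulus-locked epochs
#'
#' Each epoch starts at its onset marker and ends `tail_dur` (default 0.1 s)
#' after the end of its stimulus, so a 64-s speech stimulus yields a 64.1-s
#' epoch and a 30-s click train a 30.1-s epoch. A final epoch truncated by
#' the end of the record is an error, never silently padded.
#'
#' @param rec an [eeg_recording()] with one marker per stimulus.
#' @param stim_durations stimulus durations (s); recycled if length 1.
#' @param tail_dur extra time captured after stimulus end (s), default 0.1.
#' @return an object of class `eeg_epochs`: `data` (epochs x samples matrix,
#'   uV), `fs`, per-epoch bookkeeping fields (`n_rejected`, `g_r`,
#'   `usable`), and a logical `rejection_mask` matrix (TRUE = zeroed).
#' @export
epoch_recording <- function(rec, stim_durations, tail_dur = 0.1) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ep <- length(rec$markers)
  if (n_ep == 0) stop("recording has no epoch markers", call. = FALSE)
  stim_durations <- rep_len(stim_durations, n_ep)
  lens <- round((stim_durations + tail_dur) * rec$fs)
  if (length(unique(lens)) != 1) {
    stop("all epochs must have equal length (equal stimulus durations)", call. = FALSE)
  }
  n <- lens[1]
  data <- matrix(0, nrow = n_ep, ncol = n)
  for (k in seq_len(n_ep)) {
    s0 <- rec$markers[k]
    if (s0 + n - 1 > length(rec$potential)) {
      stop("epoch ", k, " extends past the end of the record", call. = FALSE)
    }
    data[k, ] <- rec$potential[s0:(s0 + n - 1)]
  }
  structure(
    list(data = data, fs = rec$fs, epoch_dur = n / rec$fs,
         rejection_mask = matrix(FALSE, n_ep, n),
         n_rejected = integer(n_ep), g_r = rep(1, n_ep),
         usable = rep(TRUE, n_ep), g_r_applied = FALSE),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epoch(s) x %.1f s @ %g Hz; %.2f%% samples zeroed\n",
              nrow(x$data), x$epoch_dur, x$fs,
              100 * mean(x$rejection_mask)))
  invisible(x)
}

#' Zero high-amplitude excursions and apply the corrective gain
#'
#' With continuous stimuli whole-epoch rejection would discard a minute of
#' data for one artifact, so instead every time the potential crosses
#' `threshold` a `window`-long segment centered on the offending sample is
#' zeroed (windows at epoch boundaries are clipped, not shifted). Zeroing
#' removes energy, which would bias the regression amplitude downward; each
#' epoch is therefore rescaled by the corrective gain
#' \deqn{g_r = N / (N - N_r)}
#' where `N` is the epoch sample count and `N_r` the number of distinct
#' zeroed samples. An epoch zeroed in full has undefined `g_r` and is flagged
#' unusable (excluded from response derivation) with a warning. The operation
#' is idempotent: zeroed samples are exactly 0 and cannot re-trigger.
#'
#' @param epochs an [epoch_recording()] result.
#' @param threshold excursion threshold (uV), default 100.
#' @param window zeroed segment duration (s), default 1.
#' @return the `eeg_epochs` with mask, `n_rejected`, `g_r`, `usable` updated
#'   and data scaled by `g_r`.
#' @export
zero_excursions <- function(epochs, threshold = 100, window = 1) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (window <= 0) stop("window must be positive", call. = FALSE)
  n <- ncol(epochs$data)
  half <- round(window * epochs$fs / 2)
  # undo a previously applied gain so the scan threshold refers to recorded uV
  if (epochs$g_r_applied) {
    ok <- epochs$usable & is.finite(epochs$g_r)
    epochs$data[ok, ] <- epochs$data[ok, , drop = FALSE] / epochs$g_r[ok]
  }
  for (k in seq_len(nrow(epochs$data))) {
    v <- epochs$data[k, ]
    bad <- which(abs(v) > threshold)
    mask <- epochs$rejection_mask[k, ]
    for (b in bad) {
      # exactly round(window * fs) samples when not clipped at an edge
      mask[max(1, b - half):min(n, b + half - 1L)] <- TRUE
    }
    v[mask] <- 0
    n_r <- sum(mask)
    epochs$rejection_mask[k, ] <- mask
    epochs$n_rejected[k] <- n_r
    if (n_r >= n) {
      warning("epoch ", k, " zeroed in full; flagged unusable")
      epochs$usable[k] <- FALSE
      epochs$g_r[k] <- NA_real_
      epochs$data[k, ] <- 0
    } else {
      epochs$g_r[k] <- n / (n - n_r)
      epochs$data[k, ] <- v * epochs$g_r[k]
    }
  }
  epochs$g_r_applied <- TRUE
  epochs
}
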