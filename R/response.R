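#' Deconvolved response waveform
#'
#' Amplitude (microvolts per unit regressor, or microvolts once normalized)
#' against lag in milliseconds on a uniform grid at the EEG rate. The
#' `provenance` list records how the waveform was produced (regressor kind,
#' filters applied, constituent conditions) so a result can be reproduced.
#'
#' @param amplitude numeric vector.
#' @param lags_ms lag grid (ms), uniform at `1000/fs`.
#' @param fs sampling rate (Hz).
#' @param provenance named list of processing details.
#' @param normalized has the cohort normalization factor been applied?
#' @return an object of class `response_waveform`.
#' @export
response_waveform <- function(amplitude, lags_ms, fs, provenance = list(),
                              normalized = FALSE) {
  stopifnot(length(amplitude) == length(lags_ms))
  structure(
    list(amplitude = as.numeric(amplitude), lags_ms = as.numeric(lags_ms),
         fs = fs, provenance = provenance, normalized = normalized),
    class = "response_waveform"
  )
}

#' @export
print.response_waveform <- function(x, ...) {
  cat(sprintf("<response_waveform> lags %.1f..%.1f ms @ %g Hz%s\n",
              min(x$lags_ms), max(x$lags_ms), x$fs,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Derive the evoked response by frequency-domain least squares
#'
#' The response is the set of weights over a lag range that best predicts the
#' EEG as a weighted sum of the regressor at those lags — the impulse
#' response of the auditory pathway under a linear-time-invariant assumption.
#' The regressor autocorrelation and the stimulus-response cross-correlation
#' are both computed via FFTs; cross-spectra and regressor power spectra are
#' accumulated over all usable epochs before the division, which solves the
#' least-squares problem over all epochs jointly. The regressors used here
#' are broadband, so no regularization is applied. Each polarity branch
#' (`pos`, `neg`) is solved independently and the two responses averaged.
#' Epochs are zero-padded by the lag span so the estimate is linear rather
#' than circular.
#'
#' Two ways of combining the polarity branches are provided. `"average"`
#' (the default) derives a response from each branch independently and
#' averages the two waveforms. `"joint"` solves the two-regressor
#' least-squares problem per frequency (2x2 normal equations accumulated
#' across epochs) and reports the sum of the two weight vectors — the
#' response to a simultaneous unit impulse in both branches, which is what a
#' click is. When the EEG really is a linear kernel applied to the mean of
#' the two branches (as in [forward_model()] simulations), the joint solver
#' recovers that kernel exactly, whereas the branch-averaged procedure
#' inherits a frequency-dependent bias from the cross-branch coherence; on
#' real recordings, where the rectification happens in the cochlea rather
#' than in the model, the averaged procedure is the conventional choice.
#' For impulse-train regressors the two branches are identical and both
#' options reduce to the same single regression.
#'
#' @param epochs an [eeg_epochs()] object (excursions zeroed, `g_r` applied).
#' @param regressor an [abr_regressor()] with one entry per epoch.
#' @param lags lag range `c(min, max)` in ms, default `c(-150, 350)`.
#' @param polarity `"average"` (independent branch solutions, averaged) or
#'   `"joint"` (two-column least squares, weights summed).
#' @return a [response_waveform()] over the requested lags.
#' @export
deconvolve <- function(epochs, regressor, lags = c(-150, 350),
                       polarity = c("average", "joint")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(epochs, "eeg_epochs"), inherits(regressor, "abr_regressor"))
  if (!isTRUE(all.equal(epochs$fs, regressor$fs_eeg))) {
    stop("epochs and regressor sampling rates differ", call. = FALSE)
  }
  n_ep <- nrow(epochs$data)
  if (length(regressor$pos) != n_ep) {
    stop("regressor epoch count (", length(regressor$pos),
         ") does not match EEG epoch count (", n_ep, ")", call. = FALSE)
  }
  use <- which(epochs$usable)
  if (!length(use)) stop("no usable epochs", call. = FALSE)
  fs <- epochs$fs
  l0 <- round(lags[1] / 1000 * fs)
  l1 <- round(lags[2] / 1000 * fs)
  n <- ncol(epochs$data)
  nfft <- fft_length(n + (l1 - l0) + 1L)

  pad_fft <- function(x) {
    if (length(x) > n) stop("regressor epoch longer than EEG epoch", call. = FALSE)
    stats::fft(c(x, numeric(nfft - length(x))))
  }
  # repeated regressor epochs (identical vectors) reuse their FFT
  cached_fft <- function() {
    last_x <- NULL; last_X <- NULL
    function(x) {
      if (!is.null(last_x) && identical(x, last_x)) return(last_X)
      last_x <<- x; last_X <<- pad_fft(x)
      last_X
    }
  }
  quotient <- function(num, den) {
    if (mean(den) <= nfft * 1e-24) {
      stop("regressor has (near-)zero total power; cannot deconvolve", call. = FALSE)
    }
    q <- num / den
    dead <- den < 1e-12 * max(den)
    if (any(dead)) {
      warning(sum(dead), " near-empty regressor frequency bin(s) excluded")
      q[dead] <- 0
    }
    Re(stats::fft(q, inverse = TRUE)) / nfft
  }

  same_branches <- identical(regressor$pos, regressor$neg)
  fft_p <- cached_fft(); fft_n <- cached_fft()
  if (same_branches) {
    num <- complex(nfft); den <- numeric(nfft)
    for (k in use) {
      X <- fft_p(regressor$pos[[k]])
      num <- num + Conj(X) * pad_fft(epochs$data[k, ])
      den <- den + Mod(X)^2
    }
    w <- quotient(num, den)
  } else if (polarity == "average") {
    nump <- numn <- complex(nfft)
    denp <- denn <- numeric(nfft)
    for (k in use) {
      Y <- pad_fft(epochs$data[k, ])
      Xp <- fft_p(regressor$pos[[k]])
      Xn <- fft_n(regressor$neg[[k]])
      nump <- nump + Conj(Xp) * Y; denp <- denp + Mod(Xp)^2
      numn <- numn + Conj(Xn) * Y; denn <- denn + Mod(Xn)^2
    }
    w <- (quotient(nump, denp) + quotient(numn, denn)) / 2
  } else {
    spp <- snn <- numeric(nfft)
    spn <- spy <- sny <- complex(nfft)
    for (k in use) {
      Y <- pad_fft(epochs$data[k, ])
      Xp <- fft_p(regressor$pos[[k]])
      Xn <- fft_n(regressor$neg[[k]])
      spp <- spp + Mod(Xp)^2
      snn <- snn + Mod(Xn)^2
      spn <- spn + Conj(Xp) * Xn
      spy <- spy + Conj(Xp) * Y
      sny <- sny + Conj(Xn) * Y
    }
    det <- spp * snn - Mod(spn)^2
    # Near-collinear bins (the two branches share their envelope, so their
    # coherence approaches 1 at low frequencies) make the 2x2 system
    # ill-conditioned and would amplify noise by spp*snn/det; such bins fall
    # back to regressing on the branch sum, which solves the same model with
    # a single well-conditioned column (and is exact for noiseless data).
    sing <- det < 0.05 * (spp * snn + 1e-300)
    wp <- (snn * spy - spn * sny) / det
    wn <- (spp * sny - Conj(spn) * spy) / det
    wsum_q <- (spy + sny) / (spp + snn + 2 * Re(spn))
    wj <- wp + wn
    wj[sing] <- 2 * wsum_q[sing]
    dead <- (spp + snn) < 1e-12 * max(spp + snn)
    if (any(dead)) {
      warning(sum(dead), " near-empty regressor frequency bin(s) excluded")
      wj[dead] <- 0
    }
    if (mean(spp + snn) <= nfft * 1e-24) {
      stop("regressor has (near-)zero total power; cannot deconvolve", call. = FALSE)
    }
    w <- Re(stats::fft(wj, inverse = TRUE)) / nfft
  }

  lag_idx <- ifelse(l0:l1 >= 0, (l0:l1) + 1L, nfft + (l0:l1) + 1L)
  response_waveform(
    amplitude = w[lag_idx],
    lags_ms = (l0:l1) / fs * 1000,
    fs = fs,
    provenance = list(method = "fft_least_squares",
                      regressor = regressor$kind,
                      polarity = if (same_branches) "single" else polarity,
                      n_epochs = length(use),
                      lags_ms = c(lags[1], lags[2]))
  )
}

#' Click-triggered average of EEG epochs
#'
#' The traditional way of computing an ABR: extract a fixed lag window around
#' every click and average. For unit-impulse regressors this coincides with
#' the least-squares deconvolution (exactly so when each epoch holds a single
#' impulse, statistically so for Poisson trains, whose expected power
#' spectrum is white).
#'
#' @param epochs an [eeg_epochs()] object.
#' @param click_indices list (one per epoch) of 1-based click sample indices
#'   at the EEG rate, or an impulse-train [abr_regressor()].
#' @param lags lag range `c(min, max)` in ms.
#' @return a [response_waveform()]; sweeps extending past an epoch edge are
#'   skipped.
#' @export
click_triggered_average <- function(epochs, click_indices, lags = c(-150, 350)) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (inherits(click_indices, "abr_regressor")) {
    stopifnot(click_indices$kind == "impulse_train")
    click_indices <- lapply(click_indices$pos, function(v) which(v == 1))
  }
  fs <- epochs$fs
  l0 <- round(lags[1] / 1000 * fs)
  l1 <- round(lags[2] / 1000 * fs)
  n <- ncol(epochs$data)
  acc <- numeric(l1 - l0 + 1)
  m_used <- 0L
  for (k in which(epochs$usable)) {
    for (ci in click_indices[[k]]) {
      if (ci + l0 < 1 || ci + l1 > n) next
      acc <- acc + epochs$data[k, (ci + l0):(ci + l1)]
      m_used <- m_used + 1L
    }
  }
  if (m_used == 0L) stop("no complete sweeps available", call. = FALSE)
  response_waveform(acc / m_used, (l0:l1) / fs * 1000, fs,
                    provenance = list(method = "click_triggered_average",
                                      n_sweeps = m_used))
}

#' Low-pass filter a derived response
#'
#' The derived response is low-pass filtered at 2 kHz (first-order
#' Butterworth) by default. The same operation with lower cutoffs exposes the
#' middle-latency (200 Hz) and late cortical (20 Hz) views of the very same
#' waveform. Causal by default, consistent with the EEG filtering convention;
#' a zero-phase option is provided.
#'
#' @param resp a [response_waveform()].
#' @param lp cutoff (Hz), default 2000; `NULL` returns the input unchanged.
#' @param order filter order, default 1.
#' @param direction `"causal"` (default) or `"zerophase"`.
#' @return filtered [response_waveform()].
#' @export
postfilter_response <- function(resp, lp = 2000, order = 1L,
                                direction = c("causal", "zerophase")) {
  stopifnot(inherits(resp, "response_waveform"))
  if (is.null(lp)) return(resp)
  direction <- match.arg(direction)
  y <- butter_apply(resp$amplitude, resp$fs, lp, order = order, type = "low",
                    direction = direction)
  out <- resp
  out$amplitude <- y
  out$provenance$postfilter <- list(lp_hz = lp, order = order,
                                    direction = direction)
  out
}

#' Average responses across conditions
#'
#' Responses to different conditions (e.g. the two narrators) are derived
#' separately and then averaged pointwise.
#'
#' @param responses list of [response_waveform()]s on identical lag grids.
#' @param weights optional weights; default equal.
#' @return a [response_waveform()].
#' @export
combine_conditions <- function(responses, weights = NULL) {
  stopifnot(length(responses) >= 1)
  lags <- responses[[1]]$lags_ms
  for (r in responses) {
    if (!isTRUE(all.equal(r$lags_ms, lags))) {
      stop("responses must share an identical lag grid", call. = FALSE)
    }
  }
  if (is.null(weights)) weights <- rep(1, length(responses))
  weights <- weights / sum(weights)
  amp <- Reduce(`+`, Map(function(r, w) r$amplitude * w, responses, weights))
  response_waveform(amp, lags, responses[[1]]$fs,
                    provenance = list(method = "combine_conditions",
                                      n_conditions = length(responses),
                                      weights = weights),
                    normalized = all(vapply(responses, `[[`, logical(1), "normalized")))
}

#' Cohort normalization factor between click and speech responses
#'
#' Because onsets dominate evoked activity and the linear model does not
#' capture that adaptation, raw speech-derived responses are much smaller
#' than click-evoked ones. A single empirical factor puts them on a
#' comparable scale:
#' \deqn{g_n = E_i(\sigma_{c,i}) / E_i(\sigma_{s,i})}
#' where \eqn{\sigma_{c,i}} and \eqn{\sigma_{s,i}} are the standard
#' deviations of subject i's click-evoked and speech-derived responses over
#' 0-20 ms and \eqn{E_i} is the mean over subjects. The value depends on the
#' digital audio scale (RMS 0.01 here) and is not transferable across
#' calibrations.
#'
#' @param click_resps,speech_resps lists of per-subject
#'   [response_waveform()]s, matched by position.
#' @param window lag window (ms) for the SDs, default `c(0, 20)`.
#' @return list of class `gn_factor` with `g_n`, `sigma_click`,
#'   `sigma_speech`, `window`.
#' @export
compute_gn <- function(click_resps, speech_resps, window = c(0, 20)) {
  stopifnot(length(click_resps) == length(speech_resps), length(click_resps) >= 1)
  sd_win <- function(r) {
    i <- r$lags_ms >= window[1] & r$lags_ms <= window[2]
    stats::sd(r$amplitude[i])
  }
  sc <- vapply(click_resps, sd_win, numeric(1))
  ss <- vapply(speech_resps, sd_win, numeric(1))
  if (mean(ss) == 0) stop("speech responses have zero SD in the window", call. = FALSE)
  structure(list(g_n = mean(sc) / mean(ss), sigma_click = sc,
                 sigma_speech = ss, window = window),
            class = "gn_factor")
}

#' @export
print.gn_factor <- function(x, ...) {
  cat(sprintf("<gn_factor> g_n = %.3g (n = %d subjects, %g-%g ms)\n",
              x$g_n, length(x$sigma_click), x$window[1], x$window[2]))
  invisible(x)
}

#' Apply the cohort normalization factor to a speech-derived response
#' @param resp a [response_waveform()].
#' @param gn a [compute_gn()] result (or a bare positive number).
#' @return the rescaled response, flagged `normalized = TRUE`.
#' @export
apply_gn <- function(resp, gn) {
  stopifnot(inherits(resp, "response_waveform"))
  g <- if (inherits(gn, "gn_factor")) gn$g_n else gn
  stopifnot(is.numeric(g), g > 0)
  out <- resp
  out$amplitude <- resp$amplitude * g
  out$normalized <- TRUE
  out$provenance$g_n <- g
  out
}

#' Traditional averaged ABR from periodic click trains
#'
#' The conventional measurement, for benchmarking: the continuous recording
#' is notch filtered, low-passed at 2 kHz, and high-passed with a causal
#' second-order Butterworth at 150 Hz (standard practice, canonical
#' waveform); per-click sweeps are epoched from -3 ms to the longest window
#' the periodic rate allows before temporal wrapping (`-3 + 1000/rate` ms,
#' i.e. 19.7 ms at 44.1 clicks/s); sweeps whose peak-to-peak amplitude
#' exceeds `reject_pp` are rejected; the rest are averaged.
#'
#' @param rec raw [eeg_recording()] with one marker per click-train epoch.
#' @param trains a [make_click_train()] or list of them (one per marker).
#' @param hp high-pass cutoff (Hz), default 150; order `hp_order` (2).
#' @param hp_order high-pass order, default 2.
#' @param lp low-pass cutoff (Hz), default 2000.
#' @param notches line-noise notch frequencies, default `c(60, 180, 300)`.
#' @param window_start sweep start lag (ms), default -3.
#' @param reject_pp peak-to-peak rejection threshold (uV), default 100.
#' @return a [response_waveform()] with `provenance$n_rejected` counting
#'   rejected sweeps.
#' @export
average_abr_traditional <- function(rec, trains, hp = 150, hp_order = 2L,
                                    lp = 2000, notches = c(60, 180, 300),
                                    window_start = -3, reject_pp = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (inherits(trains, "click_train")) {
    trains <- rep(list(trains), length(rec$markers))
  }
  stopifnot(length(trains) == length(rec$markers))
  rate <- trains[[1]]$rate
  window_end <- window_start + 1000 / rate
  filt <- filter_eeg(rec, hp = NULL, notches = notches)
  x <- butter_apply(filt$potential, rec$fs, lp, order = 1L, type = "low",
                    direction = "causal")
  x <- butter_apply(x, rec$fs, hp, order = hp_order, type = "high",
                    direction = "causal")
  fs <- rec$fs
  l0 <- round(window_start / 1000 * fs)
  l1 <- floor(window_end / 1000 * fs)
  acc <- numeric(l1 - l0 + 1)
  n_used <- 0L; n_rej <- 0L
  for (k in seq_along(rec$markers)) {
    idx <- rec$markers[k] + round(trains[[k]]$click_times * fs)
    for (ci in idx) {
      if (ci + l0 < 1 || ci + l1 > length(x)) next
      sweep <- x[(ci + l0):(ci + l1)]
      if (diff(range(sweep)) > reject_pp) { n_rej <- n_rej + 1L; next }
      acc <- acc + sweep
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("all sweeps rejected", call. = FALSE)
  response_waveform(acc / n_used, (l0:l1) / fs * 1000, fs,
                    provenance = list(method = "traditional_average",
                                      hp_hz = hp, hp_order = hp_order,
                                      lp_hz = lp, n_sweeps = n_used,
                                      n_rejected = n_rej,
                                      window_ms = c(window_start, window_end)))
}

#' Write a response as two-column delimited text with a JSON sidecar
#' @param resp a [response_waveform()].
#' @param path output `.tsv` path; provenance goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_response <- function(resp, path) {
  stopifnot(inherits(resp, "response_waveform"))
  utils::write.table(
    data.frame(lag_ms = resp$lags_ms, amplitude_uV = resp$amplitude),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    c(resp$provenance, list(fs = resp$fs, normalized = resp$normalized)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a response written by [write_response()]
#' @param path the `.tsv` path.
#' @return a [response_waveform()].
#' @export
read_response <- function(path) {
  tab <- utils::read.delim(path)
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else list()
  fs <- prov$fs %||% round(1000 / stats::median(diff(tab$lag_ms)))
  normalized <- isTRUE(prov$normalized)
  prov$fs <- NULL; prov$normalized <- NULL
  response_waveform(tab$amplitude_uV, tab$lag_ms, fs, provenance = as.list(prov),
                    normalized = normalized)
}
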