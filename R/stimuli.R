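#' Truncate long silent pauses in speech audio
#'
#' Natural narration contains pauses of several seconds; long gaps carry no
#' stimulus energy and waste recording time, so maximal silent runs longer
#' than `max_pause` are shortened to exactly `max_pause`. Silence is detected
#' from short-time RMS in `hop` frames: a frame is silent when its RMS falls
#' below `threshold_db` relative to the whole-signal RMS, and a run is
#' truncated only when every frame in it is silent. Non-silent content is
#' untouched and order-preserved.
#'
#' @param audio an [audio_stimulus()].
#' @param max_pause maximum allowed pause duration (s), default 0.5.
#' @param threshold_db silence threshold relative to whole-signal RMS (dB),
#'   default -40.
#' @param hop analysis frame length (s), default 0.010.
#' @return an `audio_stimulus`, at most as long as the input.
#' @export
truncate_silences <- function(audio, max_pause = 0.5, threshold_db = -40,
                              hop = 0.010) {
  stopifnot(inherits(audio, "audio_stimulus"))
  if (max_pause <= 0) stop("max_pause must be positive", call. = FALSE)
  x <- audio$samples
  fs <- audio$fs
  hop_n <- max(1L, round(hop * fs))
  n_frames <- ceiling(length(x) / hop_n)
  idx <- rep(seq_len(n_frames), each = hop_n, length.out = length(x))
  frame_rms <- sqrt(tapply(x^2, idx, mean))
  ref <- rms(x)
  if (ref == 0) {
    silent <- rep(TRUE, n_frames)
  } else {
    silent <- frame_rms < ref * 10^(threshold_db / 20)
  }
  r <- rle(as.logical(silent))
  keep <- rep(TRUE, length(x))
  max_n <- round(max_pause * fs)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    s0 <- (starts[k] - 1) * hop_n + 1
    s1 <- min(ends[k] * hop_n, length(x))
    run_len <- s1 - s0 + 1
    if (run_len > max_n) keep[(s0 + max_n):s1] <- FALSE
  }
  audio_stimulus(x[keep], fs, rms_target = audio$rms_target,
                 spl_reference = audio$spl_reference)
}

#' High-pass filter speech audio
#'
#' A gentle first-order Butterworth high-pass (default cutoff 1 kHz,
#' 6 dB/octave) emphasising the frequencies that drive the brainstem response
#' while leaving speech natural-sounding. Stimulus filtering defaults to
#' anti-causal (time-reverse, filter, reverse back) so that filter delay is
#' never added to the forward stimulus path.
#'
#' @param audio an [audio_stimulus()].
#' @param cutoff corner frequency (Hz), default 1000.
#' @param order filter order, default 1.
#' @param direction `"anticausal"` (default) or `"causal"`.
#' @return filtered `audio_stimulus`.
#' @export
highpass_speech <- function(audio, cutoff = 1000, order = 1L,
                            direction = c("anticausal", "causal")) {
  stopifnot(inherits(audio, "audio_stimulus"))
  direction <- match.arg(direction)
  y <- butter_apply(audio$samples, audio$fs, cutoff, order = order,
                    type = "high", direction = direction)
  audio_stimulus(y, audio$fs, rms_target = audio$rms_target,
                 spl_reference = audio$spl_reference)
}

#' Normalize audio to its calibration RMS
#'
#' Pure rescaling so that the digital RMS equals `rms_target` (default the
#' stimulus's own calibration target, 0.01, the amplitude of a 1-kHz tone at
#' the 75 dB SPL reference).
#'
#' @param audio an [audio_stimulus()].
#' @param rms_target target RMS; defaults to `audio$rms_target`.
#' @return rescaled `audio_stimulus`.
#' @export
normalize_rms <- function(audio, rms_target = NULL) {
  stopifnot(inherits(audio, "audio_stimulus"))
  if (is.null(rms_target)) rms_target <- audio$rms_target
  r <- rms(audio$samples)
  if (r == 0) stop("cannot normalize all-zero audio", call. = FALSE)
  audio_stimulus(audio$samples * (rms_target / r), audio$fs,
                 rms_target = rms_target, spl_reference = audio$spl_reference)
}

#' Section continuous audio into overlapping faded epochs
#'
#' Cuts the stimulus into epochs of `epoch_dur` seconds with raised-cosine
#' fade-in/out of `fade_dur` seconds. The last `overlap_dur` seconds of each
#' epoch are repeated as the first `overlap_dur` seconds of the next, so a
#' listener can pick up the story where they left off; each epoch therefore
#' advances the source by `epoch_dur - overlap_dur` seconds of novel material.
#'
#' @param audio an [audio_stimulus()].
#' @param epoch_dur epoch duration (s), default 64.
#' @param fade_dur raised-cosine fade duration (s), default 1.
#' @param overlap_dur shared content between consecutive epochs (s), default 4.
#' @return an object of class `epoched_stimulus`: list with `epochs` (list of
#'   `audio_stimulus`), the parameters, and `novel_dur` (s of novel material
#'   per epoch).
#' @export
section_epochs <- function(audio, epoch_dur = 64, fade_dur = 1, overlap_dur = 4) {
  stopifnot(inherits(audio, "audio_stimulus"))
  if (2 * fade_dur > epoch_dur) stop("fades longer than the epoch", call. = FALSE)
  if (overlap_dur < 0 || overlap_dur >= epoch_dur) {
    stop("overlap must be in [0, epoch_dur)", call. = FALSE)
  }
  fs <- audio$fs
  n_ep <- round(epoch_dur * fs)
  n_step <- round((epoch_dur - overlap_dur) * fs)
  total <- length(audio$samples)
  if (total < n_ep) stop("audio shorter than one epoch", call. = FALSE)
  n_epochs <- (total - n_ep) %/% n_step + 1
  fade_n <- round(fade_dur * fs)
  ramp <- raised_cosine_ramp(fade_n)
  epochs <- vector("list", n_epochs)
  for (k in seq_len(n_epochs)) {
    s0 <- (k - 1) * n_step + 1
    seg <- audio$samples[s0:(s0 + n_ep - 1)]
    if (fade_n > 0) {
      seg[seq_len(fade_n)] <- seg[seq_len(fade_n)] * ramp
      seg[(n_ep - fade_n + 1):n_ep] <- seg[(n_ep - fade_n + 1):n_ep] * rev(ramp)
    }
    epochs[[k]] <- audio_stimulus(seg, fs, rms_target = audio$rms_target,
                                  spl_reference = audio$spl_reference)
  }
  structure(
    list(epochs = epochs, epoch_dur = epoch_dur, fade_dur = fade_dur,
         overlap_dur = overlap_dur, novel_dur = epoch_dur - overlap_dur,
         fs = fs),
    class = "epoched_stimulus"
  )
}

#' @export
print.epoched_stimulus <- function(x, ...) {
  cat(sprintf("<epoched_stimulus> %d epochs of %g s (%g s novel each) @ %g Hz\n",
              length(x$epochs), x$epoch_dur, x$novel_dur, x$fs))
  invisible(x)
}

#' Generate a click train
#'
#' Click times either follow a Poisson point process (exponential inter-click
#' intervals at rate `rate`, statistically white, so the response analysis
#' window can be extended arbitrarily without temporal wrapping) or a
#' conventional periodic train at the same rate.
#'
#' @param rate mean click rate (clicks/s), default 44.1.
#' @param duration train duration (s), default 30.
#' @param timing `"poisson"` or `"periodic"`.
#' @param fs_audio audio sampling rate the clicks will be rendered at (Hz).
#' @param click_width_samples click duration in audio samples, default 2
#'   (81.9 us at 24,414 Hz, close to the standard 100-us click).
#' @param polarity `"rarefaction"` (negative-going) or `"condensation"`.
#' @param seed optional integer seed for reproducible Poisson timing.
#' @return an object of class `click_train`.
#' @export
make_click_train <- function(rate = 44.1, duration = 30,
                             timing = c("poisson", "periodic"),
                             fs_audio = 24414, click_width_samples = 2L,
                             polarity = c("rarefaction", "condensation"),
                             seed = NULL) {
  timing <- match.arg(timing)
  polarity <- match.arg(polarity)
  if (rate <= 0 || duration <= 0) stop("rate and duration must be positive", call. = FALSE)
  if (timing == "poisson") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    # draw enough exponential gaps to cover the duration, then crop
    n_guess <- max(10, ceiling(rate * duration + 6 * sqrt(rate * duration)))
    gaps <- stats::rexp(n_guess, rate)
    times <- cumsum(gaps)
    while (times[length(times)] < duration) {
      gaps <- stats::rexp(n_guess, rate)
      times <- c(times, times[length(times)] + cumsum(gaps))
    }
    click_times <- times[times < duration]
  } else {
    # floor(rate * duration) clicks at exact multiples of 1/rate, from 0
    click_times <- (seq_len(floor(rate * duration)) - 1) / rate
  }
  structure(
    list(click_times = click_times, rate = rate, duration = duration,
         click_width_samples = as.integer(click_width_samples),
         fs_audio = fs_audio, polarity = polarity, timing = timing),
    class = "click_train"
  )
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %d %s %s clicks over %g s (rate %g /s)\n",
              length(x$click_times), x$timing, x$polarity, x$duration, x$rate))
  invisible(x)
}

#' Render a click train as calibrated audio
#'
#' Each click becomes `click_width_samples` consecutive samples of the train's
#' polarity. The peak amplitude defaults to the peak of the 1-kHz calibration
#' sinusoid (`sqrt(2) * rms_target`), i.e. the clicks are presented at the
#' peak-to-peak-equivalent SPL of the reference tone.
#'
#' @param train a [make_click_train()] object.
#' @param rms_target,spl_reference calibration convention (see
#'   [audio_stimulus()]).
#' @return an `audio_stimulus` of duration `train$duration`.
#' @export
render_click_audio <- function(train, rms_target = 0.01, spl_reference = 75) {
  stopifnot(inherits(train, "click_train"))
  if (train$click_width_samples < 1) stop("click width must be >= 1 sample", call. = FALSE)
  fs <- train$fs_audio
  n <- round(train$duration * fs)
  x <- numeric(n)
  amp <- sqrt(2) * rms_target * if (train$polarity == "rarefaction") -1 else 1
  start_idx <- round(train$click_times * fs) + 1
  merged <- 0L
  for (s in start_idx) {
    ii <- s:min(s + train$click_width_samples - 1L, n)
    merged <- merged + sum(x[ii] != 0)
    x[ii] <- amp
  }
  if (merged > 0) message("render_click_audio: ", merged,
                          " overlapping click samples merged")
  audio_stimulus(x, fs, rms_target = rms_target, spl_reference = spl_reference)
}

#' Dual-polarity regressor container
#'
#' The drive signal for the deconvolution: two non-negative waveforms per
#' epoch (`pos` and `neg`), at the EEG sampling rate. For rectified speech,
#' `pos` holds the positive half-wave and `neg` the inverted negative
#' half-wave, so `pos - neg` reconstructs the (band-limited) signed audio.
#' For impulse trains the two branches are identical 0/1 click indicators.
#'
#' @param pos,neg lists of non-negative numeric vectors, one per epoch.
#' @param fs_eeg EEG sampling rate (Hz).
#' @param kind `"rectified_speech"` or `"impulse_train"`.
#' @return an object of class `abr_regressor`.
#' @export
abr_regressor <- function(pos, neg, fs_eeg,
                          kind = c("rectified_speech", "impulse_train")) {
  kind <- match.arg(kind)
  if (!is.list(pos)) pos <- list(pos)
  if (!is.list(neg)) neg <- list(neg)
  stopifnot(length(pos) == length(neg))
  for (k in seq_along(pos)) {
    if (min(pos[[k]]) < 0 || min(neg[[k]]) < 0) {
      stop("regressor branches must be non-negative", call. = FALSE)
    }
  }
  structure(list(pos = pos, neg = neg, fs_eeg = fs_eeg, kind = kind),
            class = "abr_regressor")
}

#' @export
print.abr_regressor <- function(x, ...) {
  cat(sprintf("<abr_regressor> %s, %d epoch(s) @ %g Hz\n",
              x$kind, length(x$pos), x$fs_eeg))
  invisible(x)
}

#' Build the rectified-speech regressor
#'
#' The auditory system is largely insensitive to the sign of acoustic
#' pressure, so the signed audio is split by half-wave rectification into a
#' positive-peaks branch and an inverted-negative-peaks branch; the response
#' is later derived from each branch and the two averaged. Rectification is
#' done at the audio rate; each branch is then anti-alias filtered and
#' resampled to the EEG rate. Resampling ripple can push samples slightly
#' negative, so branches are clipped at zero afterwards (the maximum clipped
#' magnitude is reported via a message when non-trivial).
#'
#' @param audio an [audio_stimulus()] or [section_epochs()] result.
#' @param fs_eeg EEG sampling rate (Hz), default 10000; must be below the
#'   audio rate.
#' @return an [abr_regressor()] of kind `"rectified_speech"`.
#' @export
make_regressor_speech <- function(audio, fs_eeg = 10000) {
  epochs <- if (inherits(audio, "epoched_stimulus")) audio$epochs else list(audio)
  stopifnot(all(vapply(epochs, inherits, logical(1), "audio_stimulus")))
  if (fs_eeg >= epochs[[1]]$fs) stop("fs_eeg must be below the audio rate", call. = FALSE)
  pos <- vector("list", length(epochs))
  neg <- vector("list", length(epochs))
  max_clip <- 0
  for (k in seq_along(epochs)) {
    if (k > 1L && identical(epochs[[k]], epochs[[k - 1L]])) {
      pos[[k]] <- pos[[k - 1L]]
      neg[[k]] <- neg[[k - 1L]]
      next
    }
    s <- epochs[[k]]$samples
    fs <- epochs[[k]]$fs
    # resampling is linear and max(s,0) = (|s|+s)/2, so resampling the signed
    # and full-wave-rectified signals once gives both half-wave branches
    rs <- resample_waveform(s, fs, fs_eeg)
    ra <- resample_waveform(abs(s), fs, fs_eeg)
    p <- (ra + rs) / 2
    n <- (ra - rs) / 2
    max_clip <- max(max_clip, -min(p, 0), -min(n, 0))
    pos[[k]] <- pmax(p, 0)
    neg[[k]] <- pmax(n, 0)
  }
  if (max_clip > 0.01 * max(vapply(pos, max, numeric(1)))) {
    message("make_regressor_speech: resampling ripple clipped at zero (max ",
            signif(max_clip, 3), ")")
  }
  abr_regressor(pos, neg, fs_eeg, kind = "rectified_speech")
}

#' Build the impulse-train regressor for clicks
#'
#' A click train is too sparse to resample with a low-pass design (the filter
#' would ring); instead a unit-height single-sample impulse is placed at the
#' nearest integer index to each click time at the EEG rate (ties round half
#' to even, R's default). If two clicks collide on one index a single unit
#' impulse is kept, with a warning.
#'
#' @param train a [make_click_train()] object, or a list of them (one per
#'   epoch).
#' @param fs_eeg EEG sampling rate (Hz), default 10000.
#' @param n_samples epoch length in samples at `fs_eeg`; defaults to
#'   `round(duration * fs_eeg)`.
#' @return an [abr_regressor()] of kind `"impulse_train"` (`pos == neg`).
#' @export
make_regressor_clicks <- function(train, fs_eeg = 10000, n_samples = NULL) {
  trains <- if (inherits(train, "click_train")) list(train) else train
  stopifnot(all(vapply(trains, inherits, logical(1), "click_train")))
  pos <- vector("list", length(trains))
  for (k in seq_along(trains)) {
    tr <- trains[[k]]
    n <- if (is.null(n_samples)) round(tr$duration * fs_eeg) else n_samples
    idx <- round(tr$click_times * fs_eeg) + 1
    idx <- idx[idx >= 1 & idx <= n]
    if (anyDuplicated(idx)) {
      warning("clicks collided on ", sum(duplicated(idx)),
              " sample index(es); kept single unit impulses")
      idx <- unique(idx)
    }
    v <- numeric(n)
    v[idx] <- 1
    pos[[k]] <- v
  }
  abr_regressor(pos, pos, fs_eeg, kind = "impulse_train")
}
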