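#' Synthetic auditory-brainstem kernel
#'
#' Ground-truth impulse response for simulations: a sum of damped oscillatory
#' (Gabor) bumps at configurable latencies. Defaults place early waves at 2
#' and 4 ms, the dominant positive Wave V at 6.5 ms, a middle-latency bump at
#' 30 ms and a slow cortical bump at 100 ms, with amplitudes in microvolts
#' per unit regressor drive.
#'
#' @param fs sampling rate (Hz), default 10000.
#' @param latencies_ms bump centers (ms).
#' @param amplitudes_uV bump peak amplitudes (uV).
#' @param widths_ms Gaussian SD of each bump (ms).
#' @param freqs_hz oscillation frequency of each bump (Hz).
#' @param max_lag_ms kernel support end (ms), default 350.
#' @return object of class `abr_kernel` with `amplitude`, `lags_ms`, `fs`.
#' @export
abr_kernel <- function(fs = 10000,
                       latencies_ms = c(2, 4, 6.5, 30, 100),
                       amplitudes_uV = c(0.15, 0.20, 0.50, 0.25, 0.30),
                       widths_ms = c(0.4, 0.5, 0.8, 5, 20),
                       freqs_hz = c(900, 700, 450, 40, 10),
                       max_lag_ms = 350) {
  stopifnot(length(latencies_ms) == length(amplitudes_uV),
            length(latencies_ms) == length(widths_ms),
            length(latencies_ms) == length(freqs_hz))
  t_ms <- seq(0, max_lag_ms, by = 1000 / fs)
  amp <- numeric(length(t_ms))
  for (i in seq_along(latencies_ms)) {
    d <- t_ms - latencies_ms[i]
    amp <- amp + amplitudes_uV[i] * exp(-d^2 / (2 * widths_ms[i]^2)) *
      cos(2 * pi * freqs_hz[i] * d / 1000)
  }
  structure(list(amplitude = amp, lags_ms = t_ms, fs = fs,
                 latencies_ms = latencies_ms, amplitudes_uV = amplitudes_uV),
            class = "abr_kernel")
}

#' @export
print.abr_kernel <- function(x, ...) {
  cat(sprintf("<abr_kernel> %d bump(s), support 0-%.0f ms @ %g Hz\n",
              length(x$latencies_ms), max(x$lags_ms), x$fs))
  invisible(x)
}

#' View a kernel as a response waveform (for metrics on ground truth)
#' @param kernel an [abr_kernel()].
#' @return a [response_waveform()].
#' @export
kernel_as_response <- function(kernel) {
  response_waveform(kernel$amplitude, kernel$lags_ms, kernel$fs,
                    provenance = list(method = "ground_truth_kernel"))
}

#' Default electromagnetic-leakage kernel for simulations
#'
#' A brief damped oscillation centered at -0.9 ms (the artifact precedes
#' acoustic time zero by the earphone tube delay), unit peak amplitude in uV
#' per unit signed audio.
#'
#' @param fs sampling rate (Hz).
#' @param center_ms artifact center lag (ms), default -0.9.
#' @return a [leakage_kernel()].
#' @export
simulated_leakage_kernel <- function(fs = 10000, center_ms = -0.9) {
  n_win <- round(0.010 * fs)
  l0 <- round((center_ms - 5) / 1000 * fs)
  t_ms <- (l0 + seq_len(n_win) - 1) / fs * 1000
  d <- t_ms - center_ms
  h <- exp(-d^2 / (2 * 0.3^2)) * cos(2 * pi * 1500 * d / 1000)
  leakage_kernel(h, fs, center_ms = center_ms)
}

#' Ground-truth description of a simulated recording
#'
#' Bundles everything the generator needs: the neural kernel, the background
#' noise model (1/f spectral exponent and RMS, line-harmonic amplitudes,
#' rate/size of high-amplitude excursions), the leakage artifact (kernel and
#' gain; gain 0 disables it), and the master seed. An identical seed yields a
#' bit-identical dataset.
#'
#' @param kernel an [abr_kernel()].
#' @param noise_rms_uV RMS of the 1/f background (uV), default 0.2. The
#'   default is calibrated to a good-quality recording: relative to the
#'   0.5-uV Wave V kernel it yields a derived-response SNR near 10 dB after
#'   ten 64-s epochs (the favorable end of published per-subject SNR
#'   trajectories); around 0.55 uV reproduces the median trajectory
#'   (roughly 1, 4, and 8 dB after 10, 20, and 40 epochs).
#' @param noise_exponent spectral exponent of the background (power ~
#'   1/f^exponent), default 1.
#' @param line_amps_uV amplitudes of 60/180/300 Hz line harmonics (uV).
#' @param excursion_rate_per_min rate of injected high-amplitude excursions.
#' @param excursion_amp_uV excursion peak amplitude (uV), default 300.
#' @param excursion_dur_s excursion duration (s), default 0.05.
#' @param leakage_gain leakage amplitude, uV per unit signed audio, default 0.
#' @param leakage leakage kernel; default [simulated_leakage_kernel()].
#' @param seed master seed (integer).
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(kernel = abr_kernel(),
                             noise_rms_uV = 0.2, noise_exponent = 1,
                             line_amps_uV = c(`60` = 10, `180` = 3, `300` = 2),
                             excursion_rate_per_min = 0.5,
                             excursion_amp_uV = 300, excursion_dur_s = 0.05,
                             leakage_gain = 0, leakage = NULL, seed = 1L) {
  stopifnot(noise_rms_uV >= 0, excursion_rate_per_min >= 0, leakage_gain >= 0)
  if (is.null(leakage)) leakage <- simulated_leakage_kernel(kernel$fs)
  structure(
    list(kernel = kernel, noise_rms_uV = noise_rms_uV,
         noise_exponent = noise_exponent, line_amps_uV = line_amps_uV,
         excursion_rate_per_min = excursion_rate_per_min,
         excursion_amp_uV = excursion_amp_uV,
         excursion_dur_s = excursion_dur_s,
         leakage_gain = leakage_gain, leakage = leakage,
         seed = as.integer(seed)),
    class = "simulation_truth"
  )
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(paste0("<simulation_truth> noise %g uV (1/f^%g), excursions ",
                     "%g/min, leakage gain %g, seed %d\n"),
              x$noise_rms_uV, x$noise_exponent, x$excursion_rate_per_min,
              x$leakage_gain, x$seed))
  invisible(x)
}

#' Generate speech-like broadband audio
#'
#' A stand-in for narrated speech with the acoustic properties the analysis
#' relies on: a glottal-like pulse train whose fundamental drifts inside
#' `f0_range`, passed through a slowly wandering resonance (formant-like
#' coloring), mixed with a weak fricative-like noise floor, amplitude
#' modulated at a syllabic rate, and interrupted by silent pauses (some
#' longer than 0.5 s so pause truncation is exercised). The result is
#' spectrally rich from ~100 Hz up to the Nyquist with no deep third-octave
#' zeros.
#'
#' @param duration duration (s).
#' @param fs sampling rate (Hz), default 24414.
#' @param f0_range fundamental frequency range (Hz), default `c(100, 250)`.
#' @param pauses insert silent pauses? default TRUE.
#' @param pause_rate_per_min pauses per minute, default 8.
#' @param seed optional integer seed.
#' @return an [audio_stimulus()] normalized to RMS 0.01.
#' @export
make_speechlike_audio <- function(duration, fs = 24414, f0_range = c(100, 250),
                                  pauses = TRUE, pause_rate_per_min = 8,
                                  seed = NULL) {
  stopifnot(duration > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  # drifting fundamental: smoothed random walk inside f0_range
  n_ctrl <- max(4, ceiling(duration * 2) + 1)
  f0_ctrl <- stats::runif(n_ctrl, f0_range[1], f0_range[2])
  f0 <- stats::spline(seq(0, duration, length.out = n_ctrl), f0_ctrl,
                      xout = (seq_len(n) - 1) / fs)$y
  f0 <- pmin(pmax(f0, f0_range[1]), f0_range[2])
  phase <- cumsum(f0) / fs
  x <- numeric(n)
  pulse_idx <- c(1L, which(diff(floor(phase)) > 0) + 1L)
  # per-pulse shimmer keeps the envelope's modulation spectrum broadband
  x[pulse_idx] <- exp(stats::rnorm(length(pulse_idx), 0, 0.4))
  # formant-like coloring: framewise resonator with wandering center
  frame <- max(1L, round(0.120 * fs))
  starts <- seq(1L, n, by = frame)
  colored <- numeric(n)
  for (s in starts) {
    e <- min(s + frame - 1L, n)
    fc <- stats::runif(1, 400, 2500)
    w0 <- 2 * pi * fc / fs
    r <- 0.95
    b <- c(1 - r, 0, 0)
    a <- c(1, -2 * r * cos(w0), r^2)
    colored[s:e] <- as.numeric(signal::filter(b, a, x[s:e]))
  }
  x <- x + 4 * colored
  # weak broadband noise floor (fricative-like), high-pass colored
  noise <- stats::rnorm(n)
  noise <- butter_apply(noise, fs, 1000, order = 1L, type = "high",
                        direction = "causal")
  x <- x + 0.15 * noise * stats::sd(x) / stats::sd(noise)
  # syllabic amplitude modulation: smooth broadband random envelope (speech
  # modulation spectra are filled over ~0.5-30 Hz, not a single rate)
  n_env <- max(8, ceiling(duration * 30))
  env_ctrl <- exp(stats::rnorm(n_env, 0, 0.5))
  env <- stats::spline(seq(0, duration, length.out = n_env), env_ctrl,
                       xout = (seq_len(n) - 1) / fs)$y
  x <- x * (0.3 + pmax(env, 0))
  # silent pauses with 5-ms ramps
  if (pauses && duration > 2) {
    n_pause <- stats::rpois(1, pause_rate_per_min * duration / 60)
    n_pause <- max(n_pause, if (duration >= 10) 1L else 0L)
    if (n_pause > 0) {
      ramp_n <- round(0.005 * fs)
      ramp <- raised_cosine_ramp(ramp_n)
      for (i in seq_len(n_pause)) {
        dur_p <- stats::runif(1, 0.3, 1.2)
        if (i == 1L && duration >= 10) dur_p <- stats::runif(1, 0.7, 1.2)
        np <- round(dur_p * fs)
        s0 <- sample.int(max(1L, n - np - 2L * ramp_n), 1)
        win <- c(rev(ramp), numeric(np), ramp)
        idx <- s0:(s0 + length(win) - 1L)
        x[idx] <- x[idx] * win
      }
    }
  }
  normalize_rms(audio_stimulus(x, fs))
}

#' Forward-simulate an EEG recording from audio and ground truth
#'
#' Realizes exactly the linear generative model the deconvolution assumes:
#' the neural drive is the mean of the two half-wave-rectified branches of
#' the audio at the EEG rate, convolved with the ground-truth kernel; on top
#' of that go 1/f background noise, line-harmonic sinusoids, occasional
#' high-amplitude excursions, and (optionally) the leakage kernel convolved
#' with the *signed* audio. Epoch-onset markers are written for every
#' stimulus. An optional compressive nonlinearity (`drive^compression`)
#' violates the linear assumption on purpose, to probe graceful degradation.
#'
#' @param audio an [audio_stimulus()], list of them (one per epoch), or an
#'   [section_epochs()] result.
#' @param truth a [simulation_truth()].
#' @param fs_eeg EEG sampling rate (Hz), default 10000.
#' @param gap_dur silent gap between stimulus epochs (s), default 0.5; must
#'   exceed the 0.1-s epoch tail.
#' @param compression exponent applied to the rectified drive (1 = linear).
#' @param drive_epochs optional list of precomputed per-epoch drive vectors
#'   at `fs_eeg` (mean of the rectified branches); computed from `audio`
#'   when `NULL`.
#' @param audio_eeg optional list of precomputed signed audio at `fs_eeg`
#'   (only needed when the truth includes leakage).
#' @return an [eeg_recording()] with one marker per epoch.
#' @export
forward_model <- function(audio, truth, fs_eeg = 10000, gap_dur = 0.5,
                          compression = 1, drive_epochs = NULL,
                          audio_eeg = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  epochs <- if (inherits(audio, "epoched_stimulus")) audio$epochs
            else if (inherits(audio, "audio_stimulus")) list(audio)
            else audio
  stopifnot(length(epochs) >= 1, gap_dur >= 0.1)
  kern <- truth$kernel
  if (!isTRUE(all.equal(kern$fs, fs_eeg))) {
    stop("kernel sampling rate must equal fs_eeg", call. = FALSE)
  }
  set.seed(truth$seed)
  n_stim <- round(length(epochs[[1]]$samples) / epochs[[1]]$fs * fs_eeg)
  if (length(kern$amplitude) > n_stim) stop("kernel longer than epoch", call. = FALSE)
  n_seg <- n_stim + round(gap_dur * fs_eeg)
  n_total <- n_seg * length(epochs)
  potential <- numeric(n_total)
  markers <- integer(length(epochs))
  # leakage kernel taps at signed lags, for linear convolution with offset
  leak <- truth$leakage
  leak_lag0 <- round(min(leak$lags_ms) / 1000 * fs_eeg)
  drive <- NULL; sig <- NULL
  for (k in seq_along(epochs)) {
    # repeated epochs (identical audio objects) reuse the resampled drive
    if (k == 1L || !identical(epochs[[k]], epochs[[k - 1L]])) {
      s <- epochs[[k]]$samples
      fs_a <- epochs[[k]]$fs
      if (!is.null(drive_epochs)) {
        drive <- drive_epochs[[k]]
      } else {
        rs <- resample_waveform(s, fs_a, fs_eeg)
        ra <- resample_waveform(abs(s), fs_a, fs_eeg)
        drive <- (pmax((ra + rs) / 2, 0) + pmax((ra - rs) / 2, 0)) / 2
      }
      if (compression != 1) drive <- drive^compression
      sig <- if (truth$leakage_gain > 0) {
        if (!is.null(audio_eeg)) audio_eeg[[k]]
        else resample_waveform(s, fs_a, fs_eeg)
      } else NULL
      clean <- conv_linear(drive, kern$amplitude)
      art <- if (truth$leakage_gain > 0) {
        truth$leakage_gain * conv_linear(sig, leak$impulse_response)
      } else NULL
    }
    m <- (k - 1L) * n_seg + 1L
    markers[k] <- m
    span <- m:min(m + length(clean) - 1L, n_total)
    potential[span] <- potential[span] + clean[seq_along(span)]
    if (!is.null(art)) {
      a0 <- m + leak_lag0
      aspan <- max(a0, 1L):min(a0 + length(art) - 1L, n_total)
      potential[aspan] <- potential[aspan] + art[aspan - a0 + 1L]
    }
  }
  # stationary 1/f background noise
  if (truth$noise_rms_uV > 0) {
    potential <- potential +
      one_over_f_noise(n_total, fs_eeg, truth$noise_exponent,
                       truth$noise_rms_uV)
  }
  # line harmonics with random phases
  tt <- (seq_len(n_total) - 1) / fs_eeg
  freqs <- as.numeric(names(truth$line_amps_uV))
  if (is.null(freqs) || anyNA(freqs)) freqs <- c(60, 180, 300)[seq_along(truth$line_amps_uV)]
  for (i in seq_along(truth$line_amps_uV)) {
    potential <- potential + truth$line_amps_uV[[i]] *
      sin(2 * pi * freqs[i] * tt + stats::runif(1, 0, 2 * pi))
  }
  # occasional high-amplitude excursions (movement-artifact-like bursts)
  if (truth$excursion_rate_per_min > 0) {
    n_exc <- stats::rpois(1, truth$excursion_rate_per_min * n_total / fs_eeg / 60)
    if (n_exc > 0) {
      burst_n <- max(2L, round(truth$excursion_dur_s * fs_eeg))
      burst <- truth$excursion_amp_uV * hann_window(burst_n)
      for (i in seq_len(n_exc)) {
        s0 <- sample.int(n_total - burst_n, 1)
        potential[s0:(s0 + burst_n - 1L)] <- potential[s0:(s0 + burst_n - 1L)] +
          burst * sample(c(-1, 1), 1)
      }
    }
  }
  eeg_recording(potential, fs = fs_eeg, markers = markers,
                channel_label = "simulated")
}

# linear convolution via FFT
#' @noRd
conv_linear <- function(x, h) {
  nf <- fft_length(length(x) + length(h) - 1L)
  Re(stats::fft(stats::fft(c(x, numeric(nf - length(x)))) *
                stats::fft(c(h, numeric(nf - length(h)))),
                inverse = TRUE))[seq_len(length(x) + length(h) - 1L)] / nf
}

# Gaussian noise with power spectral density ~ 1/f^exponent, given RMS
#' @noRd
one_over_f_noise <- function(n, fs, exponent, rms_target) {
  nf <- fft_length(n)
  w <- stats::rnorm(nf)
  f <- c(0, seq_len(nf - 1)) * fs / nf
  f <- pmin(f, fs - f)   # two-sided
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE))[seq_len(n)] / nf
  x * rms_target / sqrt(mean(x^2))
}

#' Simulate a complete recording session with known ground truth
#'
#' Convenience wrapper: generates (or accepts) per-epoch speech-like audio,
#' forward-models the EEG, and returns everything the analysis pipeline
#' needs, plus the truth for recovery checks. With `reuse_audio = TRUE` a
#' single audio epoch is generated and repeated, so epochs differ only in
#' their independent noise (a stationary-noise study design that is much
#' cheaper to generate).
#'
#' @param truth a [simulation_truth()].
#' @param n_epochs number of stimulus epochs, default 40.
#' @param epoch_dur stimulus duration per epoch (s), default 64.
#' @param fs_audio audio rate (Hz), default 24414.
#' @param fs_eeg EEG rate (Hz), default 10000.
#' @param reuse_audio reuse one audio epoch for all epochs? default FALSE.
#' @param n_distinct generate only this many distinct audio epochs and repeat
#'   them in blocks to fill `n_epochs` (a session that reuses excerpts);
#'   `NULL` (default) makes every epoch distinct. Ignored with `reuse_audio`.
#' @param audio optional list of pre-made [audio_stimulus()] epochs.
#' @param pauses passed to [make_speechlike_audio()].
#' @param max_pause pause cap (s) applied via [truncate_silences()], mirroring
#'   the stimulus-preparation pipeline (long pauses carry no stimulus energy
#'   and would otherwise dilute the regressor); `NULL` disables.
#' @param compression passed to [forward_model()].
#' @return list with `recording` ([eeg_recording()]), `audio` (list of
#'   epochs), `audio_eeg` (signed audio at the EEG rate, for leakage
#'   estimation), `regressor` ([abr_regressor()]), and `truth`.
#' @export
simulate_session <- function(truth, n_epochs = 40, epoch_dur = 64,
                             fs_audio = 24414, fs_eeg = 10000,
                             reuse_audio = FALSE, n_distinct = NULL,
                             audio = NULL, pauses = TRUE,
                             max_pause = 0.5, compression = 1) {
  stopifnot(inherits(truth, "simulation_truth"), n_epochs >= 1)
  set.seed(truth$seed)
  if (is.null(audio)) {
    n_target <- round(epoch_dur * fs_audio)
    gen <- function() {
      # generate with margin, truncate long pauses (as the stimulus pipeline
      # does before presentation), then cut to the exact epoch length
      margin <- if (pauses && !is.null(max_pause)) 6 else 0
      a <- make_speechlike_audio(epoch_dur + margin, fs = fs_audio,
                                 pauses = pauses)
      if (pauses && !is.null(max_pause)) a <- truncate_silences(a, max_pause)
      if (length(a$samples) < n_target) {
        a <- audio_stimulus(c(a$samples, numeric(n_target - length(a$samples))),
                            fs_audio)
      }
      audio_stimulus(a$samples[seq_len(n_target)], fs_audio)
    }
    audio <- if (reuse_audio) {
      rep(list(gen()), n_epochs)
    } else if (!is.null(n_distinct)) {
      pool <- replicate(min(n_distinct, n_epochs), gen(), simplify = FALSE)
      # block-repeat so consecutive epochs can share resampling work
      idx <- sort(rep_len(seq_along(pool), n_epochs))
      pool[idx]
    } else {
      replicate(n_epochs, gen(), simplify = FALSE)
    }
  }
  # one resampling pass per distinct epoch serves the regressor, the neural
  # drive, and the signed audio reference (resampling is linear)
  n_ep <- length(audio)
  pos <- neg <- drive <- audio_eeg <- vector("list", n_ep)
  for (k in seq_len(n_ep)) {
    if (k > 1L && identical(audio[[k]], audio[[k - 1L]])) {
      pos[[k]] <- pos[[k - 1L]]; neg[[k]] <- neg[[k - 1L]]
      drive[[k]] <- drive[[k - 1L]]; audio_eeg[[k]] <- audio_eeg[[k - 1L]]
      next
    }
    s <- audio[[k]]$samples
    rs <- resample_waveform(s, audio[[k]]$fs, fs_eeg)
    ra <- resample_waveform(abs(s), audio[[k]]$fs, fs_eeg)
    pos[[k]] <- pmax((ra + rs) / 2, 0)
    neg[[k]] <- pmax((ra - rs) / 2, 0)
    drive[[k]] <- (pos[[k]] + neg[[k]]) / 2
    audio_eeg[[k]] <- rs
  }
  regressor <- abr_regressor(pos, neg, fs_eeg, kind = "rectified_speech")
  # independent RNG stream for the EEG noise
  truth_eeg <- truth
  truth_eeg$seed <- truth$seed + 1000003L
  recording <- forward_model(audio, truth_eeg, fs_eeg = fs_eeg,
                             compression = compression,
                             drive_epochs = drive, audio_eeg = audio_eeg)
  list(recording = recording, audio = audio, audio_eeg = audio_eeg,
       regressor = regressor, truth = truth)
}

#' Generate a cohort of simulated subjects
#'
#' Per-subject ground truths sharing the noise model, with Wave V latency
#' jittered (Gaussian, SD `latency_sd` ms around 6.5 ms; earlier waves are
#' shifted along with it) and bump amplitudes scaled by a common per-subject
#' log-normal factor with SD `amplitude_sd` (fractional).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param latency_sd SD of Wave V latency across subjects (ms), default 0.25.
#' @param amplitude_sd fractional SD of response amplitude, default 0.2.
#' @param seed master seed.
#' @param ... further arguments passed to [simulation_truth()].
#' @return list of [simulation_truth()], one per subject.
#' @export
make_cohort <- function(n_subjects, latency_sd = 0.25, amplitude_sd = 0.2,
                        seed = 1L, ...) {
  stopifnot(n_subjects >= 2)
  set.seed(seed)
  shift <- stats::rnorm(n_subjects, 0, latency_sd)
  gain <- exp(stats::rnorm(n_subjects, 0, amplitude_sd))
  lapply(seq_len(n_subjects), function(i) {
    base <- abr_kernel()
    k <- abr_kernel(
      fs = base$fs,
      latencies_ms = base$latencies_ms + shift[i],
      amplitudes_uV = base$amplitudes_uV * gain[i]
    )
    simulation_truth(kernel = k, seed = seed + i, ...)
  })
}
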