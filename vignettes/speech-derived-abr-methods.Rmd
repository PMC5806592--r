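---
title: "Deriving auditory brainstem responses from continuous speech: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving auditory brainstem responses from continuous speech: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechABR)
```

## The measurement problem

The auditory brainstem response (ABR) is a scalp potential generated by
subcortical auditory nuclei in the first ~10 ms after a transient sound.
Classically it is measured by averaging thousands of responses to clicks,
which confines brainstem research to unnatural stimuli. This package
implements an alternative: treat the auditory periphery-to-brainstem chain as
a linear time-invariant system, use continuous natural speech as its input,
record continuous single-channel EEG as its output, and estimate the system's
impulse response by least-squares deconvolution. Because the regressor is the
half-wave rectified speech *waveform* (not its envelope), fine structure is
preserved and the estimate retains distinct components at click-ABR latencies
— most importantly a Wave V near 6 ms whose latency and amplitude can be
compared directly with the click-evoked response.

## The model

Writing $x(t)$ for the rectified stimulus drive and $y(t)$ for the EEG, the
model is $y = w * x + \varepsilon$, and the response $w(\tau)$ is estimated
over lags $\tau \in [-150, 350]$ ms by linear least squares. The normal
equations are formed in the frequency domain: per epoch, the cross-spectrum
$X^*(f)\,Y(f)$ and regressor power spectrum $|X(f)|^2$ are accumulated across
all usable epochs, and the ratio is inverse-transformed
(`deconvolve()`). Summing spectra before dividing solves the joint
least-squares problem over the whole recording and weights epochs by their
regressor power. The regressors used here are broadband, so no regularization
is applied; near-empty frequency bins (relative power below $10^{-12}$) are
excluded rather than amplified, with a warning. Each epoch is zero-padded by
the lag span before the FFT, making the estimate linear rather than circular;
the residual edge effect is the truncated kernel tail at the epoch boundary,
which shrinks with epoch length (about 0.5% of lag support for 64-s epochs).

### Polarity handling

The auditory system is largely insensitive to the sign of sound pressure, so
the signed audio is split into a positive half-wave branch and an inverted
negative half-wave branch. Three estimators are provided:

* `polarity = "average"` (default): derive a response from each branch
  independently and average the two waveforms. This is the conventional
  procedure and the right choice for real recordings, where rectification
  happens in the cochlea and each branch is a comparable proxy for the true
  neural drive.
* `polarity = "joint"`: solve the two-regressor least-squares problem per
  frequency (2×2 normal equations accumulated over epochs) and report the
  sum of the two weight vectors — the response to a simultaneous unit in
  both branches, which is exactly what a click is. Where the two branches
  are nearly collinear (they share their envelope, so coherence approaches 1
  at low frequencies) the 2×2 system is ill-conditioned; such bins fall back
  to regressing on the branch sum, which solves the same model with one
  well-conditioned column.
* For impulse-train regressors the branches are identical and both options
  reduce to a single regression.

This distinction matters for validation. The synthetic forward model drives
the EEG with the *mean* of the two rectified branches, and under that
generative model the joint solver recovers the ground-truth kernel exactly
(to machine precision in the noiseless case), whereas the branch-averaged
estimator inherits a frequency-dependent bias from the cross-branch
coherence — each single-branch regression absorbs part of the other branch's
contribution. All simulation-based recovery checks therefore use
`polarity = "joint"`; on real data the choice is the user's, and the default
remains the conventional averaging procedure.

## Stimulus preparation

`truncate_silences()` caps silent pauses at 0.5 s (silence: short-time RMS in
10-ms frames at least 40 dB below the whole-signal RMS — the criterion is
parameterized since any such threshold is a convention).
`highpass_speech()` applies a gentle first-order Butterworth at 1 kHz
(6 dB/octave), anti-causally so no filter delay enters the stimulus path.
`normalize_rms()` scales to digital RMS 0.01, the amplitude of a 1-kHz tone
at the 75 dB SPL reference; fades are applied after normalization, matching
the order of the preparation chain. `section_epochs()` cuts 64-s epochs with
1-s raised-cosine fades and a 4-s content overlap between consecutive epochs
(60 s novel speech per epoch). Click trains (`make_click_train()`) are
Poisson by default at 44.1 clicks/s — statistically white timing, so the
analysis window is free of temporal wrapping — with two-sample (82 µs)
rarefaction clicks at 24,414 Hz presented at the peak-to-peak-equivalent
level of the calibration tone.

The rectified branches are computed at the audio rate and resampled to the
EEG rate (10 kHz) with a zero-phase 8th-order Butterworth anti-alias filter
at 0.45 times the target rate followed by cubic interpolation; negative
resampling ripple is clipped at zero. Impulse trains are never resampled —
a unit impulse is placed at the nearest integer index (ties round half to
even; colliding clicks keep a single unit impulse, with a warning), because
low-pass resampling a spike train would ring.

## EEG conditioning

EEG filtering is *causal* throughout (`filter_eeg()`): a first-order 1-Hz
Butterworth high-pass and 5-Hz-wide second-order IIR notches at 60, 180 and
300 Hz ("5 Hz wide" is read as the −3 dB bandwidth, the conventional
parameterization). Causality matters because zero-phase filtering smears
response energy backwards in time and would bias latencies; only stimulus
processing may be anti-causal. Epochs start at the stimulus onset and end
100 ms after it (64.1 s for speech, 30.1 s for clicks); a final epoch
truncated by the end of the record is an error, never padded.

Instead of rejecting whole epochs, every excursion beyond ±100 µV zeroes a
1-s window centered on the offending sample (`zero_excursions()`; windows
are clipped at epoch edges, not shifted, keeping the sample bookkeeping
exact). Zeroing removes energy, so each epoch is rescaled by
$g_r = N/(N-N_r)$, which keeps the regression amplitude unbiased (the
package applies $g_r$ to the data; scaling the response instead would be
equivalent). The excursion scan runs after filtering, matching the order of
the conditioning chain; a flag is not needed because the scan can simply be
invoked on unfiltered epochs if desired. A fully-zeroed epoch has undefined
$g_r$ and is excluded with a warning. The operation is idempotent.

## Headphone-leakage removal

Electromagnetic leakage from the headphone driver appears in the EEG at a
fixed lag relative to the audio — *before* acoustic time zero, because time
zero is defined at the eardrum after the earphone tube delay; the artifact
sits near −0.9 ms. `estimate_leakage()` divides the EEG DFT by the DFT of
the raw *signed* audio per epoch, inverse-transforms, crops to a 10-ms lag
window centered at −0.9 ms (−5.9 to +4.1 ms), removes a sixth-order
polynomial fit per epoch (speech carries very little energy below ~100 Hz,
so the raw quotient is dominated by low-frequency noise there), averages
across epochs, and applies a 10-ms Hann window. Division bins where the
stimulus magnitude falls below $10^{-8}$ of its maximum are excluded.
`subtract_leakage()` convolves the audio with the kernel — honoring the
negative-lag placement, with linear (not circular) convolution so nothing
wraps across epoch edges — and subtracts. The polynomial is fitted per epoch
before averaging; fitting after averaging is possible by estimating from a
single concatenated epoch, but the per-epoch order is the default. Click
trials skip this correction: their artifact is a sharp spike before 0 ms
that does not overlap the response.

## Response metrics

`find_wave_v()` smooths with a zero-phase 1-kHz low-pass and takes the
maximum in 5–7 ms (ties to the earliest lag). Amplitude is reported
baseline-to-peak — the smoothed value at the peak — since no trough
convention is imposed; a peak-to-trough variant can be built from the same
waveform. `correlate_window()` computes Pearson's r over 0–20 ms.
`response_snr()` implements
$\mathrm{SNR} = 10\log_{10}[(\sigma^2_{ABR}-\sigma^2_{noise})/\sigma^2_{noise}]$
with the signal window 0–20 ms and the pre-stimulus noise window −125 to
−10 ms, variances computed mean-removed; when the signal-window variance
does not exceed the noise variance the SNR is undefined and returned as
`NA`, never clamped. `snr_curve()` recomputes the response from each epoch
prefix; `split_half()` supports even/odd, first/second and arbitrary
condition splits. The cohort normalization factor
$g_n = E_i(\sigma_{c,i})/E_i(\sigma_{s,i})$ (`compute_gn()`) is computed on
responses after the 2-kHz low-pass (the filter is part of the response
definition, so both numerator and denominator see it); its value is tied to
the digital audio scale and is not transferable across calibrations.
`average_abr_traditional()` provides the benchmark periodic-click ABR:
causal second-order 150-Hz high-pass, sweeps from −3 ms to the longest
window the 44.1 clicks/s rate allows (19.7 ms), ±100 µV peak-to-peak
rejection, arithmetic mean.

The 2-kHz response low-pass defaults to causal, consistent with the EEG
filtering convention (a zero-phase option exists); with 200-Hz or 20-Hz
cutoffs the same waveform exposes the middle-latency and late cortical
responses.

## The synthetic-data generator

`simulate_session()` realizes exactly the linear generative model the
estimator assumes, plus controlled violations, so every pipeline stage is
testable with known ground truth:

* **Kernel** (`abr_kernel()`): a sum of Gabor bumps at 2, 4, 6.5, 30 and
  100 ms with amplitudes 0.15, 0.20, 0.50, 0.25 and 0.30 µV — dominant
  positive Wave V at 6.5 ms, early waves sharp (sub-millisecond widths,
  450–900 Hz), later bumps slow. These are ordinary values for a
  click-scale ABR and its middle- and long-latency successors.
* **Speech-like audio** (`make_speechlike_audio()`): glottal pulses with a
  drifting fundamental (100–250 Hz), per-pulse amplitude shimmer, a
  wandering formant-like resonance, a weak high-passed noise floor, a
  smooth broadband amplitude envelope, and silent pauses (some longer than
  0.5 s, so pause truncation is exercised). The shimmer and the broadband
  envelope matter: speech modulation spectra are filled over ~0.5–30 Hz,
  and a regressor with deep modulation-spectrum holes would violate the
  no-near-zeros premise of unregularized deconvolution. Sessions truncate
  pauses at 0.5 s before presentation, as the stimulus chain prescribes.
* **Noise**: stationary 1/f Gaussian background, line harmonics at 60, 180
  and 300 Hz (10, 3, 2 µV), and occasional 300-µV excursion bursts
  (0.5/min) to exercise the zeroing path. The background RMS default of
  0.2 µV is calibrated against the response kernel so a 10-epoch session
  yields a derived-response SNR near 10 dB — a good-quality recording at
  the favorable end of published per-subject SNR trajectories; about
  0.55 µV instead reproduces the median trajectory (≈1, 4 and 8 dB after
  10, 20 and 40 epochs). The default is deliberately the favorable setting
  because the recovery analyses are specified at a desk scale of 10 epochs.
* **Leakage**: a damped 1.5-kHz oscillation centered at −0.9 ms, convolved
  with the signed audio at a configurable gain.
* **Nonlinearity**: an optional compressive exponent on the drive
  demonstrates graceful degradation — recovery correlation decreases
  monotonically with compression strength.

The neural drive is the mean of the two rectified branches, so the
polarity-averaging structure of the estimator is represented in the
generative model (see *Polarity handling* for which estimator inverts it
exactly). A session with `reuse_audio = TRUE` repeats one excerpt across
epochs — epochs then differ only in noise, the cheapest stationary design —
while `n_distinct` interpolates between that and fully distinct excerpts.

What passing these simulations does *not* show: real EEG noise is
non-stationary and non-Gaussian, real brainstem responses adapt and are
level-dependent, and the true neural drive is not literally rectified
audio. The simulations validate the estimator under its stated assumptions
and quantify robustness to the injected violations, nothing more.

## Validation studies and problem sizes

The shipped studies (also run by the test suite and the acceptance script)
use these scales, chosen so each property is measured at the size that
defines it:

* `kernel_recovery_study()`: 20 sessions of 10 × 64-s epochs (5 distinct
  excerpts per session, each presented twice), full pipeline, joint
  polarity solver. Compared against the ground-truth kernel passed through
  the same acquisition and response filters — the pipeline's estimand is
  the kernel as seen through its filters, so anything else would measure
  the filters, not the estimator.
* `snr_doubling_study()`: 20 sessions of 20 × 64-s epochs under pure
  stationary 1/f noise; SNR compared between the first 10 and all 20
  epochs. The expected gain is +3 dB per doubling.
* `leakage_removal_study()`: paired 8 × 8-s sessions with and without the
  artifact at gains spanning weak to dominant; 10-ms leakage physics does
  not need minute-long epochs.

## Numerical choices and degenerate inputs

FFT lengths are rounded up to 5-smooth numbers. Rounding ties follow R's
round-half-even. A regressor with near-zero total power is an error;
all-zero audio cannot be normalized; NaN in EEG is refused at load (the
zeroing step is the only rejection mechanism). Wave V ties break to the
earliest lag. The joint polarity solver's collinearity guard switches a bin
to the branch-sum regression when the normal-equation determinant falls
below 5% of its diagonal product. WAV I/O is sample-exact for float32;
BrainVision-style triplets (single channel, INT_16 or IEEE_FLOAT_32) and a
CSV+JSON fallback are supported, with amplitudes converted to µV on load.

## Known limitations

Edge truncation biases the estimate slightly for epochs much shorter than a
few times the lag span; the averaged-polarity estimator is biased under the
simulator's generative model (use the joint solver for simulations);
leakage estimation assumes the artifact path is linear and time-invariant
within a session; and the traditional-ABR benchmark implements only the
single-channel montage.
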