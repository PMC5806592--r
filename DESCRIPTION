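Package: speechABR
Title: Auditory Brainstem Responses Derived from Continuous Speech by
    Frequency-Domain Deconvolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the auditory brainstem response (ABR) to continuous,
    natural speech from single-channel EEG. The speech audio is half-wave
    rectified into dual-polarity regressors and the brainstem impulse
    response is recovered by linear least-squares deconvolution computed via
    frequency-domain cross- and auto-spectra, over lags spanning -150 to
    350 ms. Includes Poisson and periodic click-train stimulus generation for
    validation against click-evoked ABRs, EEG conditioning (causal Butterworth
    high-pass, line-noise notches, amplitude-excursion zeroing with corrective
    gain), electromagnetic headphone-leakage artifact estimation and
    subtraction by spectral division, response metrics (Wave V latency and
    amplitude, windowed morphology correlation, evoked-response SNR and its
    growth with recording time, split-half stability), and a synthetic-data
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
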