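#' Calibrated stimulus audio
#'
#' Container for a mono stimulus waveform in digital full scale (±1), together
#' with the calibration convention used throughout: a digital RMS amplitude of
#' `rms_target` (default 0.01) corresponds to `spl_reference` dB SPL (default
#' 75), the level of the 1-kHz calibration tone.
#'
#' @param samples numeric vector of samples (finite, unitless pressure).
#' @param fs sampling rate in Hz (> 0).
#' @param rms_target digital RMS corresponding to the reference level.
#' @param spl_reference reference sound level in dB SPL.
#' @return an object of class `audio_stimulus`.
#' @export
audio_stimulus <- function(samples, fs, rms_target = 0.01, spl_reference = 75) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("audio must contain at least one sample", call. = FALSE)
  if (!all(is.finite(samples))) stop("audio samples must be finite", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive number", call. = FALSE)
  structure(
    list(samples = samples, fs = fs,
         rms_target = rms_target, spl_reference = spl_reference),
    class = "audio_stimulus"
  )
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus> %d samples @ %g Hz (%.3f s), RMS %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, rms(x$samples)))
  invisible(x)
}

#' @export
length.audio_stimulus <- function(x) length(x$samples)

#' Duration of an audio stimulus in seconds
#' @param x an `audio_stimulus`.
#' @return duration (s).
#' @export
audio_duration <- function(x) length(x$samples) / x$fs

rms <- function(x) sqrt(mean(x^2))

#' Resample a waveform with anti-alias low-pass filtering
#'
#' Downsamples (or upsamples) a waveform to a new rate. For downsampling the
#' signal is first low-pass filtered with a zero-phase 8th-order Butterworth
#' at 0.45 times the new rate, then evaluated on the new sample grid by cubic
#' interpolation. Impulse trains must never pass through this routine (the
#' anti-alias filter rings); use [make_regressor_clicks()] instead.
#'
#' @param x numeric vector.
#' @param fs_in,fs_out input and output sampling rates (Hz).
#' @return numeric vector at rate `fs_out`.
#' @export
resample_waveform <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  y <- x
  if (fs_out < fs_in) {
    y <- butter_apply(y, fs_in, 0.45 * fs_out, order = 8L, type = "low",
                      direction = "zerophase")
  }
  n_out <- floor(length(x) * fs_out / fs_in)
  t_out <- (seq_len(n_out) - 1) / fs_out
  t_in <- (seq_along(x) - 1) / fs_in
  stats::spline(t_in, y, xout = t_out, method = "fmm")$y
}

#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings stimulus files use in
#' practice: PCM 16-bit, PCM 24-bit, and IEEE float32. Multichannel files are
#' averaged to mono with a warning.
#'
#' @param path path to a `.wav` file.
#' @param rms_target,spl_reference calibration passed to [audio_stimulus()].
#' @return an `audio_stimulus`.
#' @export
read_wav <- function(path, rms_target = 0.01, spl_reference = 75) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", sz + sz %% 2)
      fmt <- list(
        format = readBin(chunk[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(chunk[3:4], "integer", 1, size = 2, endian = "little"),
        fs = readBin(chunk[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(chunk[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path, call. = FALSE)
  bytes_per <- fmt$bits / 8
  n <- length(data_raw) %/% bytes_per
  x <- if (fmt$format == 3L && fmt$bits == 32L) {
    readBin(data_raw, "double", n, size = 4, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 16L) {
    readBin(data_raw, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    v / 2^23
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ", fmt$bits, " bit)",
         call. = FALSE)
  }
  if (fmt$channels > 1) {
    warning("averaging ", fmt$channels, " channels to mono")
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  audio_stimulus(x, fmt$fs, rms_target = rms_target, spl_reference = spl_reference)
}

#' Write a mono WAV file
#'
#' @param audio an `audio_stimulus` (or numeric vector with `fs` given).
#' @param path output path.
#' @param fs sampling rate, required when `audio` is a bare vector.
#' @param format `"float32"` (sample-exact round trip) or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, fs = NULL, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(audio, "audio_stimulus")) {
    x <- audio$samples; fs <- audio$fs
  } else {
    x <- as.numeric(audio)
    if (is.null(fs)) stop("fs required when writing a bare vector", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "float32") 32L else 16L
  fmt_code <- if (format == "float32") 3L else 1L
  data_bytes <- length(x) * (bits / 8)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * bits / 8), con, size = 4, endian = "little")
  writeBin(as.integer(bits / 8), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(x, 1 - 1 / 32768), -1) * 32768)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}
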