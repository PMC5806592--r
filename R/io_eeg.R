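#' Read a single-channel BrainVision-style recording
#'
#' Parses the standard header (`.vhdr`), marker (`.vmrk`), and binary data
#' triplet for a one-channel recording. Supported binary formats are
#' `INT_16` (scaled by the channel resolution) and `IEEE_FLOAT_32`, both
#' multiplexed little-endian. Amplitudes are converted to microvolts on load;
#' stimulus markers become epoch-onset sample indices.
#'
#' @param vhdr_path path to the `.vhdr` header file.
#' @return an [eeg_recording()].
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  get_key <- function(key) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    sub(paste0("^", key, "="), "", hit[1])
  }
  data_file <- get_key("DataFile")
  marker_file <- get_key("MarkerFile")
  n_chan <- as.integer(get_key("NumberOfChannels"))
  samp_int <- as.numeric(get_key("SamplingInterval"))  # microseconds
  bin_fmt <- get_key("BinaryFormat")
  if (is.null(data_file) || is.null(n_chan) || is.null(samp_int)) {
    stop("incomplete BrainVision header: ", vhdr_path, call. = FALSE)
  }
  if (n_chan != 1L) {
    stop("only single-channel recordings are supported (found ", n_chan,
         " channels)", call. = FALSE)
  }
  ch <- get_key("Ch1")
  resolution <- 1; unit <- "µV"; label <- "Ch1"
  if (!is.null(ch)) {
    parts <- strsplit(ch, ",")[[1]]
    label <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution <- as.numeric(parts[3])
    if (length(parts) >= 4 && nzchar(parts[4])) unit <- parts[4]
  }
  dir <- dirname(vhdr_path)
  fs <- 1e6 / samp_int
  dpath <- file.path(dir, data_file)
  sz <- file.info(dpath)$size
  x <- if (is.null(bin_fmt) || grepl("INT_16", bin_fmt)) {
    readBin(dpath, "integer", n = sz %/% 2, size = 2, signed = TRUE,
            endian = "little") * resolution
  } else if (grepl("IEEE_FLOAT_32", bin_fmt)) {
    readBin(dpath, "double", n = sz %/% 4, size = 4, endian = "little") * resolution
  } else {
    stop("unsupported BinaryFormat: ", bin_fmt, call. = FALSE)
  }
  if (grepl("^mV$", unit)) x <- x * 1000
  markers <- integer(0)
  if (!is.null(marker_file) && file.exists(file.path(dir, marker_file))) {
    mlines <- readLines(file.path(dir, marker_file), warn = FALSE)
    mk <- grep("^Mk[0-9]+=Stimulus,", mlines, value = TRUE)
    if (length(mk)) {
      pos <- vapply(strsplit(sub("^Mk[0-9]+=", "", mk), ","),
                    function(p) as.integer(p[3]), integer(1))
      markers <- sort(pos)  # already 1-based sample positions
    }
  }
  eeg_recording(x, fs = fs, markers = markers, channel_label = label)
}

#' Write a single-channel BrainVision-style triplet
#'
#' Companion writer used for fixtures and for exporting simulated recordings;
#' writes `IEEE_FLOAT_32` data, a minimal header, and stimulus markers.
#'
#' @param rec an [eeg_recording()].
#' @param basename output path without extension; `.vhdr`, `.vmrk`, `.eeg`
#'   are appended.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, basename) {
  stopifnot(inherits(rec, "eeg_recording"))
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  dat <- paste0(basename, ".eeg")
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base::basename(dat)),
    paste0("MarkerFile=", base::basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    "NumberOfChannels=1",
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    paste0("Ch1=", rec$channel_label, ",,1,µV")
  ), vhdr, useBytes = FALSE)
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (length(rec$markers)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S  1,%d,1,0",
                        seq_along(rec$markers) + 1L, rec$markers))
  }
  writeLines(mk, vmrk)
  con <- file(dat, "wb")
  writeBin(rec$potential, con, size = 4, endian = "little")
  close(con)
  invisible(vhdr)
}

#' Read the plain-text EEG fallback format (CSV + JSON sidecar)
#'
#' A documented fallback for recordings not stored as BrainVision triplets:
#' a one-column CSV (or headerless text) of potentials in microvolts and a
#' JSON sidecar with `fs` (Hz) and `markers` (1-based onset sample indices).
#'
#' @param csv_path path to the sample file.
#' @param json_path sidecar path; defaults to `csv_path` with `.json`.
#' @return an [eeg_recording()].
#' @export
read_eeg_csv <- function(csv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x <- utils::read.csv(csv_path, header = FALSE)[[1]]
  if (is.character(x)) x <- as.numeric(x[x != "potential_uV"])
  eeg_recording(as.numeric(x), fs = meta$fs,
                markers = as.integer(meta$markers %||% integer(0)),
                channel_label = meta$channel_label %||% "EEG")
}

#' Write the plain-text EEG fallback format
#' @param rec an [eeg_recording()].
#' @param csv_path output sample file; the JSON sidecar goes next to it.
#' @return `csv_path`, invisibly.
#' @export
write_eeg_csv <- function(rec, csv_path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$potential, csv_path, row.names = FALSE,
                     col.names = FALSE, sep = ",")
  jsonlite::write_json(
    list(fs = rec$fs, markers = rec$markers, channel_label = rec$channel_label),
    paste0(tools::file_path_sans_ext(csv_path), ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(csv_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
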