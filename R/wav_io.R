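#' Raw recording container
#'
#' Holds a mono stream of samples normalised to `[-1, 1)` (integer PCM counts
#' divided by `2^(bit_depth - 1)`) together with the sampling rate and
#' provenance label. This is the unit of ingest for the whole pipeline; it is
#' uncalibrated (counts, not pascals).
#'
#' @param samples Numeric vector of normalised samples, all in `[-1, 1)`.
#' @param rate_hz Sampling rate in Hz (e.g. 250000, 384000).
#' @param bit_depth Integer bit depth of the source PCM stream (default 16).
#' @param label Free-text provenance (device, position).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, rate_hz, bit_depth = 16L, label = "") {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  if (any(!is.finite(samples)))
    stop("samples must be finite")
  if (any(samples < -1 | samples >= 1))
    stop("samples must lie in [-1, 1)")
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 bit_depth = as.integer(bit_depth), label = as.character(label)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples @ %g Hz (%.3f s), %d-bit, nyquist %g Hz\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              x$bit_depth, nyquist(x)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Nyquist frequency of a recording
#' @param rec A `raw_recording` or `calibrated_recording`.
#' @return Half the sampling rate, in Hz.
#' @export
nyquist <- function(rec) rec$rate_hz / 2

#' Duration of a recording in seconds
#' @param rec A `raw_recording` or `calibrated_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  n <- if (!is.null(rec$samples)) length(rec$samples) else length(rec$pressure_pa)
  n / rec$rate_hz
}

# -- RIFF/WAVE plumbing -------------------------------------------------------
# Minimal PCM reader/writer. Only uncompressed integer PCM (format code 1) is
# supported; anything else (mu-law, float, ADPCM, ...) is rejected.

read_u32 <- function(con) readBin(con, "integer", 1L, size = 4L, endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                                  endian = "little")

#' Read an uncompressed 16-bit PCM WAV file
#'
#' Parses the RIFF container, checks for integer PCM, and returns samples
#' normalised by `2^(bit_depth - 1)` so full-scale negative maps to -1.0.
#' Multi-channel files are reduced to channel 0 with a warning (surveys use
#' single microphones).
#'
#' @param path Path to a `.wav` file.
#' @param label Provenance label to attach; defaults to the file name.
#' @return A [raw_recording()].
#' @export
read_wav <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  read_u32(con)
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; dat <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    id <- rawToChar(id)
    sz <- read_u32(con)
    if (is.na(sz) || sz < 0) stop("truncated WAV file: ", path)
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      if (length(body) < 16L) stop("truncated fmt chunk: ", path)
      fmt <- list(
        code       = sum(as.integer(body[1:2]) * c(1L, 256L)),
        n_channels = sum(as.integer(body[3:4]) * c(1L, 256L)),
        rate       = sum(as.numeric(body[5:8]) * 256^(0:3)),
        bits       = sum(as.integer(body[15:16]) * c(1L, 256L)))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      if (length(dat) < sz) stop("truncated data chunk: ", path)
      break
    } else {
      seek(con, sz + sz %% 2L, origin = "current")
    }
  }
  if (is.null(fmt)) stop("missing fmt chunk: ", path)
  if (is.null(dat)) stop("missing data chunk: ", path)
  if (fmt$code != 1L)
    stop("unsupported WAV format code ", fmt$code,
         " (only uncompressed integer PCM is supported): ", path)
  if (fmt$bits != 16L)
    stop("unsupported bit depth ", fmt$bits, " (only 16-bit PCM): ", path)

  counts <- readBin(dat, "integer", n = length(dat) %/% 2L, size = 2L,
                    signed = TRUE, endian = "little")
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV: taking channel 0 of ", fmt$n_channels)
    counts <- counts[seq(1L, length(counts), by = fmt$n_channels)]
  }
  raw_recording(counts / 2^15, fmt$rate, 16L, label)
}

#' Write a recording as 16-bit PCM mono WAV
#'
#' Samples are quantised by rounding `samples * 2^15` and clamping to the
#' signed 16-bit range; a round trip through [read_wav()] recovers them to
#' within one quantisation step.
#'
#' @param rec A [raw_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  counts <- as.integer(pmin(pmax(round(rec$samples * 2^15), -32768), 32767))
  n <- length(counts)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36L + 2L * n)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(1L); w16(1L)                       # PCM, mono
  w32(rec$rate_hz)
  w32(rec$rate_hz * 2)                   # byte rate
  w16(2L); w16(16L)                      # block align, bits
  writeChar("data", con, eos = NULL); w32(2L * n)
  writeBin(counts, con, size = 2L, endian = "little")
  invisible(path)
}

#' Zero-phase high-pass filter
#'
#' Forward--backward (zero-phase) Chebyshev type-II high-pass, the standard
#' pre-filter applied to ultrasonic-microphone recordings before event
#' analysis (typically 10 kHz, removing the dominant audible-band energy).
#' The design (order 6, 35 dB stopband, stopband edge at 0.55 x cutoff, run
#' in both directions) gives >= 60 dB attenuation one octave below the cutoff
#' and <= 0.1 dB ripple above 1.25 x cutoff while preserving event timing.
#'
#' @param rec A [raw_recording()].
#' @param cutoff_hz Cutoff frequency, `0 <= cutoff_hz < nyquist`. A cutoff of
#'   0 returns the recording unchanged.
#' @return A filtered [raw_recording()].
#' @export
high_pass <- function(rec, cutoff_hz) {
  stopifnot(inherits(rec, "raw_recording"))
  if (cutoff_hz >= nyquist(rec))
    stop("cutoff_hz must be below the Nyquist frequency (", nyquist(rec), " Hz)")
  if (cutoff_hz < 0) stop("cutoff_hz must be non-negative")
  if (cutoff_hz == 0) return(rec)
  flt <- signal::cheby2(6, 35, 0.55 * cutoff_hz / nyquist(rec), type = "high")
  y <- signal::filtfilt(flt, rec$samples)
  # zero-phase filtering cannot grow a bounded passband signal beyond clip,
  # but guard against numerical overshoot at the container boundary
  y <- pmin(pmax(y, -1), 1 - 2^-24)
  raw_recording(y, rec$rate_hz, rec$bit_depth, rec$label)
}
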