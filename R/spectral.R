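# periodic Hann window
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))

# Welch-averaged one-sided band-power spectrum (Pa^2 per bin) of a pressure
# segment. Energy-normalised: summing bins recovers the mean-square pressure
# (Parseval), so band integrals are the calibrated quantity. n_keep bins of
# width df = fs / nfft are returned (DC first).
welch_power <- function(p, fs, nfft, n_keep) {
  w <- hann_window(nfft)
  scale <- 1 / (sum(w^2) * nfft)
  starts <- seq(1L, length(p) - nfft + 1L, by = nfft %/% 2L)
  acc <- numeric(n_keep)
  for (s in starts) {
    X <- fft(p[s:(s + nfft - 1L)] * w)
    pk <- Mod(X[seq_len(n_keep)])^2 * scale
    pk[-1L] <- pk[-1L] * 2                       # one-sided (DC unpaired)
    acc <- acc + pk
  }
  acc / length(starts)
}

#' FFT autospectrum of a one-second epoch
#'
#' Analyser-style linear (unweighted) autospectrum: Welch-averaged Hann
#' periodograms with 50% overlap, segment length `round(rate / (span/n_lines))`
#' samples so the bin width matches `span_hz / n_lines` (15.625 Hz for the
#' default 6400 lines over 0--100 kHz). Levels are per-bin band powers in
#' dB SPL re 20 uPa, energy-normalised so that summing bin energies over a
#' band ([band_level()]) reports the true in-band RMS level; a stationary
#' tone's level is recovered by summing the few bins of its window main lobe.
#'
#' @param rec A `calibrated_recording`.
#' @param epoch_start Epoch start time in seconds (default 0).
#' @param n_lines Number of FFT lines (default 6400).
#' @param span_hz Frequency span (default 100000); must not exceed Nyquist.
#' @param epoch_seconds Epoch length (default 1 s, the analyser convention).
#' @return An object of class `autospectrum` with fields `freq_hz`
#'   (`n_lines + 1` bin centres, DC through span), `level_db`, `df_hz`,
#'   `epoch_index`, `epoch_seconds`, `n_lines`, `span_hz`.
#' @export
autospectrum <- function(rec, epoch_start = 0, n_lines = 6400L,
                         span_hz = 100000, epoch_seconds = 1) {
  stopifnot(inherits(rec, "calibrated_recording"))
  if (span_hz > rec$rate_hz / 2)
    stop("span_hz exceeds the Nyquist frequency (", rec$rate_hz / 2, " Hz)")
  i0 <- floor(epoch_start * rec$rate_hz) + 1L
  i1 <- i0 + as.integer(round(epoch_seconds * rec$rate_hz)) - 1L
  if (i1 > length(rec$pressure_pa))
    stop("epoch extends past the end of the recording")
  nfft <- as.integer(round(rec$rate_hz / (span_hz / n_lines)))
  df <- rec$rate_hz / nfft
  pow <- welch_power(rec$pressure_pa[i0:i1], rec$rate_hz, nfft, n_lines + 1L)
  structure(list(freq_hz = (0:n_lines) * df,
                 level_db = pow_to_db(pow / P_REF^2),
                 df_hz = df,
                 epoch_index = as.integer(epoch_start %/% epoch_seconds),
                 epoch_seconds = epoch_seconds,
                 n_lines = as.integer(n_lines), span_hz = span_hz),
            class = "autospectrum")
}

#' @export
print.autospectrum <- function(x, ...) {
  cat(sprintf("autospectrum: epoch %d, %d lines to %g kHz (bin %g Hz)\n",
              x$epoch_index, x$n_lines, x$span_hz / 1000, x$df_hz))
  invisible(x)
}

#' @export
plot.autospectrum <- function(x, floor_db = -20, ...) {
  y <- pmax(x$level_db, floor_db)
  plot(x$freq_hz / 1000, y, type = "l", xlab = "Frequency (kHz)",
       ylab = "Level (dB SPL / bin)", ...)
  invisible(x)
}

#' One-second-epoch spectrogram
#'
#' Runs [autospectrum()] over consecutive one-second epochs (multi-buffer
#' refreshing every second); a trailing partial second is dropped.
#'
#' @inheritParams autospectrum
#' @return An object of class `noise_spectrogram`: `level_db` is an
#'   `n_epochs x (n_lines + 1)` matrix, `times_s` the epoch start times.
#' @export
spectrogram <- function(rec, n_lines = 6400L, span_hz = 100000,
                        epoch_seconds = 1) {
  stopifnot(inherits(rec, "calibrated_recording"))
  n_ep <- floor(duration_s(rec) / epoch_seconds)
  if (n_ep < 1) stop("recording shorter than one epoch")
  rows <- lapply(seq_len(n_ep) - 1L, function(e)
    autospectrum(rec, e * epoch_seconds, n_lines, span_hz, epoch_seconds)$level_db)
  sp <- structure(list(level_db = do.call(rbind, rows),
                       freq_hz = (0:n_lines) * (span_hz / n_lines),
                       times_s = (seq_len(n_ep) - 1L) * epoch_seconds,
                       df_hz = NA_real_, epoch_seconds = epoch_seconds,
                       n_lines = as.integer(n_lines), span_hz = span_hz),
                  class = "noise_spectrogram")
  sp$df_hz <- rec$rate_hz / round(rec$rate_hz / (span_hz / n_lines))
  sp$freq_hz <- (0:n_lines) * sp$df_hz
  sp
}

#' @export
print.noise_spectrogram <- function(x, ...) {
  cat(sprintf("noise_spectrogram: %d epochs of %g s, %d lines to %g kHz\n",
              nrow(x$level_db), x$epoch_seconds, x$n_lines, x$span_hz / 1000))
  invisible(x)
}

#' @export
plot.noise_spectrogram <- function(x, floor_db = 0, ...) {
  z <- pmax(x$level_db, floor_db)
  image(x$times_s + x$epoch_seconds / 2, x$freq_hz / 1000, z,
        col = hcl.colors(64, "viridis"), xlab = "Time (s)",
        ylab = "Frequency (kHz)", ...)
  invisible(x)
}

#' Extract one epoch of a spectrogram as an autospectrum
#'
#' @param spec A `noise_spectrogram`.
#' @param epoch Zero-based epoch index.
#' @return An `autospectrum`.
#' @export
epoch_spectrum <- function(spec, epoch) {
  stopifnot(inherits(spec, "noise_spectrogram"))
  i <- as.integer(epoch) + 1L
  if (i < 1L || i > nrow(spec$level_db)) stop("epoch out of range")
  structure(list(freq_hz = spec$freq_hz, level_db = spec$level_db[i, ],
                 df_hz = spec$df_hz, epoch_index = as.integer(epoch),
                 epoch_seconds = spec$epoch_seconds,
                 n_lines = spec$n_lines, span_hz = spec$span_hz),
            class = "autospectrum")
}

#' Epoch with the highest band level
#'
#' Selects the one-second epoch maximising the level in a band -- the
#' peak-epoch convention for characterising impulsive noise (the highest
#' level of impact is the one used for analysis). Ties break to the earliest
#' epoch.
#'
#' @param spec A `noise_spectrogram`.
#' @param band A [band()] (default: the full analysis band from 4 Hz).
#' @return The peak epoch as an `autospectrum`.
#' @export
peak_epoch <- function(spec, band = NULL) {
  stopifnot(inherits(spec, "noise_spectrogram"))
  if (is.null(band)) band <- band("Total", 4, spec$span_hz)
  levels <- band_level_epochs(spec, band)
  epoch_spectrum(spec, which.max(levels) - 1L)
}

#' Fine-frame spectrogram for transient structure
#'
#' Short-frame (default 5 ms Hann, 50% overlap) spectrogram resolving the
#' temporal structure that one-second epochs cannot: impact transients and
#' frequency-modulated bursts. Spans to Nyquist by default so components
#' above the 100 kHz analyser span (e.g. 98--102 kHz at a 250 kHz rate)
#' remain visible. Same energy normalisation as [autospectrum()].
#'
#' @param rec A `calibrated_recording`.
#' @param frame_s Frame length in seconds (must be <= 10 ms to resolve
#'   modulation; default 5 ms).
#' @param span_hz Frequency span; default Nyquist.
#' @return An object of class `fine_spectrogram`: `level_db` is an
#'   `n_frames x n_bins` matrix, `times_s` the frame centre times.
#' @export
fine_spectrogram <- function(rec, frame_s = 0.005, span_hz = NULL) {
  stopifnot(inherits(rec, "calibrated_recording"))
  if (frame_s > 0.010) stop("frame_s must be <= 10 ms to resolve modulation")
  if (is.null(span_hz)) span_hz <- rec$rate_hz / 2
  nfft <- as.integer(round(frame_s * rec$rate_hz))
  df <- rec$rate_hz / nfft
  n_keep <- as.integer(floor(span_hz / df)) + 1L
  hop <- nfft %/% 2L
  starts <- seq(1L, length(rec$pressure_pa) - nfft + 1L, by = hop)
  w <- hann_window(nfft)
  scale <- 1 / (sum(w^2) * nfft)
  lev <- matrix(NA_real_, length(starts), n_keep)
  for (j in seq_along(starts)) {
    X <- fft(rec$pressure_pa[starts[j]:(starts[j] + nfft - 1L)] * w)
    pk <- Mod(X[seq_len(n_keep)])^2 * scale
    pk[-1L] <- pk[-1L] * 2
    lev[j, ] <- pow_to_db(pk / P_REF^2)
  }
  structure(list(level_db = lev, freq_hz = (seq_len(n_keep) - 1L) * df,
                 times_s = (starts - 1L + nfft / 2) / rec$rate_hz,
                 df_hz = df, frame_s = frame_s, hop_s = hop / rec$rate_hz,
                 span_hz = span_hz),
            class = "fine_spectrogram")
}

#' @export
print.fine_spectrogram <- function(x, ...) {
  cat(sprintf("fine_spectrogram: %d frames of %g ms, %d bins to %g kHz (bin %g Hz)\n",
              nrow(x$level_db), x$frame_s * 1000, ncol(x$level_db),
              x$span_hz / 1000, x$df_hz))
  invisible(x)
}

#' Export a spectrogram as long-form CSV or JSON
#'
#' Columns `time_s`, `freq_hz`, `level_db_spl`, one row per epoch x bin.
#'
#' @param spec A `noise_spectrogram` or `fine_spectrogram`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spec, path) {
  df <- data.frame(
    time_s = rep(spec$times_s, times = ncol(spec$level_db)),
    freq_hz = rep(spec$freq_hz, each = nrow(spec$level_db)),
    level_db_spl = as.vector(spec$level_db))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(df, path, dataframe = "columns", digits = NA)
  else
    write.csv(df, path, row.names = FALSE)
  invisible(path)
}
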