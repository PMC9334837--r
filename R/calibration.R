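#' Fit a reference-tone calibration model
#'
#' Anchors the count scale to absolute pressure using a pistonphone-style
#' reference tone: 1 kHz at 94 dB SPL, i.e. an RMS pressure of
#' `20e-6 * 10^(94/20) ~= 1.0024 Pa`. Sensitivity is the ratio of the count
#' RMS inside the tone window to that reference pressure. A flat-response
#' measurement microphone makes this single-frequency calibration valid
#' across the band, so no frequency-response correction is applied.
#'
#' Validity checks on the window: the dominant spectral component (Hann
#' window FFT) must lie within `freq_tol` of `ref_frequency_hz`, and the
#' tone-to-residual energy ratio must be at least 20 dB; otherwise the fit
#' aborts with a calibration-failed error.
#'
#' @param tone A [raw_recording()] containing the reference tone.
#' @param tone_window Numeric `c(start, end)` in seconds; duration must be
#'   at least 0.2 s. Defaults to the whole recording.
#' @param ref_level_db_spl Reference tone level (default 94 dB SPL).
#' @param ref_frequency_hz Reference tone frequency (default 1000 Hz).
#' @param freq_tol Fractional tolerance on the dominant frequency (default 0.05).
#' @return An object of class `calibration_model` with fields
#'   `sensitivity_counts_per_pa`, `ref_frequency_hz`, `ref_level_db_spl`,
#'   `fit_rms_error_db` (residual-to-tone level, a quality figure).
#' @export
fit_calibration <- function(tone, tone_window = NULL,
                            ref_level_db_spl = 94, ref_frequency_hz = 1000,
                            freq_tol = 0.05) {
  stopifnot(inherits(tone, "raw_recording"))
  if (is.null(tone_window)) tone_window <- c(0, duration_s(tone))
  i0 <- max(1L, floor(tone_window[1] * tone$rate_hz) + 1L)
  i1 <- min(length(tone$samples), floor(tone_window[2] * tone$rate_hz))
  if (i1 - i0 + 1L < 0.2 * tone$rate_hz)
    stop("tone window must be at least 0.2 s")
  x <- tone$samples[i0:i1]

  # dominant-component check on a Hann-windowed FFT
  n <- length(x)
  w <- hann_window(n)
  X <- fft(x * w)
  pow <- Mod(X[seq_len(n %/% 2 + 1L)])^2
  pow[1L] <- 0                                   # ignore DC
  k <- which.max(pow)
  f_peak <- (k - 1L) * tone$rate_hz / n
  if (abs(f_peak - ref_frequency_hz) > freq_tol * ref_frequency_hz)
    stop(sprintf("calibration failed: dominant component at %.1f Hz, expected %.0f Hz",
                 f_peak, ref_frequency_hz))
  lobe <- max(1L, k - 3L):min(length(pow), k + 3L)
  tone_pow <- sum(pow[lobe])
  resid_pow <- sum(pow) - tone_pow
  tnr <- 10 * log10(tone_pow / max(resid_pow, .Machine$double.xmin))
  if (tnr < 20)
    stop(sprintf("calibration failed: tone-to-residual ratio %.1f dB < 20 dB", tnr))

  p_ref <- db_to_pa(ref_level_db_spl)
  sens <- sqrt(mean(x^2)) / p_ref
  structure(list(sensitivity_counts_per_pa = sens,
                 ref_frequency_hz = ref_frequency_hz,
                 ref_level_db_spl = ref_level_db_spl,
                 fit_rms_error_db = max(-tnr, -200)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model: %.6g counts/Pa (ref %g Hz @ %g dB SPL, residual %g dB)\n",
              x$sensitivity_counts_per_pa, x$ref_frequency_hz,
              x$ref_level_db_spl, x$fit_rms_error_db))
  invisible(x)
}

#' Save / load a calibration model as JSON
#'
#' Allows one pistonphone fit to be reused across all files of a measurement
#' session.
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(is.numeric(obj$sensitivity_counts_per_pa),
            obj$sensitivity_counts_per_pa > 0)
  structure(obj[c("sensitivity_counts_per_pa", "ref_frequency_hz",
                  "ref_level_db_spl", "fit_rms_error_db")],
            class = "calibration_model")
}

#' Convert a raw recording to calibrated pressure
#'
#' @param rec A [raw_recording()].
#' @param model A `calibration_model` from [fit_calibration()].
#' @return An object of class `calibrated_recording` with fields
#'   `pressure_pa`, `rate_hz`, `label`.
#' @export
apply_calibration <- function(rec, model) {
  stopifnot(inherits(rec, "raw_recording"), inherits(model, "calibration_model"))
  if (!is.finite(model$sensitivity_counts_per_pa) ||
      model$sensitivity_counts_per_pa <= 0)
    stop("invalid calibration model")
  structure(list(pressure_pa = rec$samples / model$sensitivity_counts_per_pa,
                 rate_hz = rec$rate_hz, label = rec$label),
            class = "calibrated_recording")
}

#' @export
print.calibrated_recording <- function(x, ...) {
  cat(sprintf("calibrated_recording: %d samples @ %g Hz (%.3f s), overall %.2f dB SPL\n",
              length(x$pressure_pa), x$rate_hz, duration_s(x), spl_rms(x)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Broadband RMS sound pressure level of a window
#'
#' `20 * log10(RMS(pressure) / 20e-6)`, the linear (unweighted) level in
#' dB SPL re 20 uPa. A zero signal reports `-Inf` (below any measurement
#' floor).
#'
#' @param rec A `calibrated_recording`.
#' @param window Numeric `c(start, end)` in seconds; default whole recording.
#' @return Level in dB SPL.
#' @export
spl_rms <- function(rec, window = NULL) {
  stopifnot(inherits(rec, "calibrated_recording"))
  if (is.null(window)) window <- c(0, duration_s(rec))
  i0 <- max(1L, floor(window[1] * rec$rate_hz) + 1L)
  i1 <- min(length(rec$pressure_pa), floor(window[2] * rec$rate_hz))
  if (i1 < i0) stop("empty window")
  pa_to_db(sqrt(mean(rec$pressure_pa[i0:i1]^2)))
}
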