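#' Frequency band definition
#'
#' @param name Band name.
#' @param f_lo_hz,f_hi_hz Band edges in Hz, `f_lo_hz < f_hi_hz`. Band
#'   membership is half-open on bin centres, `[f_lo, f_hi)`, so adjacent
#'   bands sharing an edge (e.g. 10--20 kHz and 20--100 kHz) never
#'   double-count a bin.
#' @return An object of class `band`.
#' @export
band <- function(name, f_lo_hz, f_hi_hz) {
  stopifnot(is.character(name), f_lo_hz < f_hi_hz)
  structure(list(name = name, f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz),
            class = "band")
}

#' The standard survey band set
#'
#' The four bands used throughout facility noise surveys: the full analysis
#' range of the measurement microphone (4 Hz--100 kHz), the human audible
#' range (20 Hz--20 kHz), the range of mouse peak hearing sensitivity
#' (10--20 kHz), and the ultrasonic range (20--100 kHz).
#'
#' @return A named list of [band()] objects.
#' @export
standard_bands <- function() {
  list(total         = band("Total",         4,     100000),
       human_audible = band("Human audible", 20,    20000),
       mouse_peak    = band("Mouse peak",    10000,  20000),
       ultrasonic    = band("Ultrasonic",    20000, 100000))
}

# indices of spectrum bins inside a band; bins below 4 Hz are masked from all
# band math (microphone frequency range starts at 4 Hz)
band_bins <- function(freq_hz, bnd, floor_hz = 4) {
  which(freq_hz >= max(bnd$f_lo_hz, floor_hz) & freq_hz < bnd$f_hi_hz)
}

#' Band-integrated level (delta cursor)
#'
#' Energy sum of the spectrum bins whose centres lie in `[f_lo, f_hi)`:
#' `10*log10(sum 10^(L_i/10))` -- the delta-cursor readout of an FFT
#' analyser, reporting one SPL for the band.
#'
#' @param spec An `autospectrum`.
#' @param bnd A [band()].
#' @return Level in dB SPL.
#' @export
band_level <- function(spec, bnd) {
  stopifnot(inherits(spec, "autospectrum"), inherits(bnd, "band"))
  idx <- band_bins(spec$freq_hz, bnd)
  if (length(idx) == 0L) stop("band contains no spectrum bins")
  pow_to_db(sum(db_to_pow(spec$level_db[idx])))
}

#' Band level of every epoch of a spectrogram
#'
#' @param spec A `noise_spectrogram`.
#' @param bnd A [band()].
#' @return Numeric vector of per-epoch band levels (dB SPL).
#' @export
band_level_epochs <- function(spec, bnd) {
  stopifnot(inherits(spec, "noise_spectrogram"), inherits(bnd, "band"))
  idx <- band_bins(spec$freq_hz, bnd)
  if (length(idx) == 0L) stop("band contains no spectrum bins")
  apply(spec$level_db[, idx, drop = FALSE], 1L,
        function(l) pow_to_db(sum(db_to_pow(l))))
}

#' Background-noise energy subtraction
#'
#' Estimates a source's own level from a measurement made in the presence of
#' background noise: `10*log10(10^(L_meas/10) - 10^(L_bg/10))`. When the
#' measured level exceeds the background by less than 3 dB the subtraction is
#' unreliable (standard acoustics practice); the result is then flagged
#' `background_limited` and `corrected` reports the upper bound
#' `l_meas - 3` dB instead.
#'
#' @param l_meas Measured level, dB SPL (source + background).
#' @param l_bg Background level, dB SPL; `-Inf` means no background.
#' @return A list with `corrected` (dB SPL) and `status`
#'   (`"ok"` or `"background_limited"`).
#' @export
background_correct <- function(l_meas, l_bg) {
  stopifnot(is.numeric(l_meas), is.numeric(l_bg), !is.na(l_meas), !is.na(l_bg))
  if (l_meas - l_bg >= 3)
    list(corrected = pow_to_db(db_to_pow(l_meas) - db_to_pow(l_bg)),
         status = "ok")
  else
    list(corrected = l_meas - 3, status = "background_limited")
}

#' Band-level table (background / measured / difference)
#'
#' The survey reporting shape: one row per band with the background level,
#' the measured (event) level, and their arithmetic difference. No background
#' correction is applied to the difference column -- for high-level impact
#' noise the measured level is dominated by the event, and the plain level
#' increase over background is the quantity reported.
#'
#' @param background,measured Named numeric vectors of band levels (dB SPL);
#'   names must cover every band in `bands`.
#' @param bands A named list of [band()]s (default [standard_bands()]).
#' @return A `band_level_table` (a data frame with columns `band`,
#'   `f_lo_hz`, `f_hi_hz`, `background_db_spl`, `measured_db_spl`,
#'   `difference_db_spl`).
#' @export
difference_table <- function(background, measured, bands = standard_bands()) {
  nm <- names(bands)
  if (!all(nm %in% names(background)) || !all(nm %in% names(measured)))
    stop("background and measured must provide a level for every band")
  out <- data.frame(
    band = vapply(bands, `[[`, "", "name"),
    f_lo_hz = vapply(bands, `[[`, 0, "f_lo_hz"),
    f_hi_hz = vapply(bands, `[[`, 0, "f_hi_hz"),
    background_db_spl = as.numeric(background[nm]),
    measured_db_spl = as.numeric(measured[nm]),
    row.names = NULL)
  out$difference_db_spl <- out$measured_db_spl - out$background_db_spl
  class(out) <- c("band_level_table", "data.frame")
  out
}

#' Mitigation reduction between two conditions
#'
#' Per-band reduction achieved by a noise-control measure:
#' `difference(condition A) - difference(condition B)`, e.g. bare metal
#' impact versus impact on a neoprene mat.
#'
#' @param cond_a,cond_b `band_level_table`s over the same bands.
#' @return `cond_b` with a `reduction_db_spl` column added.
#' @export
reduction_table <- function(cond_a, cond_b) {
  check_same_bands(cond_a, cond_b)
  out <- cond_b
  out$reduction_db_spl <- cond_a$difference_db_spl - cond_b$difference_db_spl
  out
}

#' Enclosure attenuation estimate
#'
#' Per-band attenuation of the same event measured outside versus inside an
#' enclosure (e.g. an individually ventilated cage):
#' `outside measured - inside measured`. Negative values (inside louder than
#' outside, physically implausible for an acoustic path) are clamped to 0
#' and flagged.
#'
#' @param outside,inside `band_level_table`s over the same bands.
#' @return A data frame with columns `band`, `attenuation_db`, `clamped`.
#' @export
attenuation_estimate <- function(outside, inside) {
  check_same_bands(outside, inside)
  att <- outside$measured_db_spl - inside$measured_db_spl
  data.frame(band = outside$band,
             attenuation_db = pmax(att, 0),
             clamped = att < 0,
             row.names = NULL)
}

check_same_bands <- function(a, b) {
  stopifnot(inherits(a, "band_level_table"), inherits(b, "band_level_table"))
  if (nrow(a) != nrow(b) || !all(a$band == b$band) ||
      !all(a$f_lo_hz == b$f_lo_hz) || !all(a$f_hi_hz == b$f_hi_hz))
    stop("band definitions differ between the two tables")
  invisible(TRUE)
}

#' @export
print.band_level_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Read / write a band-level table as CSV (or JSON)
#'
#' Columns: `band`, `f_lo_hz`, `f_hi_hz`, `background_db_spl`,
#' `measured_db_spl`, `difference_db_spl` and optionally
#' `reduction_db_spl`.
#'
#' @param x A `band_level_table`.
#' @param path File path (`.csv` or `.json`).
#' @return `write_band_table` returns `path` invisibly; `read_band_table`
#'   the table.
#' @export
write_band_table <- function(x, path) {
  stopifnot(inherits(x, "band_level_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.data.frame(x), path, dataframe = "rows", digits = NA)
  else
    write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_band_table
#' @export
read_band_table <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else read.csv(path, stringsAsFactors = FALSE)
  need <- c("band", "f_lo_hz", "f_hi_hz", "background_db_spl",
            "measured_db_spl", "difference_db_spl")
  if (!is.data.frame(x) || nrow(x) == 0L || !all(need %in% names(x)))
    stop("malformed band-level table: expected columns ",
         paste(need, collapse = ", "))
  class(x) <- c("band_level_table", "data.frame")
  x
}
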