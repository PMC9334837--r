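# -- canonical fixture scenes -------------------------------------------------
# Three synthetic scenes carrying the statistical structure of the canonical
# facility noise-source investigations: continuous narrowband light
# emissions, metal-impact transients (with neoprene mitigation and IVC
# enclosure variants), and a paired-device walkie-talkie scene with rf-only
# ultrasonic components. Each returns the scene spec plus the annotation the
# analysis needs (calibration window, background/on epochs, bands).

#' Reference forceps-impact survey table
#'
#' Published survey measurements of metal-forceps impact noise bundled as
#' example data: per-band background and measured levels with the printed
#' difference (and, for the neoprene condition, reduction) columns, for three
#' conditions -- bare metal surface, neoprene mat, and inside an IVC.
#'
#' @param condition One of `"metal"`, `"neoprene"`, `"ivc"`.
#' @return A `band_level_table`.
#' @export
survey_reference_table <- function(condition = c("metal", "neoprene", "ivc")) {
  condition <- match.arg(condition)
  path <- system.file("extdata", paste0("forceps_", condition, ".csv"),
                      package = "usnoise", mustWork = TRUE)
  read_band_table(path)
}

#' Ceiling-lights fixture scene
#'
#' A 12 s scene: clean 94 dB SPL / 1 kHz calibration tone in second 0;
#' stationary flat-density background set so the 40.3--47.4 kHz delta band
#' reads 29.0 dB SPL; a continuous narrowband source over 40.3--47.4 kHz,
#' on from 4 s to 9 s, at the level that brings the combined delta-band
#' reading to 33.1 dB SPL. With `inside_ivc = TRUE` a flat 30 dB enclosure
#' attenuation is applied to the source, under which it becomes
#' undetectable against the unchanged local background -- emulating
#' measurement from inside a closed cage.
#'
#' @param seed Integer seed.
#' @param inside_ivc Apply 30 dB flat enclosure attenuation.
#' @return List: `spec` ([scene_spec()]), `cal_window`, `delta_band`
#'   ([band()] 40.3--47.4 kHz), `on_epochs`, `off_epochs` (zero-based).
#' @export
scene_lights <- function(seed, inside_ivc = FALSE) {
  delta <- band("Lights", 40300, 47400)
  bg_delta <- 29.0
  on_delta <- 33.1
  # flat density over the full 4 Hz--100 kHz range hitting 29 dB in the band
  bg_total <- bg_delta + 10 * log10((100000 - 4) / (47400 - 40300))
  src_level <- db_energy_sub(on_delta, bg_delta)
  spec <- scene_spec(
    duration_s = 12, rate_hz = 250000,
    background = data.frame(f_lo_hz = 4, f_hi_hz = 100000,
                            level_db_spl = bg_total),
    sources = list(
      src_cal_tone(0, 1),
      src_narrowband(40300, 47400, src_level, t_on = 4, t_off = 9)),
    enclosure = if (inside_ivc) 30 else NULL,
    seed = seed,
    label = if (inside_ivc) "lights scene (inside IVC)" else "lights scene")
  list(spec = spec, cal_window = c(0, 1), delta_band = delta,
       on_epochs = 4:8, off_epochs = c(1:3, 9:11),
       bg_delta_db = bg_delta, on_delta_db = on_delta)
}

#' Forceps-impact fixture scene
#'
#' A 10 s scene: calibration tone in second 0; stationary background shaped
#' to the per-band background levels of the reference survey table for the
#' chosen condition; one broadband impact transient (20 ms exponential
#' decay) with onset at 5.1 s, shaped so the standard-band levels of the
#' peak epoch match the table's measured column. `enclosure_db` applies a
#' flat attenuation to the impact source (the IVC emulation used for
#' attenuation estimates; background and calibration tone are local to the
#' microphone and unattenuated).
#'
#' @param seed Integer seed.
#' @param surface `"metal"` or `"neoprene"`.
#' @param enclosure_db Flat enclosure attenuation in dB (default 0).
#' @return List: `spec`, `cal_window`, `impact_epoch` (zero-based),
#'   `bg_epochs`, `table` (the reference `band_level_table` used).
#' @export
scene_forceps <- function(seed, surface = c("metal", "neoprene"),
                          enclosure_db = 0) {
  surface <- match.arg(surface)
  tab <- survey_reference_table(surface)
  nm <- c(Total = "total", `Human audible` = "human_audible",
          `Mouse peak` = "mouse_peak", Ultrasonic = "ultrasonic")
  bg <- structure(tab$background_db_spl, names = nm[tab$band])
  meas <- structure(tab$measured_db_spl, names = nm[tab$band])
  impact_own <- mapply(db_energy_sub, meas, bg)       # impact alone, per band
  spec <- scene_spec(
    duration_s = 10, rate_hz = 250000,
    background = background_cells(bg),
    sources = list(
      src_cal_tone(0, 1),
      src_impact(5.1, impact_own)),
    enclosure = if (enclosure_db > 0) enclosure_db else NULL,
    seed = seed,
    label = sprintf("forceps scene (%s%s)", surface,
                    if (enclosure_db > 0)
                      sprintf(", %g dB enclosure", enclosure_db) else ""))
  list(spec = spec, cal_window = c(0, 1), impact_epoch = 5L,
       bg_epochs = c(1:4, 7:9), table = tab)
}

#' Walkie-talkie paired-device fixture scene
#'
#' A 10 s paired scene: calibration tone in second 0; flat background;
#' repeated 0.3 s bursts, each combining an acoustic audible beep
#' (1--7 kHz) present on both devices with two rf-only frequency-modulated
#' ultrasonic components (sweeping 48--50 kHz and 98--102 kHz) that only the
#' rf-susceptible device A records. Burst onsets sit inside distinct
#' one-second epochs so background epochs stay clean.
#'
#' @param seed Integer seed.
#' @param n_bursts Number of bursts (default 3; onsets at 3.2, 5.2, 7.2 s).
#' @return List: `spec`, `artifact` (the rf-only [src_fm_burst()]),
#'   `cal_window`, `bg_epochs`, `burst_epochs`, `component_bands` (list of
#'   the two swept ranges).
#' @export
scene_walkie <- function(seed, n_bursts = 3) {
  t_starts <- c(3.2, 5.2, 7.2)[seq_len(min(n_bursts, 3L))]
  artifact <- src_fm_burst(
    components = list(
      list(f_lo_hz = 48000, f_hi_hz = 50000, level_db_spl = 55),
      list(f_lo_hz = 98000, f_hi_hz = 102000, level_db_spl = 55)),
    t_starts = t_starts, burst_s = 0.3, rf_only = TRUE)
  spec <- scene_spec(
    duration_s = 10, rate_hz = 250000,
    background = data.frame(f_lo_hz = 4, f_hi_hz = 100000,
                            level_db_spl = 50),
    sources = list(
      src_cal_tone(0, 1),
      src_beep(1000, 7000, level_db_spl = 75, t_starts = t_starts,
               burst_s = 0.3)),
    seed = seed, label = "walkie-talkie scene")
  burst_ep <- unique(floor(t_starts))
  list(spec = spec, artifact = artifact, cal_window = c(0, 1),
       bg_epochs = setdiff(1:9, burst_ep), burst_epochs = burst_ep,
       component_bands = list(c(48000, 50000), c(98000, 102000)))
}

#' Calibrate a rendered scene with its own reference tone
#'
#' Convenience wrapper: fits the calibration on the scene's tone window and
#' returns the calibrated recording.
#'
#' @param scene Result of [render_scene()] (or a `raw_recording`).
#' @param cal_window `c(start, end)` of the reference tone, seconds.
#' @return A `calibrated_recording`.
#' @export
calibrate_scene <- function(scene, cal_window = c(0, 1)) {
  rec <- if (inherits(scene, "raw_recording")) scene else scene$rec
  apply_calibration(rec, fit_calibration(rec, cal_window))
}
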