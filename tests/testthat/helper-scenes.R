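# shared fixtures, memoised: scene rendering at 250 kHz is the expensive
# step, and several test files interrogate the same canonical scenes

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env))
    assign(name, fn(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a known-sensitivity calibration model (for scenes rendered with fixed
# counts_per_pa, bypassing the tone fit)
known_cal <- function(sens) {
  structure(list(sensitivity_counts_per_pa = sens, ref_frequency_hz = 1000,
                 ref_level_db_spl = 94, fit_rms_error_db = 0),
            class = "calibration_model")
}

# calibrated 1 s sine recording at a given SPL and frequency
tone_pressure <- function(level_db, freq_hz, rate_hz = 250000, dur_s = 1) {
  t <- (0:(rate_hz * dur_s - 1)) / rate_hz
  structure(list(pressure_pa = sqrt(2) * db_to_pa(level_db) *
                   sin(2 * pi * freq_hz * t),
                 rate_hz = rate_hz, label = "tone"),
            class = "calibrated_recording")
}

# facility-like background band levels: jitter around the bundled reference
# background row, infrasound cell pinned well below the human-audible band
# (see the methods vignette on analyser resolution below ~8 Hz)
random_background_levels <- function() {
  ha <- runif(1, 70, 90); mp <- runif(1, 40, 60); us <- runif(1, 35, 55)
  ha <- db_energy_sum(ha, mp)
  tot <- db_energy_sum(ha, us, ha - 18)
  c(total = tot, human_audible = ha, mouse_peak = mp, ultrasonic = us)
}

lights_analysis <- function(seed, inside_ivc = FALSE) {
  key <- sprintf("lights_%d_%d", seed, inside_ivc)
  fixture(key, function() {
    fx <- scene_lights(seed, inside_ivc = inside_ivc)
    sc <- render_scene(fx$spec)
    cr <- calibrate_scene(sc, fx$cal_window)
    sp <- spectrogram(cr)
    bg <- fit_background(sp, fx$off_epochs)
    list(fx = fx, scene = sc, cal = cr, spec = sp, bg = bg)
  })
}

forceps_analysis <- function(seed, surface = "metal", enclosure_db = 0) {
  key <- sprintf("forceps_%d_%s_%g", seed, surface, enclosure_db)
  fixture(key, function() {
    fx <- scene_forceps(seed, surface, enclosure_db = enclosure_db)
    sc <- render_scene(fx$spec)
    cr <- calibrate_scene(sc, fx$cal_window)
    sp <- spectrogram(cr)
    bg <- fit_background(sp, fx$bg_epochs)
    bands <- standard_bands()
    pk <- peak_epoch(sp)
    tab <- difference_table(
      vapply(bands, function(b) background_band_level(bg, b), 0),
      vapply(bands, function(b) band_level(pk, b), 0))
    list(fx = fx, scene = sc, cal = cr, spec = sp, bg = bg, table = tab)
  })
}

walkie_analysis <- function(seed) {
  key <- sprintf("walkie_%d", seed)
  fixture(key, function() {
    fx <- scene_walkie(seed)
    pair <- render_paired_devices(fx$spec, fx$artifact)
    ca <- calibrate_scene(pair$rec_a, fx$cal_window)
    cb <- calibrate_scene(pair$rec_b, fx$cal_window)
    bga <- fit_background(spectrogram(ca), fx$bg_epochs)
    bgb <- fit_background(spectrogram(cb), fx$bg_epochs)
    ev_a <- detect_fm(fine_spectrogram(ca), bga)
    ev_b <- detect_fm(fine_spectrogram(cb), bgb)
    list(fx = fx, pair = pair, ev_a = ev_a, ev_b = ev_b,
         flagged = rf_screen(ev_a, ev_b))
  })
}

reference_csv <- function(condition) {
  system.file("extdata", paste0("forceps_", condition, ".csv"),
              package = "usnoise", mustWork = TRUE)
}
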