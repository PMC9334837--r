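test_that("rendering is bit-deterministic given the seed", {
  fx <- scene_lights(seed = 4)
  a <- render_scene(fx$spec)
  b <- render_scene(fx$spec)
  expect_identical(a$rec$samples, b$rec$samples)
  expect_identical(a$truth$counts_per_pa, b$truth$counts_per_pa)
  c <- render_scene(scene_lights(seed = 5)$spec)
  expect_false(identical(a$rec$samples, c$rec$samples))
})

test_that("a scene spec requires a seed and a sane duration", {
  expect_error(scene_spec(duration_s = 10), "seed is mandatory")
  expect_error(scene_spec(duration_s = 1, seed = 1), "duration_s >= 2")
})

test_that("the calibration tone renders at exactly 94 dB SPL equivalent", {
  for (seed in c(3, 9, 27)) {
    fx <- scene_lights(seed = seed)
    sc <- render_scene(fx$spec)
    cr <- calibrate_scene(sc, fx$cal_window)
    expect_equal(spl_rms(cr, c(0.1, 0.9)), 94, tolerance = 0.1)
  }
})

test_that("lights fixture reproduces the delta-cursor readings", {
  la <- lights_analysis(11)
  lv <- band_level_epochs(la$spec, la$fx$delta_band)
  expect_equal(mean(lv[la$fx$on_epochs + 1]), 33.1, tolerance = 0.3)
  expect_equal(mean(lv[la$fx$off_epochs + 1]), 29.0, tolerance = 0.3)
})

test_that("narrowband truth recovery holds across seeds", {
  for (seed in c(101, 202, 303)) {
    fx <- scene_lights(seed = seed)
    cr <- calibrate_scene(render_scene(fx$spec), fx$cal_window)
    sp <- spectrogram(cr)
    lv <- band_level_epochs(sp, fx$delta_band)
    expect_equal(mean(lv[fx$on_epochs + 1]), 33.1, tolerance = 0.3)
    expect_equal(mean(lv[fx$off_epochs + 1]), 29.0, tolerance = 0.3)
  }
})

test_that("forceps fixture reproduces the reference difference columns", {
  for (key in list(c("metal", 7), c("neoprene", 7), c("metal", 23))) {
    fa <- forceps_analysis(as.integer(key[2]), key[1])
    expect_lt(max(abs(fa$table$difference_db_spl -
                      fa$fx$table$difference_db_spl)), 0.5)
  }
})

test_that("a configured flat enclosure is recovered as attenuation", {
  outside <- forceps_analysis(7, "metal")
  inside <- forceps_analysis(7, "metal", enclosure_db = 10)
  att <- attenuation_estimate(outside$table, inside$table)
  expect_true(all(abs(att$attenuation_db - 10) < 0.5))
  expect_false(any(att$clamped))
})

test_that("energy additivity: two equal disjoint sources sum to +3.01 dB", {
  mk <- function(two) {
    srcs <- list(src_narrowband(30000, 40000, 60, t_on = 0, t_off = 4))
    if (two) srcs <- c(srcs, list(src_narrowband(60000, 70000, 60,
                                                 t_on = 0, t_off = 4)))
    spec <- scene_spec(duration_s = 4, background = NULL, sources = srcs,
                       seed = 66, counts_per_pa = 0.002)
    cr <- apply_calibration(render_scene(spec)$rec, known_cal(0.002))
    band_level(autospectrum(cr, 1), band("tot", 4, 100000))
  }
  expect_equal(mk(TRUE) - mk(FALSE), 10 * log10(2), tolerance = 0.2)
})

test_that("apply_enclosure shapes levels per band and 0 dB is identity", {
  fx <- scene_lights(seed = 13)
  sc <- render_scene(fx$spec)
  same <- apply_enclosure(sc$rec, 0)
  expect_equal(same$samples, sc$rec$samples, tolerance = 1e-12)
  att <- apply_enclosure(sc$rec, 20)
  expect_equal(max(abs(att$samples)) / max(abs(sc$rec$samples)), 0.1,
               tolerance = 1e-9)
  # per-band shaping: only the delta band attenuated
  cr <- calibrate_scene(sc, fx$cal_window)
  shaped <- apply_enclosure(cr, data.frame(f_lo_hz = 40000, f_hi_hz = 48000,
                                           attenuation_db = 12))
  sp0 <- autospectrum(cr, 5); sp1 <- autospectrum(shaped, 5)
  expect_equal(band_level(sp0, fx$delta_band) -
                 band_level(sp1, fx$delta_band), 12, tolerance = 0.3)
  lowband <- band("low", 4, 30000)
  expect_equal(band_level(sp0, lowband), band_level(sp1, lowband),
               tolerance = 0.05)
})

test_that("clipping at fixed sensitivity raises a headroom error naming a source", {
  spec <- scene_spec(duration_s = 2, background = NULL,
                     sources = list(src_cal_tone(0, 1, level_db_spl = 94)),
                     seed = 2, counts_per_pa = 1)   # 1.42 Pa peak -> clips
  expect_error(render_scene(spec), "headroom.*cal_tone")
})

test_that("truth sidecars label scenes synthetic and record the gain used", {
  sc <- render_scene(scene_lights(seed = 8)$spec)
  expect_true(sc$truth$synthetic)
  expect_equal(sc$truth$schema, "usnoise-truth/1")
  expect_true(is.numeric(sc$truth$counts_per_pa))
  path <- withr::local_tempfile(fileext = ".wav")
  write_scene(sc, path)
  side <- jsonlite::read_json(sub("\\.wav$", ".truth.json", path),
                              simplifyVector = TRUE)
  expect_true(side$synthetic)
  expect_equal(side$seed, 8)
  # WAV round trip of the rendered scene is exact to one quantisation step
  back <- read_wav(path)
  expect_lt(max(abs(back$samples - sc$rec$samples)), 2^-15)
})

test_that("paired rendering injects rf content into the susceptible device only", {
  fx <- scene_walkie(seed = 5)
  pair <- render_paired_devices(fx$spec, fx$artifact)
  # device B equals the acoustic content; device A differs during bursts
  t0 <- round(3.2 * 250000); t1 <- round(3.5 * 250000)
  expect_false(isTRUE(all.equal(pair$rec_a$samples[t0:t1],
                                pair$rec_b$samples[t0:t1])))
  quiet <- round(1.2 * 250000):round(1.4 * 250000)
  sa <- pair$rec_a$samples[quiet] / pair$truth$counts_per_pa_a
  sb <- pair$rec_b$samples[quiet] / pair$truth$counts_per_pa_b
  expect_equal(sa, sb, tolerance = 1e-12)
  # artifact disabled: identical scenes
  pair0 <- render_paired_devices(fx$spec)
  expect_identical(pair0$rec_a$samples, pair0$rec_b$samples)
  # no rf-immune reference is a spec error
  expect_error(render_paired_devices(fx$spec, fx$artifact,
                                     device_a = list(rf_susceptible = TRUE),
                                     device_b = list(rf_susceptible = TRUE)),
               "rf_susceptible")
})
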