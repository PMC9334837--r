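test_that("background model recovers the configured spectrum and is robust", {
  la <- lights_analysis(11)
  bg <- la$bg
  # configured: flat density over 4 Hz - 100 kHz at the scene's total level;
  # per-bin medians are unbiased and band aggregates recover the configured
  # in-band levels (individual 15.625 Hz bins fluctuate with only a few
  # background epochs, so the contract is on the aggregated model)
  cells <- la$scene$truth$background
  dens_db <- cells$rendered_db_spl - 10 * log10(cells$f_hi_hz - cells$f_lo_hz)
  expected_bin <- dens_db + 10 * log10(15.625)
  mid <- bg$freq_hz > 1000 & bg$freq_hz < 99000   # away from shaped edges
  expect_lt(abs(mean(bg$median_db[mid]) - expected_bin), 0.2)
  in_band <- function(lo, hi) dens_db + 10 * log10(hi - lo)
  expect_equal(background_band_level(bg, band("mid", 30000, 60000)),
               in_band(30000, 60000), tolerance = 0.5)
  expect_equal(background_band_level(bg, standard_bands()$ultrasonic),
               in_band(20000, 100000), tolerance = 0.5)

  # one contaminated epoch (+30 dB) barely moves the median model
  dirty <- la$spec
  dirty$level_db[2, ] <- dirty$level_db[2, ] + 30
  bg_dirty <- fit_background(dirty, la$fx$off_epochs)
  shift <- background_band_level(bg_dirty, standard_bands()$ultrasonic) -
    background_band_level(bg, standard_bands()$ultrasonic)
  expect_lt(abs(shift), 0.5)

  expect_error(fit_background(la$spec, integer(0)), "insufficient background")
  expect_error(fit_background(la$spec, c(0, 1)), "insufficient background")
})

test_that("continuous narrowband source is detected with its band extent", {
  la <- lights_analysis(11)
  ev <- detect_tonal(la$spec, la$bg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "tonal")
  expect_equal(ev$t_start_s, 4); expect_equal(ev$t_end_s, 9)
  expect_lt(abs(ev$f_lo_hz - 40300), 2 * la$spec$df_hz)
  expect_lt(abs(ev$f_hi_hz - 47400), 2 * la$spec$df_hz)
})

test_that("enclosure attenuation renders the lights undetectable inside", {
  li <- lights_analysis(11, inside_ivc = TRUE)
  expect_equal(nrow(detect_tonal(li$spec, li$bg)), 0L)
})

test_that("pure background yields no tonal events", {
  fa <- forceps_analysis(7)
  # restrict to background epochs only: drop the impact epoch
  sub <- fa$spec
  keep <- fa$fx$bg_epochs + 1L
  sub$level_db <- sub$level_db[keep, , drop = FALSE]
  sub$times_s <- sub$times_s[keep]
  bg <- fit_background(sub, seq_along(keep) - 1L)
  expect_equal(nrow(detect_tonal(sub, bg)), 0L)
})

test_that("broadband impacts are detected with the printed ultrasonic excess", {
  fa <- forceps_analysis(7)
  ev <- detect_impact(fa$spec, fa$bg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "impact")
  expect_equal(floor(ev$t_start_s), 5)
  expect_gt(ev$f_hi_hz - ev$f_lo_hz, 50000)
  expect_equal(ev$excess_db, 49.34, tolerance = 1)

  neo <- forceps_analysis(7, "neoprene")
  ev2 <- detect_impact(neo$spec, neo$bg)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$excess_db, 13.27, tolerance = 1)
})

test_that("a tonal-only scene produces no impact events", {
  la <- lights_analysis(11)
  expect_equal(nrow(detect_impact(la$spec, la$bg)), 0L)
})

test_that("FM bursts resolve into per-component tracks with swept ranges", {
  wa <- walkie_analysis(5)
  fm_us <- wa$ev_a[wa$ev_a$kind == "fm" & wa$ev_a$f_lo_hz >= 20000, ]
  # three bursts x two ultrasonic components
  expect_equal(nrow(fm_us), 6L)
  lo_comp <- fm_us[fm_us$f_lo_hz < 60000, ]
  hi_comp <- fm_us[fm_us$f_lo_hz >= 60000, ]
  expect_equal(nrow(lo_comp), 3L)
  expect_lt(max(abs(lo_comp$f_lo_hz - 48000)), 200)  # one fine bin
  expect_lt(max(abs(lo_comp$f_hi_hz - 50000)), 200)
  expect_lt(max(abs(hi_comp$f_lo_hz - 98000)), 200)
  expect_lt(max(abs(hi_comp$f_hi_hz - 102000)), 200)
  # simultaneous components share a group id
  for (g in unique(fm_us$group)) {
    comp <- fm_us[fm_us$group == g, ]
    expect_equal(nrow(comp), 2L)
  }
  # the rf-immune device sees no ultrasonic components at all
  expect_equal(nrow(wa$ev_b[wa$ev_b$f_lo_hz >= 20000, ]), 0L)
})

test_that("a steady tone is classified tonal by the fine-frame tracker", {
  fs <- 250000
  t <- (0:(3 * fs - 1)) / fs
  x <- sqrt(2) * db_to_pa(60) * sin(2 * pi * 50000 * t) +
       rnorm(3 * fs) * db_to_pa(20)
  rec <- structure(list(pressure_pa = x, rate_hz = fs, label = ""),
                   class = "calibrated_recording")
  sp <- spectrogram(rec)
  bg <- fit_background(sp, 0:2)   # tone present throughout: bg includes it,
  bg$median_db[] <- -10           # so substitute a low flat floor
  ev <- detect_fm(fine_spectrogram(rec), bg)
  expect_true(nrow(ev) >= 1L)
  expect_true(all(ev$kind == "tonal"))
})

test_that("detection is monotone in source level", {
  base <- scene_lights(seed = 77)
  for (boost in c(0, 10)) {
    spec <- base$spec
    spec$sources[[2]]$level_db_spl <- spec$sources[[2]]$level_db_spl + boost
    cr <- calibrate_scene(render_scene(spec), base$cal_window)
    sp <- spectrogram(cr)
    bg <- fit_background(sp, base$off_epochs)
    expect_gte(nrow(detect_tonal(sp, bg)), 1L)
  }
})

test_that("pure background scenes stay below one false event per 100 epochs", {
  n_events <- 0L; n_epochs <- 0L
  for (i in 1:10) {
    set.seed(900 + i)
    lv <- random_background_levels()
    spec <- scene_spec(duration_s = 10, background = background_cells(lv),
                       sources = list(), seed = 900 + i, counts_per_pa = NULL)
    cr <- apply_calibration(render_scene(spec)$rec, known_cal(1))
    sp <- spectrogram(cr)
    bg <- fit_background(sp, 0:4)
    scan <- 5:9                       # epochs not used to fit the background
    sub <- sp
    sub$level_db <- sub$level_db[scan + 1L, , drop = FALSE]
    sub$times_s <- sub$times_s[scan + 1L]
    n_events <- n_events + nrow(detect_tonal(sub, bg)) +
      nrow(detect_impact(sub, bg))
    n_epochs <- n_epochs + length(scan)
  }
  expect_equal(n_epochs, 50L)
  expect_lte(n_events, 1L)
})

test_that("rf screening flags only unmatched ultrasonic events", {
  wa <- walkie_analysis(5)
  fl <- wa$flagged
  flagged <- grepl("suspected_rf", fl$flags)
  expect_true(all(fl$f_lo_hz[flagged] >= 20000))
  expect_true(all(fl$kind[flagged] == "fm"))
  expect_equal(sum(flagged), 6L)                  # 2 components x 3 bursts
  # the audible beep and calibration tone are never flagged
  expect_false(any(flagged & fl$f_lo_hz < 20000))
  # concordant detection (lights seen by both devices) -> no flags
  same <- rf_screen(wa$ev_b, wa$ev_b)
  expect_false(any(grepl("suspected_rf", same$flags)))
})

test_that("rf screening withholds the flag when the reference floor is too high", {
  wa <- walkie_analysis(5)
  # pretend device B could only detect events > 40 dB excess
  fl <- rf_screen(wa$ev_a, wa$ev_b, b_min_excess_db = 40)
  us <- fl$f_lo_hz >= 20000 & fl$kind == "fm"
  expect_false(any(grepl("suspected_rf", fl$flags[us])))
})

test_that("rf screening is invariant to a common time shift", {
  wa <- walkie_analysis(5)
  shift <- function(ev, dt) { ev$t_start_s <- ev$t_start_s + dt
                              ev$t_end_s <- ev$t_end_s + dt; ev }
  f0 <- rf_screen(wa$ev_a, wa$ev_b)
  f1 <- rf_screen(shift(wa$ev_a, 2.5), shift(wa$ev_b, 2.5))
  expect_equal(f1$flags, f0$flags)
})

test_that("barrier plausibility flags implausible through-wall levels", {
  mk <- function(level) detection_events(
    kind = "fm", t_start_s = 1, t_end_s = 2, f_lo_hz = 48000, f_hi_hz = 50000,
    peak_level_db_spl = level, excess_db = 20, group = 1L, flags = "")
  # undiminished inside an enclosure rated 10 dB: physically implausible
  fl <- barrier_plausibility(mk(55), mk(55), expected_attenuation_db = 10)
  expect_setequal(fl, c("inside_ivc_audible", "through_barrier"))
  # attenuated as expected (9.8 dB of a nominal 10): audible inside, plausible
  fl2 <- barrier_plausibility(mk(112.11), mk(102.3), expected_attenuation_db = 10)
  expect_equal(fl2, "inside_ivc_audible")
  # not detected inside: no flags
  expect_length(barrier_plausibility(mk(55), NULL, 10), 0L)
})

test_that("events export to CSV with flags intact", {
  wa <- walkie_analysis(5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(wa$flagged, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(wa$flagged))
  expect_equal(sum(grepl("suspected_rf", back$flags)), 6L)
})
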