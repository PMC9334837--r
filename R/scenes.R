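# -- synthetic acoustic scenes ------------------------------------------------
# Seeded, calibrated WAV scenes with the statistical structure of facility
# noise surveys: stationary shaped background, a clean 94 dB SPL / 1 kHz
# reference tone, continuous narrowband sources, broadband impact transients,
# FM bursts and audible beeps, optional enclosure attenuation, and rf-only
# components that bypass all acoustic transforms (emulating radio-frequency
# pickup by a susceptible device).

#' Source specifications for synthetic scenes
#'
#' Constructors for the source kinds understood by [render_scene()]. Levels
#' are the source's own in-band SPL (dB re 20 uPa); the renderer scales each
#' realisation exactly to its target.
#'
#' * `src_cal_tone`: pistonphone-style reference tone. Rendered clean (no
#'   background, no enclosure), mirroring closed-coupler calibration.
#' * `src_narrowband`: spectrally flat band-limited Gaussian noise, gated on
#'   between `t_on` and `t_off` with 10 ms raised-cosine edges (continuous
#'   sources such as fluorescent ceiling lights).
#' * `src_impact`: broadband transient with exponential decay, spectrally
#'   shaped so the standard-band levels over the one-second epoch containing
#'   the onset hit `band_levels` (named `total`, `human_audible`,
#'   `mouse_peak`, `ultrasonic`).
#' * `src_fm_burst`: summed linear-sweep sinusoids; each component sweeps
#'   `f_lo -> f_hi` over every burst. `rf_only = TRUE` marks the source as
#'   radio-frequency pickup: injected only into rf-susceptible devices and
#'   exempt from enclosure attenuation.
#' * `src_beep`: band-limited noise bursts (the audible transmit beep of a
#'   walkie-talkie, nominally 1--7 kHz).
#'
#' @param t_start,dur,t_on,t_off,t_starts,burst_s Timing in seconds.
#' @param level_db_spl In-band SPL target (for `src_impact`, a named vector
#'   over the standard bands).
#' @param freq_hz,f_lo_hz,f_hi_hz Frequency extent in Hz.
#' @param band_levels Named per-band epoch levels for `src_impact`.
#' @param decay_s Exponential decay constant of the impact envelope
#'   (default 20 ms: transient enough to be confined to one epoch, long
#'   enough to be visible in 5 ms frames).
#' @param components For `src_fm_burst`, a list of
#'   `list(f_lo_hz=, f_hi_hz=, level_db_spl=)`.
#' @param rf_only Logical; see above.
#' @return A `source_spec` list.
#' @name source_spec
NULL

#' @rdname source_spec
#' @export
src_cal_tone <- function(t_start = 0, dur = 1, level_db_spl = 94,
                         freq_hz = 1000) {
  structure(list(kind = "cal_tone", t_start = t_start, dur = dur,
                 level_db_spl = level_db_spl, freq_hz = freq_hz),
            class = "source_spec")
}

#' @rdname source_spec
#' @export
src_narrowband <- function(f_lo_hz, f_hi_hz, level_db_spl, t_on, t_off) {
  stopifnot(f_lo_hz < f_hi_hz)
  structure(list(kind = "narrowband", f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 level_db_spl = level_db_spl, t_on = t_on, t_off = t_off),
            class = "source_spec")
}

#' @rdname source_spec
#' @export
src_impact <- function(t_start, band_levels, decay_s = 0.02) {
  stopifnot(all(c("total", "human_audible", "mouse_peak", "ultrasonic") %in%
                names(band_levels)))
  structure(list(kind = "impact", t_start = t_start,
                 band_levels = band_levels, decay_s = decay_s),
            class = "source_spec")
}

#' @rdname source_spec
#' @export
src_fm_burst <- function(components, t_starts, burst_s = 0.3, rf_only = FALSE) {
  structure(list(kind = "fm_burst", components = components,
                 t_starts = t_starts, burst_s = burst_s, rf_only = rf_only),
            class = "source_spec")
}

#' @rdname source_spec
#' @export
src_beep <- function(f_lo_hz = 1000, f_hi_hz = 7000, level_db_spl,
                     t_starts, burst_s = 0.3) {
  structure(list(kind = "beep", f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                 level_db_spl = level_db_spl, t_starts = t_starts,
                 burst_s = burst_s),
            class = "source_spec")
}

#' Scene specification
#'
#' @param duration_s Scene duration in seconds (>= 2).
#' @param rate_hz Sampling rate (default 250000; 384000 emulates a
#'   full-spectrum logger).
#' @param background Data frame of piecewise-flat background cells with
#'   columns `f_lo_hz`, `f_hi_hz`, `level_db_spl` (in-cell total SPL), e.g.
#'   from [background_cells()]. `NULL` for silence.
#' @param sources List of [source_spec] objects.
#' @param enclosure `NULL`, a flat attenuation in dB, or a data frame
#'   `f_lo_hz`, `f_hi_hz`, `attenuation_db`. Applied to acoustic sources
#'   propagating through the barrier -- never to the background (the noise
#'   floor at the microphone), the calibration tone (closed-coupler), or
#'   rf-only content.
#' @param device `list(gain_db =, rf_susceptible =)`.
#' @param seed Integer seed; mandatory (scenes are reproducible).
#' @param counts_per_pa Fixed recorder sensitivity; `NULL` (default)
#'   auto-scales so the loudest sample sits at half full scale.
#' @param label Provenance label.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(duration_s, rate_hz = 250000, background = NULL,
                       sources = list(), enclosure = NULL,
                       device = list(gain_db = 0, rf_susceptible = FALSE),
                       seed, counts_per_pa = NULL, label = "synthetic scene") {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(duration_s >= 2, rate_hz > 0)
  structure(list(duration_s = duration_s, rate_hz = rate_hz,
                 background = background, sources = sources,
                 enclosure = enclosure, device = device,
                 seed = as.integer(seed), counts_per_pa = counts_per_pa,
                 label = label),
            class = "scene_spec")
}

#' Disjoint background cells from standard-band levels
#'
#' Converts the (overlapping) standard-band levels into disjoint spectral
#' cells (4--20 Hz, 20 Hz--10 kHz, 10--20 kHz, 20--100 kHz) by energy
#' subtraction, clamping any negative implied cell energy to zero (which can
#' arise from rounded published levels).
#'
#' @param levels Named vector (`total`, `human_audible`, `mouse_peak`,
#'   `ultrasonic`) of band SPLs.
#' @return Data frame with `f_lo_hz`, `f_hi_hz`, `level_db_spl`.
#' @export
background_cells <- function(levels) {
  lv <- function(nm) as.numeric(levels[[nm]])
  cells <- data.frame(
    f_lo_hz = c(4, 20, 10000, 20000),
    f_hi_hz = c(20, 10000, 20000, 100000),
    level_db_spl = c(
      pow_to_db(max(db_to_pow(lv("total")) - db_to_pow(lv("human_audible")) -
                    db_to_pow(lv("ultrasonic")), 0)),
      pow_to_db(max(db_to_pow(lv("human_audible")) -
                    db_to_pow(lv("mouse_peak")), 0)),
      lv("mouse_peak"),
      lv("ultrasonic")))
  cells
}

# Stationary background shaped to piecewise-flat cells with exact per-cell
# energies. Cell boundaries where the spectral density drops are smoothed by
# a log-linear ramp carved out of the louder cell (width up to 2 kHz or 30%
# of the cell), because a brick-wall step of tens of dB would leak analyser
# window sidelobe energy into the quiet neighbour; real facility backgrounds
# roll off smoothly. Per-cell energies are normalised exactly in the
# frequency domain, so band levels still hit their targets.
render_shaped_background <- function(n, rate_hz, cells, per_cell = FALSE) {
  df <- rate_hz / n
  kmax <- n %/% 2 - 1L                      # bins 1..kmax, freq k*df
  f <- (1:kmax) * df
  dens <- numeric(kmax)                     # linear density, Pa^2/Hz
  cells <- cells[order(cells$f_lo_hz), , drop = FALSE]
  e_cell <- db_to_pa(cells$rendered_db_spl)^2
  width <- cells$f_hi_hz - cells$f_lo_hz
  d_plateau <- e_cell / width
  sel_list <- lapply(seq_len(nrow(cells)), function(i)
    which(f >= cells$f_lo_hz[i] & f < cells$f_hi_hz[i]))
  for (i in seq_len(nrow(cells))) {
    sel <- sel_list[[i]]
    if (length(sel) == 0L || e_cell[i] <= 0) next
    rel <- rep(1, length(sel))
    for (j in seq_len(nrow(cells))[-i]) {
      if (e_cell[j] <= 0) next
      ratio <- d_plateau[j] / d_plateau[i]
      if (ratio >= 10^(-3 / 10)) next       # only smooth drops > 3 dB
      w <- min(2000, 0.3 * width[i], max(4 * df, 0.3 * width[i]))
      if (abs(cells$f_hi_hz[i] - cells$f_lo_hz[j]) < df) {        # drop to the right
        z <- f[sel] > cells$f_hi_hz[i] - w
        rel[z] <- ratio^((f[sel][z] - (cells$f_hi_hz[i] - w)) / w)
      } else if (abs(cells$f_lo_hz[i] - cells$f_hi_hz[j]) < df) { # drop to the left
        z <- f[sel] < cells$f_lo_hz[i] + w
        rel[z] <- ratio^(((cells$f_lo_hz[i] + w) - f[sel][z]) / w)
      }
    }
    dens[sel] <- d_plateau[i] * rel
  }
  amp <- sqrt(dens)
  zk <- complex(real = rnorm(kmax), imaginary = rnorm(kmax)) * amp
  # exact per-cell energy: mean(x^2) contribution of cell bins is
  # (2/n^2) * sum |Z_k|^2
  for (i in seq_len(nrow(cells))) {
    sel <- sel_list[[i]]
    if (length(sel) == 0L || e_cell[i] <= 0) next
    s <- sum(Mod(zk[sel])^2)
    if (s > 0) zk[sel] <- zk[sel] * sqrt(n^2 * e_cell[i] / 2 / s)
  }
  synth <- function(keep) {
    Z <- complex(real = numeric(n), imaginary = numeric(n))
    zz <- zk; zz[-keep] <- 0
    Z[2:(kmax + 1L)] <- zz
    Z[n:(n - kmax + 1L)] <- Conj(zz)
    Re(fft(Z, inverse = TRUE)) / n
  }
  if (per_cell) lapply(sel_list, synth) else synth(seq_len(kmax))
}

# band-limited Gaussian noise: complex-Gaussian spectrum on [f_lo, f_hi),
# scaled to an exact RMS target
gen_band_noise <- function(n, rate_hz, f_lo, f_hi, p_rms) {
  if (p_rms <= 0) return(numeric(n))
  df <- rate_hz / n
  k <- which((0:(n %/% 2)) * df >= f_lo & (0:(n %/% 2)) * df < f_hi) # 1-based bin k = freq (k-1)*df
  k <- k[k > 1L & k <= n %/% 2]              # skip DC; keep below Nyquist bin
  if (length(k) == 0L) return(numeric(n))
  Z <- complex(real = numeric(n), imaginary = numeric(n))
  Z[k] <- complex(real = rnorm(length(k)), imaginary = rnorm(length(k)))
  Z[n - k + 2L] <- Conj(Z[k])
  x <- Re(fft(Z, inverse = TRUE)) / n
  x * (p_rms / sqrt(mean(x^2)))
}

# raised-cosine gate over [t_on, t_off] with edge ramps
gate_window <- function(n, rate_hz, t_on, t_off, ramp_s = 0.01) {
  t <- (seq_len(n) - 1L) / rate_hz
  g <- numeric(n)
  g[t >= t_on & t < t_off] <- 1
  nr <- max(1L, round(ramp_s * rate_hz))
  up <- which(t >= t_on & t < t_on + ramp_s)
  if (length(up)) g[up] <- 0.5 * (1 - cos(pi * seq_along(up) / length(up)))
  dn <- which(t >= t_off - ramp_s & t < t_off)
  if (length(dn)) g[dn] <- 0.5 * (1 + cos(pi * seq_along(dn) / length(dn)))
  g
}

# enclosure attenuation (dB) applicable to a band centred between f_lo, f_hi
enclosure_att <- function(enclosure, f_lo, f_hi) {
  if (is.null(enclosure)) return(0)
  if (is.numeric(enclosure) && length(enclosure) == 1L) return(enclosure)
  fc <- (f_lo + f_hi) / 2
  row <- which(enclosure$f_lo_hz <= fc & enclosure$f_hi_hz > fc)
  if (length(row) == 0L) 0 else enclosure$attenuation_db[row[1L]]
}

# synthesize acoustic and rf pressure streams plus truth entries
synth_scene <- function(spec) {
  set.seed(spec$seed)
  n <- as.integer(round(spec$duration_s * spec$rate_hz))
  rate <- spec$rate_hz
  p_ac <- numeric(n); p_rf <- numeric(n)
  truth_sources <- list()
  cal <- NULL
  for (s in spec$sources) if (s$kind == "cal_tone") cal <- s

  # Background (silenced during the calibration-tone window). Background is
  # the noise floor AT the microphone, so the enclosure does not attenuate
  # it; the enclosure sits between the mic and the sources.
  truth_bg <- NULL
  if (!is.null(spec$background)) {
    bg_gate <- if (is.null(cal)) rep(1, n) else
      1 - gate_window(n, rate, cal$t_start, cal$t_start + cal$dur)
    cells <- spec$background
    cells$rendered_db_spl <- cells$level_db_spl
    p_ac <- p_ac + bg_gate * render_shaped_background(n, rate, cells)
    truth_bg <- cells
  }

  for (s in spec$sources) {
    tru <- unclass(s)
    if (s$kind == "cal_tone") {
      t <- (seq_len(n) - 1L) / rate
      amp <- sqrt(2) * db_to_pa(s$level_db_spl)
      tone <- amp * sin(2 * pi * s$freq_hz * t) *
        gate_window(n, rate, s$t_start, s$t_start + s$dur, ramp_s = 0.005)
      p_ac <- p_ac + tone
      tru$rendered_db_spl <- s$level_db_spl      # clean: no enclosure
    } else if (s$kind == "narrowband") {
      att <- enclosure_att(spec$enclosure, s$f_lo_hz, s$f_hi_hz)
      lev <- s$level_db_spl - att
      x <- gen_band_noise(n, rate, s$f_lo_hz, s$f_hi_hz, db_to_pa(lev))
      p_ac <- p_ac + x * gate_window(n, rate, s$t_on, s$t_off)
      tru$rendered_db_spl <- lev
    } else if (s$kind == "impact") {
      ep0 <- floor(s$t_start)                    # containing 1 s epoch
      i0 <- as.integer(ep0 * rate) + 1L
      m <- as.integer(rate)                      # render within the epoch
      idx <- i0:min(i0 + m - 1L, n)
      tt <- (seq_along(idx) - 1L) / rate + ep0
      env <- ifelse(tt >= s$t_start, exp(-(tt - s$t_start) / s$decay_s), 0)
      # finite 2 ms raised-cosine attack: an instantaneous onset would
      # scatter the (high-level) audible-band energy broadband
      atk <- 0.002
      rise <- tt >= s$t_start & tt < s$t_start + atk
      env[rise] <- env[rise] *
        0.5 * (1 - cos(pi * (tt[rise] - s$t_start) / atk))
      cells <- background_cells(s$band_levels)
      cells$attenuation_db <- vapply(seq_len(nrow(cells)), function(i)
        enclosure_att(spec$enclosure, cells$f_lo_hz[i], cells$f_hi_hz[i]), 0)
      cells$rendered_db_spl <- cells$level_db_spl - cells$attenuation_db
      parts <- render_shaped_background(length(idx), rate, cells,
                                        per_cell = TRUE)
      for (i in seq_len(nrow(cells))) {
        target <- db_to_pa(cells$rendered_db_spl[i])
        if (target <= 0) next
        x <- parts[[i]] * env
        x <- x * (target / sqrt(sum(x^2) / m))   # epoch-RMS target
        p_ac[idx] <- p_ac[idx] + x
      }
      tru$cells <- cells
      tru$rendered_db_spl <- pow_to_db(sum(db_to_pow(cells$rendered_db_spl)))
    } else if (s$kind == "fm_burst") {
      comp_levels <- numeric(length(s$components))
      burst <- numeric(n)
      for (ci in seq_along(s$components)) {
        cmp <- s$components[[ci]]
        att <- if (isTRUE(s$rf_only)) 0 else
          enclosure_att(spec$enclosure, cmp$f_lo_hz, cmp$f_hi_hz)
        lev <- cmp$level_db_spl - att
        amp <- sqrt(2) * db_to_pa(lev)
        for (t0 in s$t_starts) {
          i0 <- as.integer(round(t0 * rate)) + 1L
          m <- as.integer(round(s$burst_s * rate))
          if (i0 + m - 1L > n) next
          tt <- (seq_len(m) - 1L) / rate
          sweep_rate <- (cmp$f_hi_hz - cmp$f_lo_hz) / s$burst_s
          ph <- 2 * pi * (cmp$f_lo_hz * tt + sweep_rate * tt^2 / 2)
          ramp <- gate_window(m, rate, 0, s$burst_s, ramp_s = 0.005)
          burst[i0:(i0 + m - 1L)] <- burst[i0:(i0 + m - 1L)] +
            amp * sin(ph) * ramp
        }
        comp_levels[ci] <- lev
      }
      if (isTRUE(s$rf_only)) p_rf <- p_rf + burst else p_ac <- p_ac + burst
      tru$rendered_db_spl <- comp_levels
    } else if (s$kind == "beep") {
      att <- enclosure_att(spec$enclosure, s$f_lo_hz, s$f_hi_hz)
      lev <- s$level_db_spl - att
      x <- gen_band_noise(n, rate, s$f_lo_hz, s$f_hi_hz, db_to_pa(lev))
      g <- numeric(n)
      for (t0 in s$t_starts)
        g <- pmax(g, gate_window(n, rate, t0, t0 + s$burst_s, ramp_s = 0.005))
      p_ac <- p_ac + x * g
      tru$rendered_db_spl <- lev
    } else stop("unknown source kind: ", s$kind)
    truth_sources[[length(truth_sources) + 1L]] <- tru
  }

  list(p_ac = p_ac, p_rf = p_rf,
       truth = list(schema = "usnoise-truth/1", synthetic = TRUE,
                    seed = spec$seed, rate_hz = rate,
                    duration_s = spec$duration_s,
                    enclosure = spec$enclosure,
                    background = truth_bg, sources = truth_sources))
}

# quantise a pressure stream to counts; error on clipping with a culprit hint
pressure_to_recording <- function(p, spec, truth, culprit_hint = NULL) {
  sens <- spec$counts_per_pa
  auto <- is.null(sens)
  if (auto) sens <- 0.5 / max(abs(p)) else
    sens <- sens * 10^(spec$device$gain_db / 20)
  counts <- p * sens
  if (any(abs(counts) >= 1)) {
    bad <- if (is.null(culprit_hint)) "unknown source" else culprit_hint
    stop("headroom error: scene clips at fixed sensitivity (loudest source: ",
         bad, ")")
  }
  truth$counts_per_pa <- sens
  truth$gain_db <- spec$device$gain_db
  list(rec = raw_recording(counts, spec$rate_hz, 16L, spec$label),
       truth = truth)
}

# name of the individually loudest source, for headroom diagnostics
loudest_source <- function(spec) {
  levs <- vapply(spec$sources, function(s) switch(s$kind,
    cal_tone = s$level_db_spl,
    narrowband = s$level_db_spl,
    impact = max(unlist(s$band_levels)),
    fm_burst = max(vapply(s$components, `[[`, 0, "level_db_spl")),
    beep = s$level_db_spl), 0)
  if (length(levs) == 0L) return("background")
  spec$sources[[which.max(levs)]]$kind
}

#' Render a synthetic scene to a recording plus truth record
#'
#' Deterministic given `spec$seed`. The truth sidecar records every source's
#' rendered in-band SPL after enclosure and device transforms, the
#' background cell levels, and the count-per-pascal sensitivity used, so
#' pipeline measurements can be checked against ground truth. Rf-only
#' content is included only when `spec$device$rf_susceptible` is `TRUE`.
#'
#' @param spec A [scene_spec()].
#' @return `list(rec = raw_recording, truth = list)`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  sc <- synth_scene(spec)
  p <- sc$p_ac + if (isTRUE(spec$device$rf_susceptible)) sc$p_rf else 0
  pressure_to_recording(p, spec, sc$truth, loudest_source(spec))
}

#' Render the same scene as seen by two devices
#'
#' Emulates the cross-device comparison that unmasks radio-frequency
#' artifacts: device A (rf-susceptible, high-gain condenser style) receives
#' the rf-only components untouched by any enclosure or barrier; device B
#' (rf-immune, MEMS style) records only the acoustic content. Acoustic
#' sources share one realisation across devices (same microphone position
#' idealisation).
#'
#' @param spec A [scene_spec()] whose sources include rf-only components
#'   (or supply them via `artifact`).
#' @param artifact Optional extra [src_fm_burst()] with `rf_only = TRUE`
#'   appended to the sources.
#' @param device_a,device_b Device descriptors; exactly one may be
#'   rf-susceptible.
#' @return `list(rec_a =, rec_b =, truth =)`.
#' @export
render_paired_devices <- function(spec, artifact = NULL,
                                  device_a = list(gain_db = 0, rf_susceptible = TRUE),
                                  device_b = list(gain_db = 0, rf_susceptible = FALSE)) {
  stopifnot(inherits(spec, "scene_spec"))
  if (isTRUE(device_a$rf_susceptible) && isTRUE(device_b$rf_susceptible))
    stop("both devices rf_susceptible: no rf-immune reference")
  if (!is.null(artifact)) {
    stopifnot(identical(artifact$kind, "fm_burst"), isTRUE(artifact$rf_only))
    spec$sources <- c(spec$sources, list(artifact))
  }
  sc <- synth_scene(spec)
  pa <- sc$p_ac + if (isTRUE(device_a$rf_susceptible)) sc$p_rf else 0
  pb <- sc$p_ac + if (isTRUE(device_b$rf_susceptible)) sc$p_rf else 0
  spec_a <- spec; spec_a$device <- device_a
  spec_a$label <- paste0(spec$label, " [device A]")
  spec_b <- spec; spec_b$device <- device_b
  spec_b$label <- paste0(spec$label, " [device B]")
  a <- pressure_to_recording(pa, spec_a, sc$truth, loudest_source(spec))
  b <- pressure_to_recording(pb, spec_b, sc$truth, loudest_source(spec))
  list(rec_a = a$rec, rec_b = b$rec,
       truth = c(sc$truth, list(counts_per_pa_a = a$truth$counts_per_pa,
                                counts_per_pa_b = b$truth$counts_per_pa)))
}

#' Attenuate the acoustic content of a recording
#'
#' FFT-domain per-band gain shaping emulating an enclosure (e.g. an IVC's
#' roughly 10 dB broadband attenuation). Operates on everything in the
#' recording; within [render_scene()] the enclosure is instead applied per
#' source so that rf-only content and the calibration tone stay untouched.
#'
#' @param rec A [raw_recording()] or `calibrated_recording`.
#' @param attenuation Flat dB value or data frame `f_lo_hz`, `f_hi_hz`,
#'   `attenuation_db` (all values >= 0).
#' @return A recording of the same class.
#' @export
apply_enclosure <- function(rec, attenuation) {
  x <- if (inherits(rec, "raw_recording")) rec$samples else rec$pressure_pa
  n <- length(x)
  if (is.numeric(attenuation) && length(attenuation) == 1L) {
    stopifnot(attenuation >= 0)
    y <- x * 10^(-attenuation / 20)
  } else {
    stopifnot(all(attenuation$attenuation_db >= 0))
    freqs <- (0:(n %/% 2)) * rec$rate_hz / n
    gain <- rep(1, length(freqs))
    for (i in seq_len(nrow(attenuation))) {
      sel <- freqs >= attenuation$f_lo_hz[i] & freqs < attenuation$f_hi_hz[i]
      gain[sel] <- 10^(-attenuation$attenuation_db[i] / 20)
    }
    G <- c(gain, rev(gain[2:(n - length(freqs) + 1L)]))
    y <- Re(fft(fft(x) * G, inverse = TRUE)) / n
  }
  if (inherits(rec, "raw_recording"))
    raw_recording(y, rec$rate_hz, rec$bit_depth, rec$label)
  else
    structure(list(pressure_pa = y, rate_hz = rec$rate_hz, label = rec$label),
              class = "calibrated_recording")
}

#' Write a rendered scene as WAV plus truth JSON sidecar
#'
#' @param scene Result of [render_scene()].
#' @param path Output WAV path; the truth sidecar is written next to it with
#'   extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  write_wav(scene$rec, path)
  jsonlite::write_json(scene$truth, sub("\\.wav$", ".truth.json", path,
                                        ignore.case = TRUE),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
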