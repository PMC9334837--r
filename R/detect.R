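#' Detection event container
#'
#' Events are plain data frames (class `detection_events`) with one row per
#' event: `kind` (`"tonal"`, `"impact"`, `"fm"`), `t_start_s`, `t_end_s`,
#' `f_lo_hz`, `f_hi_hz`, `peak_level_db_spl`, `excess_db` (level above
#' background in the event's band), `group` (shared id for simultaneous
#' components), and `flags` (comma-separated subset of `suspected_rf`,
#' `through_barrier`, `inside_ivc_audible`).
#'
#' @param ... Column vectors as above.
#' @return A `detection_events` data frame.
#' @export
detection_events <- function(kind = character(), t_start_s = numeric(),
                             t_end_s = numeric(), f_lo_hz = numeric(),
                             f_hi_hz = numeric(),
                             peak_level_db_spl = numeric(),
                             excess_db = numeric(),
                             group = integer(), flags = character()) {
  out <- data.frame(kind = kind, t_start_s = t_start_s, t_end_s = t_end_s,
                    f_lo_hz = f_lo_hz, f_hi_hz = f_hi_hz,
                    peak_level_db_spl = peak_level_db_spl,
                    excess_db = excess_db, group = group, flags = flags,
                    stringsAsFactors = FALSE)
  class(out) <- c("detection_events", "data.frame")
  out
}

has_flag <- function(events, flag) {
  vapply(strsplit(events$flags, ",", fixed = TRUE),
         function(f) flag %in% f, TRUE)
}

add_flag <- function(flags, flag) {
  ifelse(nzchar(flags), paste(flags, flag, sep = ","), flag)
}

#' Export detection events
#'
#' @param events A `detection_events` data frame.
#' @param path Output path (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(as.data.frame(events), path, dataframe = "rows",
                         digits = NA)
  else
    write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' Fit a per-bin background spectrum model
#'
#' Robust per-bin background from epochs known to contain only background
#' (lights off, no drop, ...): the median level per bin and a MAD-based
#' spread. The median is insensitive to a contaminated epoch slipping into
#' the background set.
#'
#' @param spec A `noise_spectrogram`.
#' @param background_epochs Zero-based epoch indices to use; at least 3.
#' @return An object of class `background_model` with `freq_hz`,
#'   `median_db`, `mad_db`.
#' @export
fit_background <- function(spec, background_epochs) {
  stopifnot(inherits(spec, "noise_spectrogram"))
  idx <- as.integer(background_epochs) + 1L
  if (length(idx) < 3L) stop("insufficient background: need >= 3 epochs")
  if (any(idx < 1L | idx > nrow(spec$level_db))) stop("epoch index out of range")
  sub <- spec$level_db[idx, , drop = FALSE]
  structure(list(freq_hz = spec$freq_hz,
                 median_db = apply(sub, 2L, median),
                 mad_db = apply(sub, 2L, mad),
                 df_hz = spec$df_hz, n_epochs = length(idx)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: %d bins to %g kHz from %d epochs\n",
              length(x$freq_hz), max(x$freq_hz) / 1000, x$n_epochs))
  invisible(x)
}

#' Band level of a background model
#'
#' Energy sum of the per-bin median background over a band.
#'
#' @param bg A `background_model`.
#' @param bnd A [band()].
#' @return Level in dB SPL.
#' @export
background_band_level <- function(bg, bnd) {
  stopifnot(inherits(bg, "background_model"))
  idx <- band_bins(bg$freq_hz, bnd)
  if (length(idx) == 0L) stop("band contains no spectrum bins")
  pow_to_db(sum(db_to_pow(bg$median_db[idx])))
}

# resample a background model onto a coarser fine-frame grid by summing
# model-bin energies into each target bin
resample_background <- function(bg, freq_hz, df_hz) {
  edges <- c(freq_hz - df_hz / 2, max(freq_hz) + df_hz / 2)
  pow <- db_to_pow(bg$median_db)
  cell <- findInterval(bg$freq_hz, edges, rightmost.closed = FALSE)
  out <- numeric(length(freq_hz))
  ok <- cell >= 1L & cell <= length(freq_hz)
  agg <- tapply(pow[ok], cell[ok], sum)
  out[as.integer(names(agg))] <- agg
  # above the model span (e.g. 100-125 kHz) assume the highest modelled density
  empty <- out == 0
  if (any(empty) && any(!empty)) {
    dens <- out[!empty][length(out[!empty])]
    out[empty & freq_hz > max(bg$freq_hz)] <- dens
  }
  pow_to_db(out)
}

# connected super-threshold time-frequency regions of a boolean matrix
# (rows = time steps, cols = bins). The mask is first dilated by dilate_t
# rows and dilate_f bins so that regions separated by small gaps merge; the
# components are then labelled by run-based union-find, and each component
# reports its ORIGINAL super-threshold cells (rows, bin extent, and the
# per-row bin sets).
mask_components <- function(mask, dilate_f = 1L, dilate_t = 1L) {
  nr <- nrow(mask); nc <- ncol(mask)
  dil <- mask
  if (dilate_t > 0L && nr > 1L) {
    for (d in seq_len(dilate_t)) {
      dil[seq_len(nr - d), ] <- dil[seq_len(nr - d), ] | mask[(1L + d):nr, ]
      dil[(1L + d):nr, ] <- dil[(1L + d):nr, ] | mask[seq_len(nr - d), ]
    }
  }
  if (dilate_f > 0L && nc > 1L) {
    base <- dil
    for (d in seq_len(dilate_f)) {
      dil[, seq_len(nc - d)] <- dil[, seq_len(nc - d)] | base[, (1L + d):nc]
      dil[, (1L + d):nc] <- dil[, (1L + d):nc] | base[, seq_len(nc - d)]
    }
  }
  # run-based connected-component labelling with union-find
  parent <- integer(0)
  uf_find <- function(p, i) { while (p[i] != i) i <- p[i]; i }
  run_rows <- list()
  prev <- NULL
  for (r in seq_len(nr)) {
    idx <- which(dil[r, ])
    if (length(idx) == 0L) { prev <- NULL; next }
    brk <- which(diff(idx) > 1L)
    los <- idx[c(1L, brk + 1L)]; his <- idx[c(brk, length(idx))]
    cur <- data.frame(lo = los, hi = his, comp = NA_integer_)
    for (j in seq_len(nrow(cur))) {
      hits <- if (is.null(prev)) integer(0) else
        which(prev$lo <= cur$hi[j] & prev$hi >= cur$lo[j])
      if (length(hits) == 0L) {
        parent <- c(parent, length(parent) + 1L)
        cur$comp[j] <- length(parent)
      } else {
        roots <- unique(vapply(prev$comp[hits], function(i) uf_find(parent, i), 0L))
        cur$comp[j] <- roots[1L]
        for (rt in roots[-1L]) parent[rt] <- roots[1L]
      }
      run_rows[[length(run_rows) + 1L]] <- c(r, cur$lo[j], cur$hi[j],
                                             cur$comp[j])
    }
    prev <- cur
  }
  if (length(run_rows) == 0L) return(list())
  runs <- do.call(rbind, run_rows)
  roots <- vapply(runs[, 4L], function(i) uf_find(parent, i), 0L)
  out <- list()
  for (rt in unique(roots)) {
    rr <- runs[roots == rt, , drop = FALSE]
    rows <- integer(0); lo <- Inf; hi <- -Inf; cells <- list()
    for (k in seq_len(nrow(rr))) {
      r <- rr[k, 1L]
      bins <- which(mask[r, rr[k, 2L]:rr[k, 3L]]) + rr[k, 2L] - 1L
      if (length(bins) == 0L) next
      rows <- c(rows, r); lo <- min(lo, bins); hi <- max(hi, bins)
      cells[[length(cells) + 1L]] <- list(row = r, bins = bins)
    }
    if (length(rows) == 0L) next
    # coalesce per-row bin sets (a row can contribute several runs)
    rows_u <- sort(unique(rows))
    per_row <- lapply(rows_u, function(r) {
      sort(unique(unlist(lapply(cells, function(cl)
        if (cl$row == r) cl$bins else integer(0)))))
    })
    out[[length(out) + 1L]] <- list(rows = rows_u, lo = lo, hi = hi,
                                    row_bins = per_row)
  }
  out
}

# assign shared group ids to events overlapping in time
assign_groups <- function(ev) {
  if (nrow(ev) == 0L) return(ev)
  ord <- order(ev$t_start_s)
  grp <- integer(nrow(ev)); g <- 0L; t_hi <- -Inf
  for (i in ord) {
    if (ev$t_start_s[i] > t_hi) { g <- g + 1L; t_hi <- ev$t_end_s[i] }
    else t_hi <- max(t_hi, ev$t_end_s[i])
    grp[i] <- g
  }
  ev$group <- grp
  ev
}

#' Detect continuous narrowband (tonal) events
#'
#' Finds maximal contiguous time--frequency regions of a one-second-epoch
#' spectrogram where the per-bin level exceeds the background model by at
#' least `min_excess_db` for at least `min_duration_s`, with narrowband
#' extent (at most `max_width_hz`). Regions closer than one epoch in time
#' and two bins in frequency are merged. The default excess threshold is
#' 3 dB -- a doubling of sound pressure, the conventional just-detectable
#' change -- because continuous facility sources (e.g. fluorescent ceiling
#' lights at a few dB over background in their band) sit well below impact
#' levels; the duration requirement keeps false positives negligible.
#'
#' @param spec A `noise_spectrogram`.
#' @param bg A `background_model` from [fit_background()].
#' @param min_excess_db Per-bin detection threshold above background (dB).
#' @param min_duration_s Minimum event duration in seconds.
#' @param max_width_hz Maximum frequency extent for a tonal event.
#' @return A [detection_events()] data frame (possibly empty).
#' @export
detect_tonal <- function(spec, bg, min_excess_db = 3, min_duration_s = 3,
                         max_width_hz = 10000) {
  stopifnot(inherits(spec, "noise_spectrogram"),
            inherits(bg, "background_model"),
            min_excess_db > 0, min_duration_s > 0)
  keep <- spec$freq_hz >= 4
  excess <- sweep(spec$level_db, 2L, bg$median_db)
  mask <- excess >= min_excess_db
  mask[, !keep] <- FALSE
  comps <- mask_components(mask)

  ev <- detection_events()
  for (tr in comps) {
    n_ep <- length(tr$rows)
    f_lo <- spec$freq_hz[tr$lo]; f_hi <- spec$freq_hz[tr$hi] + spec$df_hz
    if (n_ep * spec$epoch_seconds < min_duration_s) next
    if (f_hi - f_lo > max_width_hz) next
    bins <- tr$lo:tr$hi
    lev <- apply(spec$level_db[tr$rows, bins, drop = FALSE], 1L,
                 function(l) pow_to_db(sum(db_to_pow(l))))
    bg_lev <- pow_to_db(sum(db_to_pow(bg$median_db[bins])))
    ev <- rbind(ev, detection_events(
      kind = "tonal",
      t_start_s = spec$times_s[min(tr$rows)],
      t_end_s = spec$times_s[max(tr$rows)] + spec$epoch_seconds,
      f_lo_hz = f_lo, f_hi_hz = f_hi,
      peak_level_db_spl = max(lev),
      excess_db = max(lev) - bg_lev,
      group = 0L, flags = ""))
  }
  class(ev) <- c("detection_events", "data.frame")
  assign_groups(ev)
}

#' Detect broadband impact events
#'
#' Impacts (e.g. metal forceps dropped on a metal surface) appear as one or
#' two epochs whose super-threshold bins span a wide frequency range. An
#' epoch is impact-like when bins exceeding the background by
#' `min_excess_db` span at least `min_bandwidth_hz`; adjacent impact-like
#' epochs (at most 2) merge into one event. The reported `excess_db` is the
#' event's level increase over background in `excess_band` (default the
#' ultrasonic band), taken at the peak epoch.
#'
#' @param spec A `noise_spectrogram`.
#' @param bg A `background_model`.
#' @param min_excess_db Per-bin threshold above background (default 10 dB).
#' @param min_bandwidth_hz Minimum super-threshold span (default 50 kHz).
#' @param excess_band [band()] in which `excess_db` is reported.
#' @return A [detection_events()] data frame.
#' @export
detect_impact <- function(spec, bg, min_excess_db = 10,
                          min_bandwidth_hz = 50000,
                          excess_band = standard_bands()$ultrasonic) {
  stopifnot(inherits(spec, "noise_spectrogram"),
            inherits(bg, "background_model"),
            min_excess_db > 0, min_bandwidth_hz > 0)
  keep <- spec$freq_hz >= 4
  excess <- sweep(spec$level_db, 2L, bg$median_db)
  hits <- lapply(seq_len(nrow(excess)), function(e) {
    idx <- which(excess[e, ] >= min_excess_db & keep)
    if (length(idx) >= 2L &&
        spec$freq_hz[max(idx)] - spec$freq_hz[min(idx)] >= min_bandwidth_hz)
      c(min(idx), max(idx)) else NULL
  })
  imp <- which(!vapply(hits, is.null, TRUE))
  ev <- detection_events()
  if (length(imp) > 0L) {
    brk <- which(diff(imp) > 1L)
    starts <- imp[c(1L, brk + 1L)]
    ends <- imp[c(brk, length(imp))]
    bg_band <- background_band_level(bg, excess_band)
    for (k in seq_along(starts)) {
      eps <- starts[k]:ends[k]
      eps <- eps[seq_len(min(length(eps), 2L))]    # impacts last <= 2 epochs
      lo <- min(vapply(hits[eps], `[`, 0, 1L))
      hi <- max(vapply(hits[eps], `[`, 0, 2L))
      band_lev <- vapply(eps, function(e) {
        idx <- band_bins(spec$freq_hz, excess_band)
        pow_to_db(sum(db_to_pow(spec$level_db[e, idx])))
      }, 0)
      pk <- eps[which.max(band_lev)]
      ev <- rbind(ev, detection_events(
        kind = "impact",
        t_start_s = spec$times_s[min(eps)],
        t_end_s = spec$times_s[max(eps)] + spec$epoch_seconds,
        f_lo_hz = spec$freq_hz[lo], f_hi_hz = spec$freq_hz[hi] + spec$df_hz,
        peak_level_db_spl = max(band_lev),
        excess_db = max(band_lev) - bg_band,
        group = 0L, flags = ""))
    }
  }
  class(ev) <- c("detection_events", "data.frame")
  assign_groups(ev)
}

#' Detect frequency-modulated burst components
#'
#' Ridge-tracks narrowband components through a fine-frame spectrogram
#' (frames of at most 10 ms, needed to resolve "highly transient" FM
#' structure). Per frame, super-threshold bins are grouped into runs; runs
#' are linked across frames into tracks; a track whose energy-weighted
#' centre frequency varies by at least `min_sweep_hz` is classified `fm`,
#' otherwise `tonal`. Simultaneous components (e.g. a 48--50 kHz and a
#' 98--102 kHz element of the same burst) are reported as separate events
#' sharing a `group` id. For `fm` events `f_lo_hz`/`f_hi_hz` report the
#' ridge-centre range (the swept extent), not the instantaneous bandwidth.
#'
#' The default threshold is higher than for one-second epochs because single
#' 5 ms periodogram frames fluctuate by several dB; persistence
#' (`min_frames`) suppresses the remaining false alarms.
#'
#' @param fspec A `fine_spectrogram`.
#' @param bg A `background_model` (fitted on one-second epochs; resampled
#'   internally onto the fine grid).
#' @param min_excess_db Per-bin threshold above background (default 12 dB).
#' @param min_frames Minimum track length in frames (default 4).
#' @param min_sweep_hz Centre-frequency variation separating `fm` from
#'   `tonal` (default 1000 Hz).
#' @return A [detection_events()] data frame.
#' @export
detect_fm <- function(fspec, bg, min_excess_db = 12, min_frames = 4L,
                      min_sweep_hz = 1000) {
  stopifnot(inherits(fspec, "fine_spectrogram"),
            inherits(bg, "background_model"), min_excess_db > 0)
  bg_fine <- resample_background(bg, fspec$freq_hz, fspec$df_hz)
  keep <- fspec$freq_hz >= 4
  excess <- sweep(fspec$level_db, 2L, bg_fine)
  mask <- excess >= min_excess_db
  mask[, !keep] <- FALSE
  comps <- mask_components(mask)

  ev <- detection_events()
  for (tr in comps) {
    if (length(tr$rows) < min_frames) next
    centers <- mapply(function(r, bins) {
      p <- db_to_pow(fspec$level_db[r, bins])
      sum(p * fspec$freq_hz[bins]) / sum(p)
    }, tr$rows, tr$row_bins)
    lev <- mapply(function(r, bins)
      pow_to_db(sum(db_to_pow(fspec$level_db[r, bins]))),
      tr$rows, tr$row_bins)
    bins_all <- tr$lo:tr$hi
    bg_lev <- pow_to_db(sum(db_to_pow(bg_fine[bins_all])))
    is_fm <- (max(centers) - min(centers)) >= min_sweep_hz
    ev <- rbind(ev, detection_events(
      kind = if (is_fm) "fm" else "tonal",
      t_start_s = fspec$times_s[min(tr$rows)] - fspec$frame_s / 2,
      t_end_s = fspec$times_s[max(tr$rows)] + fspec$frame_s / 2,
      f_lo_hz = if (is_fm) min(centers) else fspec$freq_hz[tr$lo],
      f_hi_hz = if (is_fm) max(centers) else fspec$freq_hz[tr$hi] + fspec$df_hz,
      peak_level_db_spl = max(lev),
      excess_db = max(lev) - bg_lev,
      group = 0L, flags = ""))
  }
  class(ev) <- c("detection_events", "data.frame")
  assign_groups(ev)
}

#' Screen events for radio-frequency interference artifacts
#'
#' High-gain condenser microphones and their cables can act as aerials and
#' record radio-frequency pickup that masquerades as ultrasonic sound; an
#' RF-insensitive reference device (e.g. a MEMS microphone) recording the
#' same scene will not show it. An ultrasonic event detected by device A but
#' absent from reference device B -- where B's noise floor would have
#' permitted detection (`excess - device_offset_db > b_min_excess_db`) --
#' gains the flag `suspected_rf`. Audible-band events (below 20 kHz) are
#' exempt: concordant acoustic detection is not expected to fail there, and
#' RF pickup manifests ultrasonically.
#'
#' @param events_a Events from the high-gain device under suspicion.
#' @param events_b Events from the reference device over the same interval.
#' @param tol_s Time-overlap slack in seconds (default 0.1).
#' @param tol_hz Frequency-overlap slack in Hz (default 1000).
#' @param device_offset_db Expected sensitivity offset A minus B (default 0;
#'   absolute cross-device calibration is rarely available).
#' @param b_min_excess_db Detection threshold of device B's pipeline
#'   (default 12, matching [detect_fm()]).
#' @return `events_a` with `flags` updated.
#' @export
rf_screen <- function(events_a, events_b, tol_s = 0.1, tol_hz = 1000,
                      device_offset_db = 0, b_min_excess_db = 12) {
  stopifnot(inherits(events_a, "detection_events"),
            inherits(events_b, "detection_events"))
  if (nrow(events_a) == 0L) return(events_a)
  for (i in seq_len(nrow(events_a))) {
    a <- events_a[i, ]
    if (a$f_lo_hz < 20000) next                       # audible-band exemption
    matched <- nrow(events_b) > 0L && any(
      events_b$t_start_s <= a$t_end_s + tol_s &
      events_b$t_end_s >= a$t_start_s - tol_s &
      events_b$f_lo_hz <= a$f_hi_hz + tol_hz &
      events_b$f_hi_hz >= a$f_lo_hz - tol_hz)
    if (!matched && (a$excess_db - device_offset_db) > b_min_excess_db)
      events_a$flags[i] <- add_flag(events_a$flags[i], "suspected_rf")
  }
  events_a
}

#' Barrier-propagation plausibility check
#'
#' Ultrasonic sound is readily absorbed by surfaces and does not pass
#' through walls or sealed enclosures undiminished. If an event measured
#' inside an enclosure retains a level within `expected_attenuation_db - 3`
#' dB of the outside level, that propagation is physically implausible and
#' the event gains `through_barrier` -- supporting an RF-artifact
#' interpretation. Any inside detection at all additionally gains
#' `inside_ivc_audible` (the animals are exposed under normal housing).
#'
#' @param event_outside One-row `detection_events` measured outside.
#' @param event_inside Matching one-row `detection_events` measured inside,
#'   or `NULL` if not detected inside.
#' @param expected_attenuation_db Nominal enclosure attenuation (dB).
#' @return Character vector of flags (possibly empty).
#' @export
barrier_plausibility <- function(event_outside, event_inside,
                                 expected_attenuation_db) {
  stopifnot(inherits(event_outside, "detection_events"))
  flags <- character()
  if (is.null(event_inside) || nrow(event_inside) == 0L) return(flags)
  flags <- c(flags, "inside_ivc_audible")
  if (event_inside$peak_level_db_spl >=
      event_outside$peak_level_db_spl - (expected_attenuation_db - 3))
    flags <- c(flags, "through_barrier")
  flags
}
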