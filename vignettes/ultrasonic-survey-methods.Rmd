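---
title: "Measuring ultrasonic facility noise: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ultrasonic facility noise: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Mice hear from roughly 1 kHz to 100 kHz, with peak sensitivity at
10--20 kHz and a secondary sensitivity near 50 kHz. Facility noise surveys
aimed at human comfort stop at 20 kHz and therefore miss most of the
spectrum the animals are exposed to. Ultrasonic sources are also invisible
to staff: nobody hears a fluorescent ballast singing at 45 kHz, so nobody
mitigates it. `usnoise` implements the measurement chain a sound-analyser
workflow uses to make those sources visible and quantifiable:

1. ingest 16-bit PCM WAV recordings at high sample rates (250 kHz,
   384 kHz);
2. anchor the count scale to absolute pressure with a 94 dB SPL / 1 kHz
   reference tone (`fit_calibration()`), so all levels are dB SPL re
   20 uPa, linear (unweighted -- A-weighting only covers the audible range
   and is deliberately not offered);
3. compute FFT autospectra in one-second epochs, 6400 lines spanning
   0--100 kHz (bin width 15.625 Hz), Welch-averaged Hann periodograms with
   50% overlap (`autospectrum()`, `spectrogram()`);
4. integrate named bands -- the "delta cursor" -- and build
   background/measured/difference tables (`band_level()`,
   `difference_table()`);
5. detect tonal, impact and FM events against a robust background model
   and screen them for radio-frequency artifacts (`detect_*()`,
   `rf_screen()`).

A seeded scene generator (`render_scene()`) produces calibrated synthetic
recordings with the statistical structure of the three canonical facility
noise sources, so the entire chain is testable without access to a
facility.

## Level conventions and spectral scaling

All levels are dB SPL re 20 uPa RMS. The spectra are *energy normalised*:
a bin's value is the in-bin band power, scaled so that the energy sum over
bins equals the time-domain mean square (Parseval). Two consequences:

* the band integral (`band_level()`) is the calibrated quantity, exactly
  matching a delta-cursor readout;
* a stationary tone's level is recovered by summing the few bins of its
  window main lobe; the single peak bin alone under-reads by the Hann
  spreading loss (about 1.8 dB at bin centre). An amplitude-corrected
  display would make the peak bin read the tone level but would break
  energy conservation; since every contract in this package is an energy
  sum, the energy convention is used throughout and documented here.

Band membership is half-open on bin centres, `[f_lo, f_hi)`, so the
standard bands (Total 4 Hz--100 kHz, Human audible 20 Hz--20 kHz, Mouse
peak 10--20 kHz, Ultrasonic 20--100 kHz) never double-count shared
boundary bins. Bins below 4 Hz are masked from all band math: the
measurement microphone's response starts at 4 Hz. At 15.625 Hz bin width
this means energy below ~8 Hz falls into the masked DC bin; a scene
dominated by infrasound in the 4--20 Hz cell cannot satisfy a tight
Parseval check at the analyser's own resolution, which is why the
stationarity checks in the test-suite use facility-like backgrounds (not
infrasound-dominated ones).

When `rate / (span / n_lines)` is not an integer, the segment length is
rounded and the actual bin width recomputed; band edges land on the actual
grid.

## Calibration

`fit_calibration()` implements closed-coupler pistonphone calibration:
sensitivity (counts/Pa) is the count RMS of the tone window divided by the
reference pressure `20e-6 * 10^(94/20) ~ 1.0024 Pa`. The window must hold a
quasi-stationary tone: the dominant Hann-FFT component must lie within 5%
of 1 kHz and carry at least 20 dB more energy than the residual, otherwise
the fit aborts (the 20 dB threshold is our choice; it rejects accidental
noise windows while accepting real calibrator recordings). A flat-response
measurement microphone makes the single-frequency calibration valid across
the band; frequency-response correction curves are out of scope. High-gain
ultrasonic recording microphones without a calibrator can only provide
relative levels; `cmd_survey(..., relative = TRUE)` reports dB re full
scale and labels them as such.

## Detection thresholds

Defaults, all overridable:

* **tonal** (`detect_tonal()`): 3 dB per-bin excess over the per-bin
  median background, sustained at least 3 s, extent at most 10 kHz.
  3 dB is a doubling of sound pressure -- the conventional just-detectable
  change -- and is the right scale for continuous sources: a ceiling-light
  band sitting 4 dB over background in its 7 kHz emission band must be
  found, while the 3-s persistence requirement keeps the false-alarm rate
  on pure background below one event per hundred epochs (property-tested).
  A higher threshold (e.g. 6 dB) would miss exactly the low-level
  continuous sources this kind of survey exists to find.
* **impact** (`detect_impact()`): 10 dB per-bin excess spanning at least
  50 kHz within one or two epochs. Impacts are 26--54 dB over background,
  so the margin is large.
* **fm** (`detect_fm()`): 12 dB per-bin excess on 5 ms frames with at
  least 4-frame persistence. Single short-frame periodograms fluctuate by
  several dB (chi-squared with 2 degrees of freedom), so the fine-frame
  threshold must be much higher than the epoch-level one; persistence
  suppresses the rest. A track whose energy-weighted centre frequency
  moves at least 1 kHz is `fm`, otherwise `tonal`. For `fm` events the
  reported frequency range is the ridge-centre (swept) range.

`rf_screen()` flags an ultrasonic event on the suspect device as
`suspected_rf` when the rf-immune reference device shows no overlapping
event although its noise floor would have permitted detection. Audible
events are exempt: RF pickup manifests ultrasonically, and concordant
acoustic detection is expected below 20 kHz. `barrier_plausibility()`
adds `through_barrier` when an "ultrasonic" event passes an enclosure
essentially undiminished -- ultrasound is readily absorbed and does not
pass through walls, so undiminished propagation supports the RF-artifact
interpretation.

## The synthetic scenes: what they emulate, and what they do not

`render_scene()` works in pascals and quantises to 16-bit counts at the
end (auto-scaled so the loudest sample sits at half full scale, or at a
fixed `counts_per_pa` with a hard headroom error on clipping).

* **Background** is stationary Gaussian noise with piecewise-flat spectral
  density over disjoint cells (4--20 Hz, 20 Hz--10 kHz, 10--20 kHz,
  20--100 kHz), each cell scaled to an exact in-band SPL. Cell boundaries
  where the density drops by more than 3 dB are smoothed with a log-linear
  ramp carved out of the louder cell (up to 2 kHz wide): a brick-wall step
  of 40 dB would leak analyser window-sidelobe energy into the quiet
  neighbour, and real facility backgrounds roll off smoothly rather than
  discontinuously. The background represents the noise floor *at the
  microphone* and is therefore not attenuated by a configured enclosure.
* **The calibration tone** renders clean (no background, no enclosure),
  mirroring closed-coupler calibration, at exactly 94 dB SPL equivalent.
* **Continuous narrowband sources** (ceiling-lights emulation) are
  band-limited noise -- the emission is modelled as band-limited noise
  rather than a tone with sidebands, a deliberate choice where the
  evidence does not distinguish the two -- gated with 10 ms raised-cosine
  edges.
* **Impacts** are per-cell shaped noise under an exponential envelope
  (default decay 20 ms: transient enough to live inside one epoch,
  long enough to be visible in 5 ms frames) with a 2 ms raised-cosine
  attack (an instantaneous onset would scatter the high-level audible-band
  energy broadband), scaled so the standard-band levels over the onset
  epoch hit their targets exactly.
* **FM bursts** are summed linear-sweep sinusoids; components marked
  `rf_only` are injected only into rf-susceptible devices and bypass all
  acoustic transforms, emulating electromagnetic pickup by a poorly
  shielded high-gain microphone. The artifact's absolute level is a free
  parameter (no published value exists); the canonical scene uses 55 dB
  SPL per component, comfortably above the fine-frame detection floor.
* **Enclosures** attenuate acoustic sources (flat or per band), not the
  background or rf content. The canonical cage emulation uses 10 dB flat;
  the lights-in-cage variant uses 30 dB, under which the source vanishes
  into the local background.

What the scenes do **not** emulate: room acoustics (reverberation,
directionality), microphone polar patterns and frequency-response ripple,
non-stationary backgrounds, and the truly unknown crest factor and
spectral tilt of a real forceps impact (only per-band epoch energies are
matched). Passing the fixture tests therefore demonstrates that the
measurement chain is correct, not that any particular facility is quiet.

## Dynamic range of 16-bit capture

A full-scale impact peak of a few hundred pascals forces a gain at which
the 16-bit quantisation floor sits near 46 dB SPL in the ultrasonic band
-- above a quiet facility's 40 dB ultrasonic background. This is physics,
not implementation: one 16-bit file cannot hold a 112 dB impact peak and a
40 dB background floor simultaneously. Absolute survey measurements of
such scenes belong to the analyser path (in-memory recordings, or
higher-bit-depth hardware); the WAV path is the recorder path, appropriate
for detection and relative comparisons. The survey functions accept either
(`cmd_survey()` takes a path or a `raw_recording`).

## Numerical and design choices

* Zero-phase high-pass (`high_pass()`): forward-backward Chebyshev
  type-II, order 6, 35 dB stopband, stopband edge at 0.55 x cutoff. After
  the two passes this gives >= 70 dB one octave below the cutoff and
  < 0.01 dB ripple above 1.25 x cutoff, comfortably inside the stated
  contract, while preserving event timing.
* Background model: per-bin median and MAD over designated background
  epochs; the median tolerates a contaminated epoch. Aggregated band
  levels are the reliable quantity; individual 15.625 Hz bins estimated
  from a handful of epochs fluctuate by around +-1 dB.
* Event merging: super-threshold time-frequency cells are dilated by one
  epoch/frame and one bin before connected-component labelling, so
  regions separated by small gaps merge into one event.
* Background correction (`background_correct()`) uses energy subtraction
  and refuses to report a point estimate when measured and background
  levels are within 3 dB (standard practice; the result is then flagged
  `background_limited` with the upper bound `measured - 3 dB`).
* Ties in `peak_epoch()` break to the earliest epoch.
* Scenes are deterministic given their mandatory seed; identical spec and
  seed give bit-identical WAVs.

## Problem sizes used by the test-suite

The bundled tests and the acceptance script run the full chain on scenes
of 3--12 s at 250 kHz (one to three million samples per scene), twenty
replicate stationary scenes for the energy-conservation check, and ten
replicate background-only scenes (fifty epochs) for the false-alarm rate.
These sizes give the fixture statistics quoted in the README while keeping
a complete run in the low minutes on one core.

## Known limitations

* Only uncompressed integer PCM WAV is supported (16-bit; mono, or
  channel 0 of a multi-channel file with a warning).
* Analyser parity is defined by the contracts above (bin width, energy
  conservation, tone recovery, epoch cadence), not bit-exactness with any
  proprietary implementation.
* Neural-network call detection and perceptual (audiogram-weighted)
  levels are out of scope; levels are unweighted dB SPL.
* `detect_fm()` classifies a wideband noise burst as `fm` when its
  energy-weighted centre wanders more than 1 kHz; for rf screening this is
  immaterial (audible events are exempt), but the `kind` label of audible
  noise bursts should not be over-interpreted.
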