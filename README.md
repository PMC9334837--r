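# usnoise

Calibrated measurement and screening of audible **and ultrasonic** noise in
laboratory-animal facilities.

Mice hear roughly 1--100 kHz -- peak sensitivity at 10--20 kHz, a secondary
sensitivity near 50 kHz -- so a noise survey that stops at the human
audible limit of 20 kHz misses most of what the animals are exposed to, and
staff cannot hear the offending sources (fluorescent ballasts, metal-on-metal
impacts, electronics) to mitigate them. `usnoise` is for facility managers,
animal-welfare scientists and bioacousticians who need to find, measure and
mitigate such sources with analyser-grade arithmetic:

* **WAV ingest** of high-rate 16-bit PCM recordings (250 kHz, 384 kHz),
  with an optional zero-phase 10 kHz high-pass for ultrasonic-recorder
  workflows;
* **absolute calibration** from a pistonphone-style reference tone
  (1 kHz at 94 dB SPL), so levels are dB SPL re 20 μPa, linear
  (unweighted);
* **analyser-style spectra**: one-second epochs, 6400 FFT lines spanning
  0--100 kHz (bin width 15.625 Hz), Welch-averaged Hann periodograms,
  energy-normalised so band sums are exact;
* **band metrics**: delta-cursor band levels
  `L_band = 10·log10( Σ_i 10^(L_i/10) )`, background correction by energy
  subtraction `10·log10(10^(L_meas/10) − 10^(L_bg/10))` (flagged
  `background_limited` under 3 dB separation), peak-epoch
  difference tables and mitigation-reduction tables over the standard
  bands (Total 4 Hz--100 kHz, Human audible 20 Hz--20 kHz, Mouse peak
  10--20 kHz, Ultrasonic 20--100 kHz);
* **event detection**: continuous tonal sources, broadband impacts, and
  frequency-modulated bursts (5 ms fine frames, ridge tracking);
* **RF-artifact screening**: high-gain condenser microphones can act as
  aerials and record radio-frequency interference that masquerades as
  ultrasound; cross-device comparison against an rf-immune reference flags
  `suspected_rf` events, and a barrier-plausibility check flags
  "ultrasound" that implausibly passes through walls undiminished;
* a **seeded synthetic scene generator** producing calibrated WAV scenes
  (shaped backgrounds, reference tone, narrowband/impact/FM/beep sources,
  enclosure attenuation, rf-only injection) with truth sidecars, so the
  whole pipeline is testable without facility access.

## Worked example: the singing ceiling lights

Older fluorescent ceiling lights emit continuous narrowband ultrasound.
The canonical synthetic scene reproduces that survey situation: a 94 dB
reference tone in second 0, a stationary background, and a 40.3--47.4 kHz
source switched on from 4 s to 9 s.

```r
library(usnoise)

fx    <- scene_lights(seed = 11)            # scene spec + annotation
scene <- render_scene(fx$spec)              # deterministic, truth sidecar
cal   <- calibrate_scene(scene, fx$cal_window)
sp    <- spectrogram(cal)                   # 12 one-second epochs

lv <- band_level_epochs(sp, fx$delta_band)  # delta cursor, 40.3-47.4 kHz
mean(lv[fx$on_epochs + 1])                  # 33.12  (lights on)
mean(lv[fx$off_epochs + 1])                 # 29.06  (lights off)

background_correct(33.1, 29.0)
#> $corrected [1] 30.96     $status [1] "ok"

bg <- fit_background(sp, fx$off_epochs)
detect_tonal(sp, bg)
#>    kind t_start_s t_end_s  f_lo_hz  f_hi_hz peak_level_db_spl excess_db
#>   tonal         4       9 40296.88 47406.25             33.14      4.11
```

Read: the band reads 33.1 dB SPL with the lights on versus 29.0 dB off;
energy subtraction attributes 30.96 dB SPL to the lights themselves; the
detector localises one tonal event to the on-period with the correct band
extent. Rendering the same scene behind a 30 dB enclosure
(`scene_lights(seed, inside_ivc = TRUE)`) yields zero detections -- a
closed cage shields its occupants from a source this weak.

The impact workflow is analogous: `scene_forceps()` emulates metal forceps
dropped onto a metal surface (bare, on a neoprene mat, or measured behind
a 10 dB cage attenuation); `cmd_survey()` produces the per-band
background/measured/difference table, `reduction_table()` the mitigation
reduction, and `attenuation_estimate()` the enclosure attenuation.
`cmd_table1()` re-derives every difference/reduction cell of the bundled
reference survey table (`survey_reference_table()`) and reports any
mismatch at printed precision.

A thin command-line dispatcher over the same functions is installed at
`inst/cli/noise-survey.R` (verbs: `calibrate`, `survey`, `table1`,
`simulate`, `screen-rf`).

## Scope

Vibration measurement, neural-network call classification, perceptual
(audiogram) weighting and hardware control are out of scope. Absolute
facility measurements obviously cannot be reproduced without the facility;
the synthetic scenes reproduce the *measurement chain* on inputs with the
same statistical structure.
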