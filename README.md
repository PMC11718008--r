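# fmcwvitals

Non-contact cardiorespiratory monitoring with a seat-back FMCW radar, in R.

A 60 GHz frequency-modulated continuous-wave (FMCW) radar mounted behind a
seat observes the back of a seated person. Breathing displaces the torso
wall by ~1 mm; each heartbeat adds a ~0.02 mm quasi-periodic displacement
whose cycle shows **two peaks followed by one valley** (the valley aligns
with the ECG T-wave; a three-peak cycle is associated with a prolonged
QTc). `fmcwvitals` implements both directions of this measurement:

* **Forward model** — synthesize raw beat-signal data cubes
  (frames × chirps × fast-time samples) from parametric breathing, a
  cardiac template train with jittered interbeat intervals (IBIs), body
  movement artifacts and noise, with recorded ground truth.
* **Inverse chain** — chirp averaging, fast-time FFT, multi-bin slow-time
  phase extraction and unwrapping (displacement = phase × λ/4π),
  time-domain body-movement compensation (derivative threshold
  0.48 mm/sample, cumulative-sum rebuild), breathing-rate estimation in
  0.1–0.8 Hz, variational mode decomposition (VMD, K = 10) of the
  0.8–6 Hz cardiac band, selection of the cardiac fundamental and its
  harmonics with rejection of integer multiples of the breathing rate,
  waveform reconstruction from ≥ 2 harmonics, valley-based IBI/HR, the HRV
  metrics RMSSD, SDRR and pNN50, and waveform-morphology flagging.

The core relations: beat signal
`y(t) = A²α · cos(2π f_min t_d + 2π K t t_d)` with delay `t_d = 2R/c`;
range resolution `ΔR = c/(2·BW)` (3 cm at 5 GHz); displacement read from
the slow-time phase as `d = φ · λ/(4π)`. HRV metrics follow their standard
definitions: RMSSD is the RMS of successive IBI differences, SDRR the
population SD of the IBIs, pNN50 the percentage of successive differences
exceeding 50 ms.

## Worked example

```r
library(fmcwvitals)

# a seated subject: 15 breaths/min at 1 mm, heart at 70 beats/min with
# 40 ms IBI jitter and a 0.02 mm two-peak waveform, plus a posture shift
prof <- physio_profile(breathing_rate = 15, mean_ibi = 0.857, ibi_sd = 40,
                       seed = 1)
rec <- simulate_recording(prof,
                          list(movement_event(120, "narrow_pulse")),
                          duration = 300)

report <- run_pipeline(rec$cube)
report
#> <vitals_report> status: ok
#>   BR 15.0 breaths/min | HR 69.6 beats/min | 348 beats
#>   RMSSD 20.8 ms | SDRR 31.0 ms | pNN50 2.5% | morphology: typical_two_peak
#>   flags: movement_compensated

glance(evaluate_against_truth(report, rec$truth))
#> # A tibble: 1 × 12
#>   n_true n_matched n_missed median_abs_ibi_error_ms ...
#> 1    348       348        0                    10.0 ...
```

The report says: breathing recovered at 15 breaths/min, heart rate at
69.6 beats/min from 348 detected beats, short-term variability (RMSSD)
21 ms, overall variability (SDRR) 31 ms, 2.5% of successive intervals
differing by more than 50 ms, and the cycle shape classified as the
typical two-peak pattern. The evaluation matches every detected valley to
the simulation's ground-truth beats: here all 348 beats are found with a
median absolute interbeat-interval error of 10 ms.

`autoplot(report)` draws the IBI tachogram; `tidy(report)` returns the
per-beat table. A command-line front end
(`inst/cli/fmcwvitals.R`, subcommands `simulate`, `process`, `evaluate`,
`calibrate-threshold`) wraps the same functions for shell use.

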