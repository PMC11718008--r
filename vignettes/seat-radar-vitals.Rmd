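---
title: "Cardiorespiratory monitoring with a seat-back FMCW radar: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiorespiratory monitoring with a seat-back FMCW radar: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcwvitals)
```

## The measurement problem

A millimetre-wave FMCW radar mounted behind a seat back observes the torso
of a seated person at 12--27 cm. Breathing moves the back wall by roughly a
millimetre; each heartbeat adds a quasi-periodic displacement of about
0.02 mm whose cycle shows two peaks followed by one dominant valley (the
valley aligning with the ECG T-wave; in subjects with a prolonged QTc the
cycle shows three peaks instead). The package implements both directions of
this measurement:

* a **forward model** that synthesizes raw beat-signal data cubes
  (frames × chirps × fast-time samples) from parametric physiology, movement
  artifacts, and noise, with recorded ground truth; and
* the **inverse chain** that recovers breathing rate (BR), heart rate (HR),
  the interbeat-interval (IBI) series, the HRV metrics RMSSD, SDRR and
  pNN50, and a waveform-morphology label from such cubes.

## Radar model

A chirp sweeps from $f_{\min}$ over bandwidth $BW = K T$. A reflector at
range $R$ delays the echo by $t_d = 2R/c$ and the mixer output is the beat
signal $A^2\alpha\cos(2\pi f_{\min} t_d + 2\pi K t\, t_d)$: its fast-time
frequency $K t_d$ encodes range in bins of
$\Delta R = c/(2\,BW)$ (3 cm at 5 GHz), and its slow-time phase moves by
$4\pi (f_{\min}+BW/2)\,d(t)/c$ for sub-wavelength displacement $d(t)$ —
the quantity the whole chain is built to read. The default waveform
(58 GHz start, 5 GHz sweep, 64 samples at 1 MHz, 32 chirps per frame,
20 Hz frame rate) gives a 96 cm maximum range and a ~4.96 mm centre
wavelength; displacement is phase times $\lambda/(4\pi)$. Sub-millimetre
range walk within one chirp is far below one range bin and is neglected.

The frame rate bounds two things at once: 20 Hz samples vibrations up to
10 Hz (twice the highest cardiac harmonic retained), and it caps the
*unambiguous slow-time velocity* at a quarter wavelength per frame
(~1.24 mm/frame). Displacement steps beyond that alias and no longer look
like anything physical — which is why the movement-artifact model keeps its
events inside the window between the compensation threshold (0.48 mm) and
that limit.

## Forward model and its defaults

The generator's defaults are the study conditions under which the package
evaluates itself:

* breathing: 1 mm fundamental in the 0.1--0.8 Hz band, with 2nd--4th
  harmonics at 4%, 2% and 1% of the fundamental. In quiet breathing these
  harmonics have amplitudes comparable to the cardiac displacement itself
  (a few hundredths of a millimetre), which is precisely why they are the
  method's main adversary; deep breathing is emulated by raising them until
  the second harmonic dominates the cardiac band.
* heart: a 0.02 mm cardiac template train. The template is a sum of smooth
  wrapped-Gaussian lobes — the cycle shape is known only qualitatively, so
  the two/three-peak count and the dominance of the valley are the
  contract, and the first-to-second peak ratio (default 0.7; the second
  peak dominates at rest) is a parameter.
* interbeat intervals: a mean-reverting AR(1) sequence with stationary SD
  40 ms, lag-1 autocorrelation 0.8 (resting RR series are strongly
  autocorrelated through respiratory coupling), clipped to 0.3--1.5 s.
* movement artifacts: narrow strong pulses and positive/negative DC steps,
  defaulting to 5 mm over 1 s (peak step ~0.79 mm/frame — detectable,
  unaliased).
* noise: per-chirp phase noise (0.05 rad SD, common to all scatterers, so
  32-chirp averaging buys $10\log_{10}32\approx15$ dB for white noise) and
  independent additive receiver noise per sample. The torso is six
  scatterers at consecutive range bins sharing one displacement with
  independent log-normal reflectivities.

The evaluation cohort (`cohort_recording()`) draws each subject's mean IBI
uniformly from 0.70--1.05 s (rest HR 57--86), independent of the breathing
rate, as in a resting adult population; coincidences between the cardiac
fundamental and a breathing multiple therefore occur at their natural rate
and are handled by refusal rather than avoided by construction.

What the generator does *not* emulate: body-shape-specific reflection
patterns, posture-dependent coupling, non-stationary breathing depth,
ectopic beats, clutter and multipath, RF nonlinearity, or multiple people.
Passing tests on this cohort show the chain's signal-processing claims
hold under controlled physics; they do not certify clinical performance.

## The inverse chain

1. **DC removal, chirp averaging, fast-time FFT** (rectangular window —
   isolated point scatterers), one-sided spectrum; bins 4--9 are the
   default torso span.
2. **Phase extraction**: per-bin slow-time phase, 2π-unwrapped, scaled by
   $\lambda/4\pi$, initial offset removed.
3. **Movement compensation**: first-difference the trace, mask steps above
   0.48 mm/sample (the empirical-rule mean + 3 SD of clean-breathing
   steps; `calibrate_threshold()` re-derives it), and rebuild by
   cumulative sum. Two refinements matter in practice: a double-threshold
   (hysteresis 0.25 mm) extension of each spike run — an event's ramp-in
   and ramp-out steps are sub-threshold but are still movement — plus a
   5-sample margin; and derivative interpolation across the masked run
   instead of zeroing, which preserves the breathing drift underneath the
   event (zeroing a one-second window deletes ~1 mm of genuine breathing
   change and leaves a baseline break whose broadband spectrum is far
   larger than the cardiac signal). Pure zero-fill semantics remain
   available (`motion_config(fill = "zero", hysteresis = 0,
   spike_dilation = 0)`).
4. **Breathing**: zero-phase FFT band-pass 0.1--0.8 Hz with raised-cosine
   skirts, Welch spectrum (Hann, 60 s segments, 50% overlap, padded FFT),
   peak → BR; harmonics 1--4 form the exclusion list. Breathing-band RMS
   below 0.15 mm flags a breath-hold (BR undefined, exclusions empty).
   One-sigma cross-bin rejection fuses the per-bin estimates.
5. **Cardiac band**: 0.8--6 Hz zero-phase FFT filter. The lower skirt
   passes a 0.9 Hz fundamental with well under 3 dB loss — raising the
   edge to 1 Hz is the classic failure in which a 55 beats/min fundamental
   is suppressed and its second harmonic reported as HR.
6. **Variational mode decomposition** into K = 10 modes (see below).
7. **Harmonic selection** ("the strongest component that is not a
   breathing multiple is the heart"): every in-band mode is scored as a
   candidate fundamental by its harmonic pattern — the number of orders
   2--4 at which other modes sit within `max(0.05 Hz, 3%)` of its integer
   multiples, with power as tie-break. If the winner sits on a breathing
   multiple, reconstruction is refused (the HR cannot be trusted);
   otherwise modes within a wider gathering window (`max(0.15 Hz, 8%)`,
   at least 10% of the order's main mode) are collected at orders 1--4,
   breathing exclusion always winning. At least two components are
   required; the reconstruction is their sample-wise sum.
8. **Beats and metrics**: valleys (prominence ≥ 30% of the median cycle
   amplitude, ≥ 0.3 s apart) on the ×4 band-limited-upsampled waveform,
   timed by least-squares alignment against the ensemble-average cycle;
   per-bin HRs pass one-sigma rejection; surviving bins vote per beat
   (majority required) and the cross-bin median times each fused beat;
   interval artifact correction (below); RMSSD/SDRR/pNN50 on the
   normal-to-normal set; morphology from the band-passed waveform.

## Decomposition choices

The canonical alternating (ADMM) scheme is implemented directly: Wiener
update of each mode's spectrum around its centre frequency, centroid update
of the centre, optional dual ascent (`tau = 0` by default — tolerant to
noise), mirror extension, tolerance 1e-7, at most 500 iterations per
round, centres initialized uniformly over the cardiac band. Four choices
depart from the textbook recipe, each forced by measurement:

* **Bandwidth penalty `alpha = 40000`** in the pipeline (the function's own
  default stays at the literature's 2000). The mode half-width is
  $f_s/\sqrt\alpha$; at $f_s = 20$ Hz, 2000 gives ~0.45 Hz-wide modes that
  swallow a cardiac fundamental and the nearest breathing multiple
  (0.1--0.2 Hz apart under these conditions) into one mode, breaking the
  exclusion logic. 40000 gives ~0.1 Hz half-width: narrow enough to
  resolve them, wide enough to keep most jitter sidebands.
* **Reported centre frequency = parabolic-refined spectral peak**, not the
  ADMM centroid: the Lorentzian filter tails overlap neighbouring lines
  and bias the centroid by several percent, which then breaks
  integer-multiple matching. The internal updates stay canonical.
* **Degenerate-mode aggregation** (`merge_tol = 0.02` Hz): with more modes
  than narrowband components, surplus modes converge onto one component
  and split its energy arbitrarily; since the whole selection logic ranks
  modes by power, co-located modes are summed (reconstruction unchanged)
  and the freed slots kept as zero modes.
* **Residual re-seeding** (≤ 5 rounds): the greedy updates strand a weak
  line lying between two stronger neighbours (the deep-breathing cardiac
  fundamental, typically). After each convergence, if the strongest
  residual line *outside every mode's half-width* exceeds twice the
  weakest mode's peak, that mode is re-seeded onto it deterministically.

## Beat-series cleanup and NN intervals

The fused beat list is corrected before HRV computation. Interval outliers
are judged against an adaptive band, median ± max(4 × MAD, 25% of the
median), so the rules scale with the subject's own variability: duplicate
detections (< 0.3 s apart — physiologically impossible) merge to their
midpoint; a spurious beat splitting one interval into two short halves is
removed; an interval beyond the upper band is treated as missed beats and
evenly interpolated; adjacent short/long intervals with a plausible sum
but a successive difference above 200 ms mark one mistimed beat, which is
re-centred. Interpolated beats, beats within 3.5 s of a
detected movement spike (the event plus the band-pass ringing around it),
beats within 5 s of the recording edges (filter settling), and beats whose
local cycle amplitude falls below 45% of the median (a ~4 dB drop — the
signature of destructive interference) are excluded from the
normal-to-normal set used for RMSSD, SDRR and pNN50; HR and the reported
IBI series keep the full corrected series. SDRR uses the population
standard deviation.

A wide-band per-beat re-timing step (`refine_beats_wideband()`) is
implemented but off by default: it recovers timing detail the narrowband
reconstruction smooths away, but at the cohort's noise level it locks onto
breathing interference instead and was measured to do more harm than good.
This is a known limitation: the chain slightly *underestimates* RMSSD
because mode filters truncate jitter sidebands.

## Morphology

The two-peaks-then-valley versus three-peaks-then-valley distinction is a
property of the band-passed waveform, not of the harmonic reconstruction
(narrowband re-synthesis demonstrably erases the weak third peak), so the
classifier runs on the 0.8--6 Hz trace. The default estimator averages all
valley-aligned, time-normalized cycles and counts peaks on the mean cycle
with a prominence floor of 6% of the cycle span — calibrated on clean
band-limited template trains, where the weakest genuine secondary peak
keeps ~10% of the span and ensemble noise ripples stay under ~2%. Per-beat
noise at the 0.02 mm scale makes cycle-by-cycle counting hopeless, but a
per-cycle majority variant (70% of cycles) is kept for recordings whose
shape may genuinely alternate, where an ensemble average would blend the
shapes. Morphology needs near-stationary beat timing (heavy jitter smears
the harmonic phases); the evaluation cohort for this claim therefore
emulates the calm-rest/breath-hold protocol under which the patterns were
established: 0.1 mm breathing, 10 ms IBI jitter, no movement events.

## Problem sizes and determinism

The standard evaluation runs 8 recordings × 300 s at 20 Hz (6000 frames ×
32 chirps × 64 samples each) for the error bounds and ablations, and
2 × 10 recordings × 120 s for morphology; unit tests use 40--120 s
fixtures. Every stochastic element is seeded through one integer per
recording; identical seeds give bit-identical cubes and reports. All
filters are zero-phase; signals are bridge-detrended before FFT filtering
(the filter is circular, and post-compensation baseline drift otherwise
rings into the passband); beat counting and timing run on ×4 band-limited
interpolation, exact for signals below a quarter of the original Nyquist.
Band-pass filtering uses reflection padding (the FFT filter is circular,
and post-compensation baseline drift would otherwise act as a step
discontinuity ringing into the passband); stopband attenuation is a
steady-state property, with the usual zero-phase edge transients confined
to the first/last seconds — one reason for the edge guard above.

## Reading results

`run_pipeline()` returns a `vitals_report` whose `status` distinguishes a
normal run, breath-hold, reconstruction refusal (the cardiac fundamental
sat on a breathing multiple — reporting a number would risk a doubled HR),
and insufficient beats. `glance()` gives the one-row summary,
`tidy()` the per-beat table, `autoplot()` the tachogram, and
`evaluate_against_truth()` the error summary against simulated ground
truth.
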