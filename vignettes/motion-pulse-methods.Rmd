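---
title: "Motion-based cardiac signal estimation from video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based cardiac signal estimation from video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primpulse)
```

## The measurement principle

Cardiopulmonary activity moves the body surface: every heartbeat displaces
the head and face by a fraction of a millimetre, and breathing adds a slower
oscillation. Under stable illumination these movements modulate the light
intensity reflected into a camera. `primpulse` estimates heart rate from
that modulation — a motion-based (ballistocardiographic) method, not
imaging photoplethysmography: it does not rely on skin-colour variation and
therefore works on densely haired, heavily pigmented faces such as those of
chimpanzees, filmed with an ordinary camera at ordinary frame rates
(25 fps in the setting the pipeline is calibrated for).

The processing chain implemented by `estimate_pulse()` is:

1. **ROI tracking.** A rectangular facial region of interest is supplied
   for the first frame and stabilised over time with a MOSSE correlation
   filter, so the intensity signal follows the moving head.
2. **Luma extraction.** Each RGB frame is converted to YCbCr; only the
   intensity channel Y is used. The raw signal is the mean of Y over the
   ROI, one sample per frame: `i_Y(t) = sum I(x, y, t) / |ROI|`.
3. **Cardiac isolation.** The trace is band-passed to the cardiac band
   (1.5–4.2 Hz, i.e. 90–250 beats per minute; a third-order Butterworth
   applied forward and backward), then decomposed with CEEMDAN; the
   intrinsic mode function carrying the cardiac oscillation is selected.
4. **Pulse statistics.** Peaks of the cardiac component are detected; heart
   rate follows the peak-count formula `HR = 60 p F_r / n` (p peaks over n
   frames at frame rate F_r), reported over 10 s windows and over whole
   segments; interbeat intervals pass a ±25 % plausibility filter.
5. **Segment qualification.** Only maximal runs of at least 100 s without
   tracker target loss are analysed, so that at least ten consecutive
   windowed heart-rate values exist for any comparison with a reference.

Validation statistics against a reference pulse recording (`compare_pulse()`)
are the session mean error in percent, the Pearson correlation across
paired 10 s windows, and a two-sample Kolmogorov–Smirnov test on the two
interbeat-interval distributions.

## Model components and their parameters

### Colour transform

The YCbCr conversion multiplies RGB scaled to [0, 1] and adds the offset
(16, 128, 128), so Y lies in [16, 235] — only this scaling convention is
consistent with first-row coefficients summing to ≈ 219. The default
`"paper"` coefficient set is the one this pipeline was described with; it
departs from ITU-R BT.601 in three entries (65.841 vs 65.481, −39.797 vs
−37.797, −18.2214 vs −18.214). Whether those three entries are
typographical cannot be settled from the description, so both are provided
(`color_matrix("paper")`, `color_matrix("bt601")`) with the described set
as default. The difference is irrelevant downstream: only the temporal
variation of Y enters the analysis, and the two matrices differ by a fixed
near-identity linear map.

### MOSSE tracker

The filter is defined in the Fourier domain as `H* = A/B` with
`A_i = η G ⊙ F_i* + (1−η) A_{i−1}` and `B_i = η F_i ⊙ F_i* + (1−η) B_{i−1}`,
learning rate η = 0.125. Parameters the original description leaves open
follow common correlation-filter practice:

* patch preprocessing: `log(1+v)`, zero-mean unit-norm, Hann window;
* Gaussian target response, `target_sigma` = 2 px;
* initialisation over 8 training patches (the exact crop plus 7 small
  random affine warps, seedable);
* denominator regularisation ε = 1e−5;
* target loss when the peak-to-sidelobe ratio of the response falls below
  5 (sidelobe excludes an 11×11 window around the peak);
* the filter update uses the patch at the newly located position; with
  η = 1 the update is exactly a fresh single-patch initialisation
  (memoryless limit), which the tests assert.

The box size is fixed (translation only — the update equations carry no
scale term), and the tracked box itself is the ROI for the intensity trace.
There is no re-detection after loss: losing the target simply truncates the
qualifying segment, as in the exclusion of noisy session parts the method
was designed around.

### Band-pass and decomposition

Both passbands are third-order Butterworth: respiratory 0.25–0.8 Hz
(15–48 breaths/min) and cardiac 1.5–4.2 Hz. Filtering is zero-phase
(forward–backward) so that detected peak times are not shifted against a
reference trace; a causal filter would delay peaks by a
frequency-dependent amount and bias the KS comparison. The stated band
edges are taken as authoritative where the equivalent in beats per minute
would disagree (4.2 Hz rather than 250/60 Hz).

CEEMDAN (complete ensemble empirical mode decomposition with adaptive
noise) separates the band-passed trace into intrinsic mode functions.
Stage 1 averages the first sifted mode of `ensemble_size` noise-perturbed
copies `x + β₀ w_i`; stage k perturbs the running residual with the k-th
EMD mode of each stored noise realisation, `r_k + β_k E_k(w_i)`, and
averages the first sifted mode; residuals are formed by subtraction, so
reconstruction is exact by construction (asserted at 1e−8 relative).
Defaults: relative noise amplitude `noise_std` = 0.2 (β_k scales with the
running residual's standard deviation), `ensemble_size` = 100, at most 9
IMFs, all driven by one seed. Sifting uses natural cubic-spline envelopes
through the extrema with up to two extrema mirrored about each end (edge
control), plateau-aware extrema detection, and the classical Cauchy
stopping criterion at 0.2. The sifting core is compiled (C++); the test
suite contains an independently written plain-R implementation of the same
algorithm and asserts per-IMF correlation above 0.99 on fixed signals, as
well as exact additive reconstruction.

The decomposition is run *after* the cardiac band-pass, which is the
stated processing order, even though published IMF spectra for this method
span frequencies below the cardiac band — a tension we note but do not
attempt to resolve; with the band-passed input the cardiac component is
nominally the first meaningful mode.

**IMF selection.** The original rule — "take IMF 1" — assumes the first
mode carries the cardiac oscillation. In this implementation the ensemble
noise residue often occupies the first one or two modes, and the cardiac
tone can split across neighbouring modes. The selection rule is therefore
band-constrained: among IMFs whose dominant frequency (Hann-windowed
periodogram with parabolic peak interpolation) lies in the cardiac band,
the one with the greatest in-band spectral power is chosen; when no IMF
qualifies the segment is declared to have no usable cardiac component.
On a clean band-passed tone this reduces to the first qualifying mode.

### Peak detection

Peaks are local maxima (plateau-aware: a run of tied samples counts once,
at its midpoint — symmetric pulses sampled at 25 fps routinely tie two
samples) subject to two rules: a minimum separation of `60/max_bpm`
seconds, and a topographic prominence of at least `prominence_frac` times
the trace standard deviation. The separation rule is the primary guard
against ripple sub-peaks. The prominence default is 0.1: the selected IMF
is amplitude-modulated wherever the cardiac tone leaks into a neighbouring
mode, and a stricter cut (e.g. 0.3·sd) demonstrably discards genuine beats
in dipped stretches (on a representative synthetic run, 277 of 286 beats
recovered at 0.3·sd vs 285 at 0.1·sd), biasing heart rate low by several
beats per minute. Windows with zero detected peaks report `NA` rather
than 0 beats per minute.

The session heart rate reported by `estimate_pulse()` applies the
peak-count formula over all analysed segment frames (p = all peaks,
n = all frames), which avoids the ±6 BPM count quantisation of individual
10 s windows; the windowed series is what enters comparisons against a
reference, since windowed averaging is how the method is validated.

### Interval filter and segment rules

"Within 25 % of the average detected pulse period" is read literally: raw
intervals are successive peak differences; the mean is computed once over
the raw intervals of the segment (not iterated, not session-pooled), and
intervals outside [0.75 μ, 1.25 μ] are discarded. Which interval *values*
survive is invariant to their order, and on constructed lists the filter
reproduces brute-force application of the rule. Segment qualification
demands at least 100 s without target loss at the default window of 10 s —
the shortest stretch giving the ten consecutive heart-rate values a
comparison requires.

### Validation statistics

The mean error is defined on session means,
`100·|mean(videoHR) − mean(refHR)| / mean(refHR)`, absolute-valued; this
reading reproduces the published worked cell (video mean 152.7 vs
reference mean 153.1 → 0.26 %) and is preferred over per-window absolute
percentage error, which does not. Windows are paired by start time with a
±0.5 s tolerance and at least ten pairs are required. The KS p-value uses
the asymptotic two-sample distribution at effective size
`n_a n_b/(n_a+n_b)`; the tests check it against a 10,000-draw permutation
oracle (agreement within 0.02 at 30-draw samples).

## The synthetic generator

`make_video()` renders the quantity the ROI measurement actually sees: a
textured "face" patch (smoothed seeded noise, mean 120, contrast ±30 on
the 0–255 scale) on a plain background, whose intensity is modulated by a
cardiac sinusoid of amplitude `pulse_amplitude` (default 1.0 luma unit —
deliberately subtle), a respiratory sinusoid, a slow global illumination
drift (default amplitude 2 at 0.05 Hz, emulating the illumination
variations that motivate the use of CEEMDAN), and white frame-to-frame
illumination noise (`noise_std`, default 0.5). Frames are quantised to
8-bit integers as a camera would deliver; the textured patch dithers the
quantisation, so the sub-unit modulation survives averaging over the ROI.
The patch can translate along a per-frame motion path to exercise the
tracker. All randomness derives from one seed, frames are rendered on
demand from precomputed draws, and a given spec is bit-reproducible.

Heart rate may be a constant or a stepwise schedule; the cardiac phase is
the integral of the scheduled frequency. With `hrv_sd > 0`, each interbeat
interval is additionally perturbed by independent Gaussian noise and the
perturbed beat sequence drives *both* the video's cardiac phase and the
reference PPG (`make_ppg()`), which adds Gaussian-shaped pulses at those
beat times with optional sensor-side beat jitter (`jitter_sd`) and dropout
bursts. Beat-to-beat variability is the phenomenon the KS comparison
targets; without it the comparison is degenerate, because video-derived
intervals are quantised to the 40 ms frame grid while a strictly periodic
reference concentrates on one or two values.

What the generator does *not* emulate: real facial texture and
three-dimensional head pose change, skin specularity, compression
artefacts, camera shake, and physiological waveform morphology (systolic
and diastolic shape, dicrotic notch). Passing the synthetic recovery tests
therefore demonstrates that the algorithm chain is implemented correctly
and recovers known ground truth under its stated signal model — it does
not certify accuracy on real chimpanzee video, which would require the
original recordings and reference sensor data.

## Problem sizes and study conditions

The end-to-end recovery study (in both the test suite and
`scripts/acceptance.R`) uses 20 seeded videos of 110 s at 25 fps and
160×120 px, heart rates drawn uniformly from 96–180 BPM, with
`noise_std = 0.35` putting the cardiac-band signal-to-noise ratio near
6 dB (comfortably above the 5 dB floor the study conditions specify);
recovery within 3 BPM of truth is required in at least 18 of 20. The
validation session reported by the acceptance script uses 110 s at
140 BPM with `hrv_sd = 0.08` — wide, "flat" interbeat distributions of
the kind reported for chimpanzee sessions — sensor jitter of 5 ms and a
2.5 s dropout burst. Decomposition oracle checks run at 300–400 samples
with ensembles of 20, where the plain-R reference is affordable.

## Known limitations

* **Interval quantisation.** At 25 fps, video interbeat intervals live on
  a 40 ms grid. Unless the true interval distribution is several grid
  steps wide, a KS test against a finely sampled reference will reject on
  discreteness alone; the acceptance report's KS values should be read
  with this in mind. The heart-rate statistics are unaffected.
* **Mode splitting.** CEEMDAN can distribute a narrowband cardiac tone
  over adjacent IMFs; the band-power selection rule picks the dominant
  share, and the permissive prominence threshold recovers beats in the
  dipped stretches, but a few beats per session can still be lost near
  splits.
* **Tracker relearning.** After a genuine target loss the adaptive filter
  may relearn the background and the peak-to-sidelobe ratio can climb back
  above threshold, so loss flags become intermittent; qualification is
  conservative only while the flags persist. There is no re-detection.
* **No container decoding.** Compressed video (MP4/AVI) must be decoded to
  PNG frame directories externally; the package reads frame directories
  and in-memory or lazily generated frame stacks.
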