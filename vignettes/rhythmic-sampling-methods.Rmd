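---
title: "Rhythmic sampling of frequency-tagged target and distractor: methods"
author: "rhythmtag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic sampling of frequency-tagged target and distractor: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rhythmtag)
```

## The analysis problem

In a dual frequency-tagging design, an attended random-dot kinematogram
(the *target*) and an ignored affective picture (the *distractor*) flicker
concurrently at distinct rates. Each flicker entrains a steady-state visual
evoked potential (SSVEP) at its own frequency, so the EEG response to each
stimulus can be isolated spectrally even though the stimuli overlap in
space and time. The scientific question is temporal: is the processing
strength of each stimulus constant over the trial, or does attention sample
the two stimuli rhythmically — and if both are sampled at a shared
delta-band rhythm, does the *relative phase* of the two sampling time
courses predict behavior?

`rhythmtag` implements the full chain: narrowband SSVEP isolation,
moving-window amplitude and decoding-accuracy time series, envelope
spectra and delta-band peak detection, relative-phase estimation, and
cohort statistics — together with a synthetic-EEG generator with known
ground truth, so every stage can be validated by parameter recovery
without any recorded data.

## Paradigm arithmetic

Tag frequencies are defined as exact refresh-rate ratios, not decimals: a
60 Hz display with a 14-frame target cycle (6 on, 8 off) gives
$f_T = 60/14 = 4.2857$ Hz ("4.29 Hz" as a display label), and a 10-frame
distractor cycle gives $f_D = 6$ Hz. An 11.667 s trial then holds exactly
50 target and 70 distractor cycles; keeping the ratios exact avoids
cumulative phase drift over the trial. Coherent-motion events span 4 target
cycles (933 ms) inside the 2.3-10.4 s window. `makeSchedule()` checks that
the trial duration is a common multiple of both periods to within one
refresh frame and reports the implied cycle counts when it is not.

Trials are 28 per emotion category (pleasant, neutral, unpleasant; 84
total); epochs are sampled at 500 Hz, giving floor(11.667 x 500) = 5833
samples per trial.

## The forward model behind the synthetic data

`simulateSubject()` generates, per trial, channel $c$ and time $t$:

$$x_c(t) = w_T(c)\,A_T\,[1 + m\cos(2\pi f_s t + \phi)]\,p_T(t) +
  [w_D(c) + \delta_{cat}(c)]\,A_D\,[1 + m\cos(2\pi f_s t + \phi +
  \Delta\phi)]\,p_D(t) + \varepsilon_c(t)$$

* $p_T, p_D$: flicker responses at the tag frequencies — pure sinusoids by
  default; a square-wave on/off mode (duty cycle from the frame counts)
  adds harmonics and exercises filter selectivity.
* $w_T, w_D$: occipitally weighted topographies (target peaking at Oz,
  distractor at POz) over a standard 31-channel 10-20 montage.
* $f_s$: the sampling-rhythm frequency (default 1 Hz), $m$ the modulation
  depth (default 0.5), $\phi$ one uniformly drawn envelope phase per
  subject, $\Delta\phi \in [0, \pi]$ the injected target-distractor
  relative phase — the controlled quantity.
* $\delta_{cat}$: fixed unit-norm random per-category patterns scaled by
  `patternSeparability`, giving each emotion category a distinct 6 Hz
  spatial pattern. Because $\delta_{cat}$ multiplies the distractor
  envelope, decodability waxes and wanes with the distractor's sampling
  rhythm.
* $\varepsilon$: per-channel independent $1/f^\alpha$ noise
  ($\alpha = 1$), with RMS set so that the deterministic tagged signal at
  its best channel has `snr` times the noise RMS. Noise is spatially
  white; real EEG noise is spatially correlated, which is one reason
  passing recovery tests here do not guarantee identical sensitivity on
  recorded data.

Behavioral accuracy per subject is
$\mathrm{clip}(0.35 + 0.45\,\Delta\phi/\pi + \mathcal{N}(0, 0.15),\,0,\,1)$
— the simplest monotone model of the observed positive phase-performance
relationship; per-category accuracies add only a small jitter (sd 0.03)
because the design predicts no category effect on behavior.

### Calibrated defaults

Two generator constants were calibrated once, before the validation
thresholds were frozen, and are not revisited:

* `patternSeparability = 0.02` at `snr = 1` puts whole-trial decoding at
  roughly 56% pairwise and 41% three-way, the observed range for this
  paradigm (chance 50% / 33.3%).
* `behaviorGain = 0.45`, `behaviorNoiseSd = 0.15` put the phase-behavior
  Pearson correlation near 0.6, the observed effect size.

## Narrowband isolation

The tag-specific signals are obtained by zero-phase band-pass filtering of
the trial-averaged SSVEP to center ± 0.5 Hz. The filter is applied in the
frequency domain: flat response on the passband, cosine taper to zero over
a 0.75 Hz transition, zero beyond, with 2 s reflection padding against
boundary transients. This construction is exactly zero-phase (no group
delay at any frequency) and satisfies: unit passband gain (a centered tone
passes at 1.00 ± 0.01), total rejection of the other tag (offset 1.71 Hz
lies beyond the taper), and ≥ 80% of white-noise output variance within
center ± 0.75 Hz.

The transition width is a deliberate scientific choice, not a convenience:
amplitude modulation of a carrier at $f_s \approx 1$ Hz lives entirely in
sidebands at $f_{tag} \pm 1$ Hz. A brick-wall ± 0.5 Hz filter would remove
those sidebands and with them the very modulation the envelope analysis
measures — no estimator can recover a rhythm the filter has deleted. The
cosine taper keeps the ± 1 Hz sidebands at half amplitude. The
complementary cost is mild leakage of the target's upper sideband
(5.29 Hz) into the distractor band; that leakage is identical across
emotion categories and therefore cannot inform decoding.

Trials are filtered in full and only then cropped to the 2-11 s analysis
interval, so filter transients fall outside the scored segment.

## Amplitudes, envelopes and spectra

Whole-trial and windowed amplitudes are $\sqrt{2}\times$RMS of the
narrowband signal — the peak amplitude of a pure tone — rather than an FFT
bin, because 60/14 Hz does not sit on the FFT grid of a 9 s segment. Two
numerical floors follow from this estimator and are worth knowing:

* A 0.5 s window holds a non-integer number of 60/14 Hz half-cycles, so
  even a perfectly unmodulated tone shows a phase-sampling ripple of
  $\sin(2\pi f L)/(2\pi f L)/2 \approx 2\%$ across windows. "Constant
  envelope" therefore means a coefficient of variation at that floor, not
  at machine precision.
* Windowed RMS smooths the envelope by roughly the window's sinc factor:
  with a 0.5 s window, a (1 + 0.5 cos 2πt) envelope yields a series
  max/min ratio near 2, approaching the true 3 only as the window
  shortens (the 0.1 s diagnostic window reaches ≈ 3).

The default moving window (0.5 s length, 0.25 s step over 2-11 s) yields
35 points at 4 Hz. Envelope series are mean- and linear-trend-removed
(discarding the DC carrier term of the AM) and zero padded to at least 512
points before the amplitude spectrum is taken; the spectral peak is the
global maximum in 0.25-3 Hz, a band that covers delta, excludes DC
leakage, and deliberately includes the 1.71 Hz two-tone beat so that
injected modulation can be distinguished from pure signal-processing
beating. Ties break toward the lower frequency. The window-free Hilbert
(analytic-signal) envelope is provided as a robustness alternative and
agrees with the windowed estimate within one raw bin on the same subject.

## Subset-averaged decoding

Distractor processing is indexed by decoding the emotion category from the
per-channel 6 Hz amplitude pattern. Trials of each category are randomly
split into 3 near-equal subsets; each subset is trial-averaged into a
"subset SSVEP" (the pseudo-trial trick that trades trials for SNR);
features are per-channel $\sqrt{2}\times$RMS of the 6 ± 0.5 Hz narrowband
subset SSVEP over the scoring window. A linear SVM (C = 1, LibSVM via
e1071, no tuning) is trained on 2 subsets per class and tested on the
held-out one; all 3 folds are rotated per iteration (the spec's original
description draws a single assignment — full rotation averages the same
estimator over folds and reduces variance; a `rotateFolds = FALSE` flag
restores the narrower scheme), and 100 fresh random partitions are
averaged by default. Features are standardized with training-fold
statistics (flag-controlled); three-way decoding uses one-vs-rest decision
values with ties broken by the fixed category order.

Because subset-averaging, linear filtering and windowed RMS commute, the
implementation precomputes per-channel trial Gram matrices over each
scoring window; random partitions then cost $O(|S|^2)$ sums instead of
re-averaging waveforms, which is what makes 200-permutation null
distributions affordable. A consistency test asserts the Gram route equals
the direct average-filter-RMS route.

The moving-window decoder reuses the same partition schedule across
windows within an iteration, so temporal fluctuations of the accuracy
series reflect the signal, not partition noise.

## Where rhythm recovery works — and where it cannot

Recovery of the injected $f_s$ from the *amplitude* series succeeds at the
default conditions (snr = 1): trial averaging attenuates noise by
$\sqrt{84}$ before the envelope is taken.

The *decoding-accuracy* series is different. At the whole-trial-calibrated
defaults, per-window decodability is barely above chance (features rest on
0.5 s of data, 4.2 times noisier than the 9 s whole-trial features), and
the accuracy series is dominated by frozen trial noise that no number of
partition iterations can remove. Decoding-series recovery is therefore
validated on a strong-pattern subject (`patternSeparability = 0.15`,
`snr = 2`), where mean window accuracy sits mid-range (≈ 0.85). Even
there, recovery succeeds for roughly three quarters of simulated subjects;
in the remainder a low-frequency (0.25–0.6 Hz) component of the frozen
trial noise outweighs the 1 Hz accuracy modulation, and raising the
number of partition iterations does not help — the limit is the data, not
the estimator precision. Both extremes of decodability fail for opposite
reasons: near chance there is no modulation to see, and at saturation
(accuracy ≈ 1 everywhere) the bounded accuracy scale clips the rhythm
away. This
mirrors the empirical observation that decoding-based rhythmicity is an
SNR-limited measurement. Relative-phase recovery and the phase-behavior
link are validated under the same strong-pattern conditions at the
paradigm's cohort size (n = 27).

The noiseless end-to-end phase check uses the 6 Hz *amplitude* series as
the distractor index (`summarizeSubject(distractorSeries = "amplitude")`):
noiseless decoding saturates at accuracy 1.0 and carries no rhythm at all,
so a closed-form antiphase subject is only recoverable through the
amplitude route.

## Relative phase and group statistics

Both series are detrended and their phases read from the DFT bin nearest
the evaluation frequency; `fEval = "auto"` uses the mean of the two
spectral peak frequencies, guarded to agree within 2 raw bins (phases at
unrelated frequencies are meaningless). The relative phase is the folded
absolute difference in $[0, \pi]$: the sign is discarded because only the
degree of temporal separation (in-phase vs antiphase sampling) is
interpreted. A 3-bin cross-spectrum variant (`neighborhood = 1`) is
available for robustness reporting. Within the cohort pipeline, a subject
whose two peaks disagree beyond the guard is evaluated at the
target-series peak rather than aborting the run.

Cohort statistics follow the conventions of the design: arithmetic mean
± sd of the folded phases reported in π units; a one-sample two-sided
Kolmogorov-Smirnov test of phases/π against uniform(0, 1) with the
asymptotic p (adequate at n = 27; exact p behind a flag); Pearson
correlation (two-sided — the direction is a hypothesis, but sidedness is
unstated in the source convention) between phase and accuracy; one-sample
t against chance for decoding; and a one-way between-subjects ANOVA on
the 3 × n per-category accuracies, giving df = (2, 3n − 3) — chosen
deliberately to match the headline df convention even though the design
is within-subject.

## Problem sizes and determinism

Every stochastic operation takes an explicit integer seed and restores the
caller's RNG state, so pipelines are pure functions of (config, seed);
`runPipeline()` writes byte-identical reports on reruns. Validation runs
use desk-scale sizes chosen to exercise the claims without waste: 50 seeds
for frequency-recovery rates, 200 label permutations for chance
calibration (null mean within ± 0.02 of chance), 15 runs over the
$\Delta\phi$ grid for phase recovery (median error < 0.1π), one n = 27
cohort plus 1000 redrawn null behaviors for correlation calibration, and
reduced iteration counts (6-20) where the quantity of interest is a mean
over windows or permutations rather than a single subject's precision.

## Known limitations

* Spatially white noise, fixed topographies, no eye or muscle artifacts,
  no inter-trial latency jitter: recovery rates here are upper bounds on
  real-data sensitivity.
* The gentle filter transition trades a little distractor-band purity
  (category-independent target sideband leakage) for envelope fidelity.
* The behavior model is linear in $\Delta\phi/\pi$; any monotone link
  would fit the qualitative claim, and the linear choice is the simplest.
* Whole-trial amplitude conflates stimulus drive with attention (no
  no-distractor baseline exists in the design); only the within-trial
  dynamics are interpreted.
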