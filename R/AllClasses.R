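#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Paradigm / stimulus schedule
## ---------------------------------------------------------------------------

#' Experimental paradigm configuration
#'
#' Frame-accurate description of the dual flicker paradigm: an attended
#' random-dot target and an ignored affective-picture distractor flickering at
#' rates defined as exact ratios of the display refresh rate. With the
#' defaults (60 Hz refresh, 6-on/8-off and 6-on/4-off frame cycles) the tag
#' frequencies are 60/14 = 4.2857 Hz (displayed as "4.29 Hz") and 60/10 =
#' 6 Hz, and an 11.667 s trial holds exactly 50 target and 70 distractor
#' flicker cycles.
#'
#' @slot refreshRate display refresh rate, Hz.
#' @slot targetOnFrames,targetOffFrames frames per target flicker cycle
#'   (default 6 + 8: 100 ms on, 133.33 ms off).
#' @slot distractorOnFrames,distractorOffFrames frames per distractor flicker
#'   cycle (default 6 + 4: 100 ms on, 66.67 ms off).
#' @slot trialDuration trial length, s.
#' @slot nTrialsPerCategory trials per emotion category.
#' @slot categories emotion-category labels, in fixed order.
#' @slot motionWindow interval (s) within which coherent-motion events occur.
#' @slot motionCycles coherent-motion event duration in target flicker cycles.
#' @seealso [paradigmConfig()], [makeSchedule()]
#' @export
setClass("ParadigmConfig", representation(
  refreshRate = "numeric",
  targetOnFrames = "integer", targetOffFrames = "integer",
  distractorOnFrames = "integer", distractorOffFrames = "integer",
  trialDuration = "numeric",
  nTrialsPerCategory = "integer",
  categories = "character",
  motionWindow = "numeric",
  motionCycles = "integer"
))

setValidity("ParadigmConfig", function(object) {
  msg <- character()
  if (object@refreshRate <= 0) msg <- c(msg, "refreshRate must be > 0")
  fr <- c(object@targetOnFrames, object@targetOffFrames,
          object@distractorOnFrames, object@distractorOffFrames)
  if (any(fr < 1L)) msg <- c(msg, "all frame counts must be >= 1")
  if (object@trialDuration <= 0) msg <- c(msg, "trialDuration must be > 0")
  if (object@nTrialsPerCategory < 1L) msg <- c(msg, "nTrialsPerCategory must be >= 1")
  if (length(object@categories) < 1L || anyDuplicated(object@categories))
    msg <- c(msg, "categories must be distinct labels")
  if (length(object@motionWindow) != 2L ||
      object@motionWindow[1] < 0 || object@motionWindow[2] > object@trialDuration ||
      diff(object@motionWindow) <= 0)
    msg <- c(msg, "motionWindow must be an increasing interval inside [0, trialDuration]")
  # trial must hold an integer number of both flicker periods (within 1 frame)
  tol <- 1 / object@refreshRate
  for (nm in c("target", "distractor")) {
    per <- periodSeconds(object, nm)
    k <- round(object@trialDuration / per)
    if (abs(object@trialDuration - k * per) > tol)
      msg <- c(msg, sprintf(
        "trialDuration is not a common multiple of both flicker periods: %.4f s implies %.3f %s cycles",
        object@trialDuration, object@trialDuration / per, nm))
  }
  if (length(msg)) msg else TRUE
})

#' Stimulus schedule for one trial
#'
#' On/off cycle onsets of both flicker streams plus the coherent-motion
#' events of the target, produced by [makeSchedule()].
#'
#' @slot targetCycleOnsets,distractorCycleOnsets cycle onset times, s.
#' @slot nTargetCycles,nDistractorCycles cycle counts.
#' @slot motionEvents data.frame with columns `onset` and `duration` (s).
#' @slot config the generating [ParadigmConfig-class].
#' @export
setClass("StimulusSchedule", representation(
  targetCycleOnsets = "numeric",
  distractorCycleOnsets = "numeric",
  nTargetCycles = "integer",
  nDistractorCycles = "integer",
  motionEvents = "data.frame",
  config = "ParadigmConfig"
))

setValidity("StimulusSchedule", function(object) {
  msg <- character()
  if (object@nTargetCycles != length(object@targetCycleOnsets))
    msg <- c(msg, "nTargetCycles must equal length(targetCycleOnsets)")
  if (object@nDistractorCycles != length(object@distractorCycleOnsets))
    msg <- c(msg, "nDistractorCycles must equal length(distractorCycleOnsets)")
  per <- periodSeconds(object@config, "target")
  d <- diff(object@targetCycleOnsets)
  if (length(d) && max(abs(d - per)) > 1e-9)
    msg <- c(msg, "consecutive target onsets must differ by exactly one target period")
  if (nrow(object@motionEvents)) {
    mw <- object@config@motionWindow
    ok <- object@motionEvents$onset >= mw[1] &
      object@motionEvents$onset + object@motionEvents$duration <= mw[2]
    if (!all(ok)) msg <- c(msg, "every motion event must lie inside motionWindow")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic generator
## ---------------------------------------------------------------------------

#' Synthetic EEG generator configuration
#'
#' Parameters of the forward model used by [simulateSubject()]: two tagged
#' SSVEP components with occipitally weighted topographies, category-specific
#' distractor patterns, delta-band amplitude modulation with a controlled
#' target-distractor relative phase, 1/f noise at a controlled SNR, and a
#' behavioral-accuracy model linear in the relative phase.
#'
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels (10-20 names).
#' @slot fSamp injected sampling-rhythm (envelope) frequency, Hz.
#' @slot modDepth amplitude-modulation depth m in [0, 1].
#' @slot relPhase injected target-distractor envelope phase offset, rad in [0, pi].
#' @slot targetAmp,distractorAmp carrier amplitudes (uV) of the tagged components.
#' @slot targetTopography,distractorTopography per-channel gain vectors.
#' @slot patternSeparability scale of the category-specific pattern
#'   perturbations (unit-norm random vectors times this factor).
#' @slot snr ratio of tagged-signal RMS to noise RMS at the best channel;
#'   `Inf` for noiseless data.
#' @slot noiseExponent 1/f^alpha spectral slope of the noise.
#' @slot flickerMode `"sine"` (fundamental only) or `"square"` (on/off,
#'   adds harmonics).
#' @slot behaviorBase,behaviorGain,behaviorNoiseSd accuracy model:
#'   clip(base + gain * relPhase/pi + N(0, sd), 0, 1).
#' @slot seed integer RNG seed; generation is a pure function of it.
#' @seealso [synthConfig()], [simulateSubject()], [simulateCohort()]
#' @export
setClass("SynthConfig", representation(
  fs = "numeric",
  channels = "character",
  fSamp = "numeric",
  modDepth = "numeric",
  relPhase = "numeric",
  targetAmp = "numeric",
  distractorAmp = "numeric",
  targetTopography = "numeric",
  distractorTopography = "numeric",
  patternSeparability = "numeric",
  snr = "numeric",
  noiseExponent = "numeric",
  flickerMode = "character",
  behaviorBase = "numeric",
  behaviorGain = "numeric",
  behaviorNoiseSd = "numeric",
  seed = "integer"
))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@fs <= 12) msg <- c(msg, "fs must exceed twice the distractor tag frequency")
  if (object@modDepth < 0 || object@modDepth > 1) msg <- c(msg, "modDepth must be in [0, 1]")
  if (object@relPhase < 0 || object@relPhase > pi + 1e-12)
    msg <- c(msg, "relPhase must be in [0, pi]")
  if (is.na(object@snr) || object@snr <= 0) msg <- c(msg, "snr must be > 0 (Inf for noiseless)")
  bad <- c(object@fSamp, object@modDepth, object@relPhase, object@targetAmp,
           object@distractorAmp, object@targetTopography,
           object@distractorTopography, object@patternSeparability,
           object@noiseExponent, object@behaviorBase, object@behaviorGain,
           object@behaviorNoiseSd)
  if (any(!is.finite(bad))) msg <- c(msg, "non-finite generator parameter")
  if (length(object@targetTopography) != length(object@channels) ||
      length(object@distractorTopography) != length(object@channels))
    msg <- c(msg, "topographies must have one gain per channel")
  if (!object@flickerMode %in% c("sine", "square"))
    msg <- c(msg, "flickerMode must be 'sine' or 'square'")
  if (length(msg)) msg else TRUE
})

#' Epoch-format EEG dataset
#'
#' The central data container: a trials x channels x samples array with
#' per-trial emotion-category labels, sampling rate, channel names, the
#' subject's behavioral accuracy, and (for synthetic data) the generation
#' ground truth.
#'
#' @slot data numeric array, trials x channels x samples (uV).
#' @slot labels factor of category labels, one per trial.
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels.
#' @slot behavior list(overall = fraction, perCategory = named vector).
#' @slot groundTruth list of injected parameters, or empty for real data.
#' @slot subjectId identifier string.
#' @export
setClass("EEGDataset", representation(
  data = "array",
  labels = "factor",
  fs = "numeric",
  channels = "character",
  behavior = "list",
  groundTruth = "list",
  subjectId = "character"
))

setValidity("EEGDataset", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3D array (trials x channels x samples)")
  else {
    if (d[1] != length(object@labels)) msg <- c(msg, "one label per trial required")
    if (d[2] != length(object@channels)) msg <- c(msg, "one channel name per channel required")
  }
  if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SSVEP containers
## ---------------------------------------------------------------------------

#' Condition-averaged SSVEP waveform
#'
#' Pointwise trial average (channels x samples) for one emotion category or
#' for all trials.
#'
#' @slot values channels x samples matrix (uV).
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels.
#' @slot nTrialsAveraged number of trials in the average.
#' @slot category category label or "all".
#' @export
setClass("SSVEPWaveform", representation(
  values = "matrix", fs = "numeric", channels = "character",
  nTrialsAveraged = "integer", category = "character"
))

setValidity("SSVEPWaveform", function(object) {
  msg <- character()
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (nrow(object@values) != length(object@channels))
    msg <- c(msg, "one channel label per row required")
  if (length(msg)) msg else TRUE
})

#' Narrowband (tag-specific) signal
#'
#' Zero-phase band-pass filtered SSVEP, center +/- halfWidth Hz, isolating
#' the response to one flicker stream.
#'
#' @slot values channels x samples matrix.
#' @slot fs sampling rate, Hz.
#' @slot channels channel labels.
#' @slot center band center, Hz.
#' @slot halfWidth band half width, Hz (default 0.5).
#' @slot analysisInterval default scoring interval, s.
#' @export
setClass("NarrowbandSignal", representation(
  values = "matrix", fs = "numeric", channels = "character",
  center = "numeric", halfWidth = "numeric", analysisInterval = "numeric"
))

setValidity("NarrowbandSignal", function(object) {
  msg <- character()
  lo <- object@center - object@halfWidth
  hi <- object@center + object@halfWidth
  if (!(lo > 0 && hi < object@fs / 2))
    msg <- c(msg, "band [center - halfWidth, center + halfWidth] must lie strictly inside (0, fs/2)")
  if (length(msg)) msg else TRUE
})

#' Amplitude spectrum
#'
#' One-sided amplitude spectrum of a waveform segment or envelope series,
#' scaled so a unit sinusoid has amplitude 1.
#'
#' @slot freqs frequencies, Hz, strictly increasing from 0.
#' @slot amplitudes non-negative amplitudes (uV, or accuracy units for
#'   decoding-series spectra).
#' @slot resolution frequency spacing after zero padding, Hz.
#' @export
setClass("AmplitudeSpectrum", representation(
  freqs = "numeric", amplitudes = "numeric", resolution = "numeric"
))

setValidity("AmplitudeSpectrum", function(object) {
  msg <- character()
  if (length(object@freqs) != length(object@amplitudes))
    msg <- c(msg, "freqs and amplitudes must have equal length")
  if (object@freqs[1] != 0 || is.unsorted(object@freqs, strictly = TRUE))
    msg <- c(msg, "freqs must be strictly increasing, starting at 0")
  if (any(object@amplitudes < 0)) msg <- c(msg, "amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Envelope / windowing
## ---------------------------------------------------------------------------

#' Moving-window specification
#'
#' @slot length window duration, s (default 0.5).
#' @slot step window step, s (default 0.25).
#' @slot interval analysis interval, s (default c(2, 11)).
#' @seealso [windowSpec()], [windowedAmplitude()], [windowedDecoding()]
#' @export
setClass("WindowSpec", representation(
  length = "numeric", step = "numeric", interval = "numeric"
))

setValidity("WindowSpec", function(object) {
  msg <- character()
  span <- diff(object@interval)
  if (!(object@length > 0 && object@length <= span))
    msg <- c(msg, "0 < length <= interval span required")
  if (!(object@step > 0 && object@step <= object@length))
    msg <- c(msg, "0 < step <= length required")
  if (length(msg)) msg else TRUE
})

#' Envelope (or decoding-accuracy) time series
#'
#' Uniformly sampled slow time course whose spectrum and phase are analyzed:
#' moving-window or Hilbert amplitude of a narrowband signal, or a
#' moving-window decoding-accuracy series.
#'
#' @slot times time stamps, s (window centers or sample times), uniform.
#' @slot values amplitudes (uV) or accuracies (fraction).
#' @slot rate sampling rate of the series, Hz (1/step windowed, fs Hilbert).
#' @slot source one of "target_amplitude", "distractor_amplitude",
#'   "distractor_decoding".
#' @export
setClass("EnvelopeSeries", representation(
  times = "numeric", values = "numeric", rate = "numeric", source = "character"
))

setValidity("EnvelopeSeries", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1) {
    d <- diff(object@times)
    if (any(d <= 0)) msg <- c(msg, "times must be strictly increasing")
    else if (max(d) - min(d) > 1e-6) msg <- c(msg, "times must be uniformly spaced")
  }
  if (!all(is.finite(object@values))) msg <- c(msg, "values must be finite")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Decoding
## ---------------------------------------------------------------------------

#' Decoding analysis specification
#'
#' Subset-averaged ("ERP") decoding: per iteration, trials of each category
#' are randomly split into `nSubsets` near-equal subsets, each subset is
#' trial-averaged, features are per-channel sqrt(2) x RMS amplitudes of the
#' 6 +/- 0.5 Hz narrowband subset SSVEP, and a linear SVM is trained on
#' `nSubsets - 1` subsets and tested on the held-out one.
#'
#' @slot nSubsets subsets per category (default 3).
#' @slot nIterations random re-partitions averaged over (default 100).
#' @slot cost linear-SVM cost parameter C (default 1).
#' @slot standardize standardize features with training-fold statistics.
#' @slot rotateFolds evaluate all leave-one-subset-out folds per iteration
#'   (default) or only a single random fold.
#' @slot center,halfWidth feature band, Hz (default 6 +/- 0.5).
#' @slot interval whole-trial scoring interval, s.
#' @slot seed integer RNG seed for the partitions.
#' @export
setClass("DecodingSpec", representation(
  nSubsets = "integer", nIterations = "integer", cost = "numeric",
  standardize = "logical", rotateFolds = "logical",
  center = "numeric", halfWidth = "numeric", interval = "numeric",
  seed = "integer"
))

setValidity("DecodingSpec", function(object) {
  msg <- character()
  if (object@nSubsets < 3L) msg <- c(msg, "nSubsets must be >= 3")
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
  if (length(msg)) msg else TRUE
})

#' Decoding result
#'
#' @slot accuracy mean accuracy over iterations, fraction.
#' @slot chance theoretical chance level (0.5 pairwise, 1/3 three-way).
#' @slot perIteration accuracy per iteration.
#' @slot mode "pairwise" or "threeway".
#' @slot level "whole_trial" or "windowed".
#' @slot classes the category labels involved.
#' @export
setClass("DecodingResult", representation(
  accuracy = "numeric", chance = "numeric", perIteration = "numeric",
  mode = "character", level = "character", classes = "character"
))

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1) msg <- c(msg, "accuracy must be in [0, 1]")
  if (length(object@perIteration) &&
      abs(object@accuracy - mean(object@perIteration)) > 1e-8)
    msg <- c(msg, "accuracy must equal mean(perIteration)")
  if (length(msg)) msg else TRUE
})

#' Moving-window decoding-accuracy series
#'
#' An [EnvelopeSeries-class] of three-way decoding accuracies with its chance
#' level attached.
#'
#' @slot chance theoretical chance level.
#' @export
setClass("DecodingSeries", contains = "EnvelopeSeries",
         representation(chance = "numeric"))

setValidity("DecodingSeries", function(object) {
  if (any(object@values < 0 | object@values > 1))
    "decoding accuracies must be in [0, 1]" else TRUE
})

## ---------------------------------------------------------------------------
## Phase / group level
## ---------------------------------------------------------------------------

#' Target-distractor phase comparison
#'
#' Relative phase between the target-amplitude and distractor-decoding time
#' series, evaluated at a single frequency near the shared sampling rhythm.
#'
#' @slot fUsed evaluation frequency, Hz.
#' @slot phiTarget,phiDistractor series phases, rad in (-pi, pi].
#' @slot relPhase folded absolute phase difference, rad in [0, pi].
#' @slot peakTarget,peakDistractor series spectral peak frequencies, Hz.
#' @export
setClass("PhaseComparison", representation(
  fUsed = "numeric", phiTarget = "numeric", phiDistractor = "numeric",
  relPhase = "numeric", peakTarget = "numeric", peakDistractor = "numeric"
))

setValidity("PhaseComparison", function(object) {
  if (object@relPhase < -1e-12 || object@relPhase > pi + 1e-12)
    "relPhase must lie in [0, pi]" else TRUE
})

#' Cohort-level analysis result
#'
#' @slot nSubjects number of subjects.
#' @slot summaries per-subject summary rows (see [summarizeSubject()]).
#' @slot meanRelPhase,sdRelPhase relative-phase mean and sd, rad.
#' @slot ksStatistic,ksP K-S uniformity test of the phase distribution.
#' @slot phaseBehaviorR,phaseBehaviorP Pearson correlation of phase with accuracy.
#' @slot decodingVsChance list of one-sample t results per decoding mode.
#' @slot amplitudeComparison paired t of target vs distractor amplitude.
#' @slot behaviorAnova one-way ANOVA of behavior across categories.
#' @export
setClass("GroupResult", representation(
  nSubjects = "integer", summaries = "data.frame",
  meanRelPhase = "numeric", sdRelPhase = "numeric",
  ksStatistic = "numeric", ksP = "numeric",
  phaseBehaviorR = "numeric", phaseBehaviorP = "numeric",
  decodingVsChance = "list", amplitudeComparison = "list",
  behaviorAnova = "list"
))

setValidity("GroupResult", function(object) {
  msg <- character()
  if (!is.na(object@phaseBehaviorR) && abs(object@phaseBehaviorR) > 1)
    msg <- c(msg, "|r| must be <= 1")
  ps <- c(object@ksP, object@phaseBehaviorP)
  if (any(!is.na(ps) & (ps < 0 | ps > 1))) msg <- c(msg, "p-values must be in [0, 1]")
  if (object@ksStatistic < 0 || object@ksStatistic > 1)
    msg <- c(msg, "ksStatistic must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Full pipeline configuration
#'
#' @slot paradigm a [ParadigmConfig-class].
#' @slot synth a [SynthConfig-class] template.
#' @slot windows a [WindowSpec-class].
#' @slot decoding a [DecodingSpec-class] for whole-trial decoding.
#' @slot windowedIterations iterations for moving-window decoding (smaller
#'   than whole-trial by default purely for speed).
#' @slot nSubjects cohort size (default 27).
#' @slot seed master seed.
#' @export
setClass("RunConfig", representation(
  paradigm = "ParadigmConfig", synth = "SynthConfig",
  windows = "WindowSpec", decoding = "DecodingSpec",
  windowedIterations = "integer", nSubjects = "integer", seed = "integer"
))

setValidity("RunConfig", function(object) {
  if (object@nSubjects < 2L) "nSubjects must be >= 2" else TRUE
})
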