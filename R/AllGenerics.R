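#' @include AllGenerics.R
NULL

#' Sampling rate accessor
#'
#' Returns the sampling rate in Hz of an EEG container (epochs, averaged
#' waveforms, narrowband signals).
#'
#' @param object an object with a sampling rate.
#' @return Sampling rate in Hz (numeric scalar).
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Channel label accessor
#'
#' @param object an object carrying channel labels (10-20 names).
#' @return Character vector of channel labels.
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' Per-trial category labels
#'
#' @param object an [EEGDataset-class].
#' @return Factor of emotion-category labels, one per trial.
#' @export
setGeneric("trialLabels", function(object) standardGeneric("trialLabels"))

#' Number of trials
#'
#' @param object an [EEGDataset-class].
#' @return Integer trial count.
#' @export
setGeneric("nTrials", function(object) standardGeneric("nTrials"))

#' Simulation ground truth
#'
#' For synthetic datasets, the injected parameters (sampling-rhythm frequency,
#' relative phase, category patterns, behavior) recorded at generation time.
#'
#' @param object an [EEGDataset-class].
#' @return A list of ground-truth values, or `NULL` for real data.
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' Behavioral accuracy accessor
#'
#' @param object an [EEGDataset-class].
#' @return List with elements `overall` (fraction correct) and `perCategory`
#'   (named numeric vector).
#' @export
setGeneric("behaviorAccuracy", function(object) standardGeneric("behaviorAccuracy"))

#' Series / waveform values
#'
#' @param object an [EnvelopeSeries-class], [SSVEPWaveform-class] or
#'   [NarrowbandSignal-class].
#' @return Numeric vector (series) or channels-by-samples matrix (waveforms).
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))

#' Series time stamps
#'
#' @param object an [EnvelopeSeries-class].
#' @return Numeric vector of times in seconds (window centers or sample times).
#' @export
setGeneric("seriesTimes", function(object) standardGeneric("seriesTimes"))

#' Spectrum frequency axis
#'
#' @param object an [AmplitudeSpectrum-class].
#' @return Numeric vector of frequencies in Hz, starting at 0.
#' @export
setGeneric("specFreqs", function(object) standardGeneric("specFreqs"))

#' Spectrum amplitudes
#'
#' @param object an [AmplitudeSpectrum-class].
#' @return Numeric vector of non-negative amplitudes.
#' @export
setGeneric("specAmplitudes", function(object) standardGeneric("specAmplitudes"))

#' Decoding accuracy accessor
#'
#' @param object a [DecodingResult-class].
#' @return Mean decoding accuracy as a fraction in [0, 1].
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' Chance level accessor
#'
#' @param object a [DecodingResult-class] or [DecodingSeries-class].
#' @return Theoretical chance accuracy (0.5 pairwise, 1/3 three-way).
#' @export
setGeneric("chanceLevel", function(object) standardGeneric("chanceLevel"))

#' Relative phase accessor
#'
#' @param object a [PhaseComparison-class].
#' @return Folded target-distractor relative phase in radians, in [0, pi].
#' @export
setGeneric("relPhase", function(object) standardGeneric("relPhase"))
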