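## accessors and show methods

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EEGDataset", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "SSVEPWaveform", function(object) object@fs)
#' @rdname samplingRate
#' @export
setMethod("samplingRate", "NarrowbandSignal", function(object) object@fs)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EEGDataset", function(object) object@channels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "SSVEPWaveform", function(object) object@channels)
#' @rdname channelNames
#' @export
setMethod("channelNames", "NarrowbandSignal", function(object) object@channels)

#' @rdname trialLabels
#' @export
setMethod("trialLabels", "EEGDataset", function(object) object@labels)

#' @rdname nTrials
#' @export
setMethod("nTrials", "EEGDataset", function(object) dim(object@data)[1])

#' @rdname groundTruth
#' @export
setMethod("groundTruth", "EEGDataset", function(object)
  if (length(object@groundTruth)) object@groundTruth else NULL)

#' @rdname behaviorAccuracy
#' @export
setMethod("behaviorAccuracy", "EEGDataset", function(object) object@behavior)

#' @rdname seriesValues
#' @export
setMethod("seriesValues", "EnvelopeSeries", function(object) object@values)
#' @rdname seriesValues
#' @export
setMethod("seriesValues", "SSVEPWaveform", function(object) object@values)
#' @rdname seriesValues
#' @export
setMethod("seriesValues", "NarrowbandSignal", function(object) object@values)

#' @rdname seriesTimes
#' @export
setMethod("seriesTimes", "EnvelopeSeries", function(object) object@times)

#' @rdname specFreqs
#' @export
setMethod("specFreqs", "AmplitudeSpectrum", function(object) object@freqs)

#' @rdname specAmplitudes
#' @export
setMethod("specAmplitudes", "AmplitudeSpectrum", function(object) object@amplitudes)

#' @rdname accuracy
#' @export
setMethod("accuracy", "DecodingResult", function(object) object@accuracy)

#' @rdname chanceLevel
#' @export
setMethod("chanceLevel", "DecodingResult", function(object) object@chance)
#' @rdname chanceLevel
#' @export
setMethod("chanceLevel", "DecodingSeries", function(object) object@chance)

#' @rdname relPhase
#' @export
setMethod("relPhase", "PhaseComparison", function(object) object@relPhase)

setMethod("show", "ParadigmConfig", function(object) {
  cat(sprintf(
    "ParadigmConfig: %.0f Hz refresh | target %.4f Hz (%d+%d frames) | distractor %.4f Hz (%d+%d frames)\n",
    object@refreshRate, tagFrequency(object, "target"),
    object@targetOnFrames, object@targetOffFrames,
    tagFrequency(object, "distractor"),
    object@distractorOnFrames, object@distractorOffFrames))
  cat(sprintf("  trial %.3f s | %d trials x %d categories (%s)\n",
              object@trialDuration, object@nTrialsPerCategory,
              length(object@categories),
              paste(object@categories, collapse = ", ")))
})

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf("StimulusSchedule: %d target cycles, %d distractor cycles, %d motion event(s)\n",
              object@nTargetCycles, object@nDistractorCycles,
              nrow(object@motionEvents)))
})

setMethod("show", "EEGDataset", function(object) {
  d <- dim(object@data)
  cat(sprintf("EEGDataset '%s': %d trials x %d channels x %d samples @ %g Hz\n",
              object@subjectId, d[1], d[2], d[3], object@fs))
  cat("  labels:", paste(sprintf("%s=%d", levels(object@labels),
                                 table(object@labels)), collapse = " "), "\n")
  if (length(object@groundTruth))
    cat(sprintf("  synthetic (fSamp=%.2f Hz, relPhase=%.2fpi, snr=%.3g)\n",
                object@groundTruth$fSamp, object@groundTruth$relPhase / pi,
                object@groundTruth$snr))
})

setMethod("show", "SSVEPWaveform", function(object) {
  cat(sprintf("SSVEPWaveform (%s): %d channels x %d samples @ %g Hz, %d trials averaged\n",
              object@category, nrow(object@values), ncol(object@values),
              object@fs, object@nTrialsAveraged))
})

setMethod("show", "NarrowbandSignal", function(object) {
  cat(sprintf("NarrowbandSignal: %.4f +/- %.2f Hz, %d channels x %d samples @ %g Hz\n",
              object@center, object@halfWidth, nrow(object@values),
              ncol(object@values), object@fs))
})

setMethod("show", "AmplitudeSpectrum", function(object) {
  cat(sprintf("AmplitudeSpectrum: %d bins, 0-%.4g Hz, resolution %.4g Hz\n",
              length(object@freqs), max(object@freqs), object@resolution))
})

setMethod("show", "EnvelopeSeries", function(object) {
  cat(sprintf("EnvelopeSeries [%s]: %d points @ %g Hz, t = %.3f-%.3f s\n",
              object@source, length(object@values), object@rate,
              min(object@times), max(object@times)))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult (%s, %s): accuracy %.2f%% (chance %.2f%%), %d iterations\n",
              object@mode, object@level, 100 * object@accuracy,
              100 * object@chance, length(object@perIteration)))
})

setMethod("show", "PhaseComparison", function(object) {
  cat(sprintf("PhaseComparison @ %.3f Hz: relative phase %.3fpi (peaks %.3f / %.3f Hz)\n",
              object@fUsed, object@relPhase / pi, object@peakTarget,
              object@peakDistractor))
})

setMethod("show", "GroupResult", function(object) {
  cat(sprintf("GroupResult: n = %d subjects\n", object@nSubjects))
  cat(sprintf("  mean relative phase %.2fpi +/- %.2fpi | K-S D = %.3f (p = %.3f)\n",
              object@meanRelPhase / pi, object@sdRelPhase / pi,
              object@ksStatistic, object@ksP))
  cat(sprintf("  phase-behavior r = %.4f (p = %.4g)\n",
              object@phaseBehaviorR, object@phaseBehaviorP))
  dv <- object@decodingVsChance$threeway
  cat(sprintf("  three-way decoding %.1f%% vs chance 33.3%%: t(%d) = %.2f, p = %.3g\n",
              100 * dv$mean, dv$df, dv$t, dv$p))
})
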