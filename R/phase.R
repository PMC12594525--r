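## relative phase between target- and distractor-processing time series

#' Relative phase between two processing time series
#'
#' Both series are mean- and trend-removed; their phases are read from the
#' discrete Fourier transform at the (unpadded) bin nearest `fEval`, and the
#' relative phase is the folded absolute difference in [0, pi] (0 = in
#' phase, pi = antiphase sampling). With `fEval = "auto"` the evaluation
#' frequency is the mean of the two series' spectral peak frequencies,
#' required to agree within 2 raw bins — the guard prevents comparing phases
#' at unrelated frequencies.
#'
#' @param targetSeries an [EnvelopeSeries-class] (target amplitude).
#' @param distractorSeries an [EnvelopeSeries-class] or
#'   [DecodingSeries-class] (distractor decoding accuracy) on the same time
#'   grid.
#' @param fEval evaluation frequency in Hz, or `"auto"`.
#' @param searchBand peak-search band passed to [peakFrequency()].
#' @param neighborhood half-width in bins for the cross-spectrum estimator
#'   (0 = single-bin, the default; 1 averages the cross-spectrum over a
#'   3-bin neighborhood for robustness).
#' @return A [PhaseComparison-class].
#' @export
relativePhase <- function(targetSeries, distractorSeries, fEval = "auto",
                          searchBand = c(0.25, 3.0), neighborhood = 0L) {
  stopifnot(is(targetSeries, "EnvelopeSeries"),
            is(distractorSeries, "EnvelopeSeries"))
  if (length(targetSeries@times) != length(distractorSeries@times) ||
      max(abs(targetSeries@times - distractorSeries@times)) > 1e-9)
    stop("series must share the same time axis (same WindowSpec)")
  n <- length(targetSeries@values)
  if (n < 8) stop("need >= 8 samples")
  rate <- targetSeries@rate
  binWidth <- rate / n
  pT <- peakFrequency(envelopeSpectrum(targetSeries), searchBand)
  pD <- peakFrequency(envelopeSpectrum(distractorSeries), searchBand)
  if (identical(fEval, "auto")) {
    if (abs(pT - pD) > 2 * binWidth)
      stop(sprintf(
        "series peak frequencies disagree by more than 2 bins (%.3f vs %.3f Hz, bin %.3f Hz); pass an explicit fEval",
        pT, pD, binWidth))
    fEval <- (pT + pD) / 2
  }
  xT <- stats::fft(detrendSeries(targetSeries@values))
  xD <- stats::fft(detrendSeries(distractorSeries@values))
  k <- round(fEval / binWidth)          # 0-based bin index
  k <- min(max(k, 1L), floor(n / 2))
  if (neighborhood > 0L) {
    ks <- (k - neighborhood):(k + neighborhood)
    ks <- ks[ks >= 1 & ks <= floor(n / 2)]
    cross <- sum(xT[ks + 1] * Conj(xD[ks + 1]))
    phiT <- Arg(xT[k + 1]); phiD <- Arg(xD[k + 1])
    d <- Arg(cross)
  } else {
    phiT <- Arg(xT[k + 1]); phiD <- Arg(xD[k + 1])
    d <- phiT - phiD
  }
  rel <- abs(atan2(sin(d), cos(d)))     # wrap to (-pi, pi], fold to [0, pi]
  new("PhaseComparison", fUsed = k * binWidth, phiTarget = phiT,
      phiDistractor = phiD, relPhase = rel, peakTarget = pT,
      peakDistractor = pD)
}

#' Z-score a time series for display
#'
#' @param series an [EnvelopeSeries-class] with nonzero variance.
#' @return The series standardized to mean 0, sd 1 (times unchanged), as a
#'   plain [EnvelopeSeries-class].
#' @export
zscoreSeries <- function(series) {
  stopifnot(is(series, "EnvelopeSeries"))
  s <- stats::sd(series@values)
  if (!is.finite(s) || s == 0) stop("cannot z-score a constant series")
  new("EnvelopeSeries", times = series@times,
      values = (series@values - mean(series@values)) / s,
      rate = series@rate, source = series@source)
}

#' Per-subject analysis summary
#'
#' Runs the full per-subject chain — trial averaging, narrowband isolation
#' at both tag frequencies, whole-trial amplitudes, moving-window target
#' amplitude and three-way decoding series, envelope spectra and peak
#' frequencies, relative phase — and assembles one summary row.
#'
#' @param dataset an [EEGDataset-class].
#' @param paradigm the [ParadigmConfig-class] that produced it.
#' @param windows a [WindowSpec-class].
#' @param decoding a [DecodingSpec-class] for whole-trial decoding.
#' @param windowedIterations iterations for the moving-window decoder.
#' @param distractorSeries distractor-processing time series used for the
#'   phase comparison: `"decoding"` (moving-window three-way accuracy, the
#'   primary definition) or `"amplitude"` (moving-window 6 Hz amplitude, a
#'   diagnostic mode; decoding accuracy saturates at 1 on noiseless input
#'   and then carries no rhythm, so closed-form end-to-end checks use this).
#' @param fEval passed to [relativePhase()]. With the default `"auto"`, a
#'   subject whose two peak frequencies disagree beyond the guard is
#'   evaluated at the target-series peak instead of aborting the cohort.
#' @return One-row data.frame: subject, relPhase (rad), peakTarget,
#'   peakDistractor (Hz), behavior, ampTarget, ampDistractor (uV), acc3way.
#' @export
summarizeSubject <- function(dataset, paradigm = paradigmConfig(),
                             windows = windowSpec(),
                             decoding = decodingSpec(),
                             windowedIterations = 10L,
                             distractorSeries = c("decoding", "amplitude"),
                             fEval = "auto") {
  distractorSeries <- match.arg(distractorSeries)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  fT <- tagFrequency(paradigm, "target")
  fD <- tagFrequency(paradigm, "distractor")
  avg <- stage("average", averageTrials(dataset, "all"))
  nbT <- stage("narrowband", narrowband(avg, fT, analysisInterval = windows@interval))
  nbD <- stage("narrowband", narrowband(avg, fD, analysisInterval = windows@interval))
  ampT <- stage("amplitude", wholeTrialAmplitude(nbT))
  ampD <- stage("amplitude", wholeTrialAmplitude(nbD))
  envT <- stage("envelope", windowedAmplitude(nbT, windows))
  acc <- stage("decoding", decodeThreeway(dataset, decoding))
  wspec <- decoding
  wspec@nIterations <- as.integer(windowedIterations)
  envD <- if (distractorSeries == "decoding")
    stage("decoding", windowedDecoding(dataset, wspec, windows))
  else
    stage("envelope", windowedAmplitude(nbD, windows,
                                        source = "distractor_amplitude"))
  ph <- stage("phase", {
    if (identical(fEval, "auto"))
      tryCatch(relativePhase(envT, envD, "auto"),
               error = function(e)
                 relativePhase(envT, envD,
                               peakFrequency(envelopeSpectrum(envT))))
    else relativePhase(envT, envD, fEval)
  })
  data.frame(subject = dataset@subjectId,
             relPhase = ph@relPhase,
             peakTarget = ph@peakTarget,
             peakDistractor = ph@peakDistractor,
             behavior = dataset@behavior$overall,
             ampTarget = ampT$mean,
             ampDistractor = ampD$mean,
             acc3way = acc@accuracy,
             stringsAsFactors = FALSE)
}
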