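## condition-averaged SSVEP, narrowband isolation, amplitudes, spectra

#' Condition-averaged SSVEP
#'
#' Pointwise mean across trials of one emotion category (or all trials).
#' Trial averaging cancels non-phase-locked noise by 1/sqrt(n) and leaves
#' the steady-state response locked to the flicker.
#'
#' @param dataset an [EEGDataset-class].
#' @param category a category label or `"all"`.
#' @return An [SSVEPWaveform-class].
#' @export
averageTrials <- function(dataset, category = "all") {
  validObject(dataset)
  idx <- if (identical(category, "all")) seq_len(nTrials(dataset))
         else which(dataset@labels == category)
  if (!length(idx))
    stop(sprintf("no trials with category '%s'", category))
  m <- colMeans(dataset@data[idx, , , drop = FALSE], dims = 1)
  new("SSVEPWaveform", values = m, fs = dataset@fs,
      channels = dataset@channels,
      nTrialsAveraged = length(idx), category = as.character(category))
}

#' Narrowband isolation of a tagged component
#'
#' Zero-phase band-pass filtering of the SSVEP to center +/- halfWidth Hz,
#' isolating the response to one flicker stream. The filter has a flat
#' passband, a raised-cosine transition of `transWidth` Hz, zero response
#' beyond, and exactly zero group delay (it is applied in the frequency
#' domain with reflection padding). Attenuation at center +/- 3 halfWidth is
#' total; the paper's target/distractor bands (4.2857 and 6 Hz, +/- 0.5 Hz)
#' do not overlap each other's passbands.
#'
#' @param waveform an [SSVEPWaveform-class] (or [EEGDataset-class]; then
#'   trials are filtered individually and returned as an array).
#' @param center band center, Hz.
#' @param halfWidth band half width, Hz.
#' @param analysisInterval default scoring interval, s.
#' @return A [NarrowbandSignal-class].
#' @export
narrowband <- function(waveform, center, halfWidth = 0.5,
                       analysisInterval = c(2, 11)) {
  stopifnot(is(waveform, "SSVEPWaveform"))
  if (!(center - halfWidth > 0 && center + halfWidth < waveform@fs / 2))
    stop("band [center - halfWidth, center + halfWidth] must lie inside (0, fs/2)")
  y <- t(nbFilterMatrix(t(waveform@values), waveform@fs, center, halfWidth))
  new("NarrowbandSignal", values = y, fs = waveform@fs,
      channels = waveform@channels, center = center, halfWidth = halfWidth,
      analysisInterval = analysisInterval)
}

#' Whole-trial narrowband amplitude
#'
#' Per-channel amplitude = sqrt(2) x RMS of the narrowband signal over the
#' analysis interval (equals the peak amplitude of a pure sinusoid; grid-free,
#' unlike an FFT bin, which matters because 60/14 Hz is not on the FFT grid
#' of a 9 s segment). Also reports the all-channel mean used for the
#' target-vs-distractor comparison and the per-channel vector for topography.
#'
#' @param nb a [NarrowbandSignal-class].
#' @param interval scoring interval, s (default the signal's
#'   `analysisInterval`).
#' @return List with `perChannel` (named numeric) and `mean` (scalar, uV).
#' @export
wholeTrialAmplitude <- function(nb, interval = nb@analysisInterval) {
  stopifnot(is(nb, "NarrowbandSignal"))
  nS <- ncol(nb@values)
  if (diff(interval) < 2 / nb@center)
    stop("interval must cover at least 2 cycles of the band center")
  rg <- sampleRange(interval[1], diff(interval), nb@fs, nS)
  seg <- nb@values[, rg[1]:rg[2], drop = FALSE]
  perChannel <- sqrt(2 * rowMeans(seg^2))
  names(perChannel) <- nb@channels
  list(perChannel = perChannel, mean = mean(perChannel))
}

#' Amplitude spectrum of an averaged waveform
#'
#' One-sided amplitude spectrum of the mean-removed segment at one channel,
#' zero padded to at least 4x the segment length for display resolution.
#' Used for spectral peak display (the tagged peaks at 4.29 and 6 Hz);
#' amplitude scoring uses [wholeTrialAmplitude()].
#'
#' @param waveform an [SSVEPWaveform-class].
#' @param channel channel label (default "Oz" if present, else channel 1).
#' @param interval analysis interval, s.
#' @return An [AmplitudeSpectrum-class].
#' @export
ssvepSpectrum <- function(waveform, channel = NULL, interval = c(2, 11)) {
  stopifnot(is(waveform, "SSVEPWaveform"))
  if (is.null(channel))
    channel <- if ("Oz" %in% waveform@channels) "Oz" else waveform@channels[1]
  ch <- match(channel, waveform@channels)
  if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel))
  nS <- ncol(waveform@values)
  rg <- sampleRange(interval[1], diff(interval), waveform@fs, nS)
  v <- waveform@values[ch, rg[1]:rg[2]]
  amplitudeSpectrumCore(v - mean(v), waveform@fs, padMin = 4L * length(v))
}

#' Paired comparison of target and distractor amplitudes
#'
#' Paired two-sided t-test of per-subject whole-trial target amplitudes
#' against distractor amplitudes (all-channel means). Degenerate inputs with
#' zero-variance differences are reported with `degenerate = TRUE` and a
#' limiting p-value (0 for a nonzero constant difference, 1 for identity).
#'
#' @param target,distractor equal-length paired numeric vectors, n >= 3.
#' @return List with `t`, `df`, `p`, `meanDifference`, `direction`,
#'   `degenerate`.
#' @export
compareAmplitudes <- function(target, distractor) {
  n <- length(target)
  if (n != length(distractor)) stop("paired samples must have equal length")
  if (n < 3) stop("need n >= 3 pairs")
  d <- target - distractor
  direction <- if (mean(d) > 0) "target > distractor"
               else if (mean(d) < 0) "target < distractor" else "none"
  if (stats::sd(d) < 1e-12) {
    return(list(t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                df = n - 1, p = if (mean(d) == 0) 1 else 0,
                meanDifference = mean(d), direction = direction,
                degenerate = TRUE))
  }
  ht <- stats::t.test(target, distractor, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, meanDifference = mean(d), direction = direction,
       degenerate = FALSE)
}
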