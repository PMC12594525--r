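## amplitude-envelope time series and their spectra

#' Moving-window specification
#'
#' @param length window duration, s.
#' @param step window step, s.
#' @param interval analysis interval, s.
#' @return A validated [WindowSpec-class]. The defaults (0.5 s windows,
#'   0.25 s steps over [2, 11] s) give 35 windows at an effective series
#'   rate of 4 Hz.
#' @export
windowSpec <- function(length = 0.5, step = 0.25, interval = c(2, 11)) {
  new("WindowSpec", length = length, step = step, interval = interval)
}

#' Moving-window amplitude time series
#'
#' One value per window: sqrt(2) x RMS of the channel-reduced narrowband
#' signal within the window. Times are window centers; the series rate is
#' 1/step. Channel reduction defaults to the mean over all channels
#' (matching whole-trial scoring across all electrodes); a single-channel
#' mode exists for diagnostics.
#'
#' @param nb a [NarrowbandSignal-class].
#' @param spec a [WindowSpec-class].
#' @param channelReduce `"mean_over_channels"` or `"single_channel"`.
#' @param channel channel label when `channelReduce = "single_channel"`.
#' @param source series source tag.
#' @return An [EnvelopeSeries-class].
#' @export
windowedAmplitude <- function(nb, spec = windowSpec(),
                              channelReduce = c("mean_over_channels",
                                                "single_channel"),
                              channel = NULL,
                              source = "target_amplitude") {
  stopifnot(is(nb, "NarrowbandSignal"))
  validObject(spec)
  channelReduce <- match.arg(channelReduce)
  v <- if (channelReduce == "mean_over_channels") colMeans(nb@values)
  else {
    ch <- match(channel, nb@channels)
    if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel))
    nb@values[ch, ]
  }
  starts <- windowStarts(spec)
  nS <- length(v)
  vals <- vapply(starts, function(s) {
    rg <- sampleRange(s, spec@length, nb@fs, nS)
    sineAmplitude(v[rg[1]:rg[2]])
  }, numeric(1))
  new("EnvelopeSeries", times = starts + spec@length / 2, values = vals,
      rate = 1 / spec@step, source = source)
}

#' Hilbert (window-free) amplitude envelope
#'
#' Magnitude of the analytic signal of the channel-reduced narrowband
#' signal, computed over the full support and then cropped to `interval` so
#' transform edge effects fall outside the scored segment.
#'
#' @param nb a [NarrowbandSignal-class].
#' @param interval crop interval, s.
#' @param channelReduce,channel as in [windowedAmplitude()].
#' @param source series source tag.
#' @return An [EnvelopeSeries-class] at rate `fs`.
#' @export
hilbertEnvelope <- function(nb, interval = nb@analysisInterval,
                            channelReduce = c("mean_over_channels",
                                              "single_channel"),
                            channel = NULL,
                            source = "target_amplitude") {
  stopifnot(is(nb, "NarrowbandSignal"))
  channelReduce <- match.arg(channelReduce)
  v <- if (channelReduce == "mean_over_channels") colMeans(nb@values)
  else {
    ch <- match(channel, nb@channels)
    if (is.na(ch)) stop(sprintf("unknown channel '%s'", channel))
    nb@values[ch, ]
  }
  if (length(v) < 10 * nb@fs / nb@center)
    stop("signal must span at least 10 cycles of the band center")
  env <- Mod(analyticSignal(v))
  rg <- sampleRange(interval[1], diff(interval), nb@fs, length(v))
  idx <- rg[1]:rg[2]
  t <- (idx - 1) / nb@fs
  new("EnvelopeSeries", times = t, values = env[idx], rate = nb@fs,
      source = source)
}

#' Spectrum of an envelope (or decoding-accuracy) series
#'
#' The series is mean- and linear-trend-removed (discarding the DC carrier
#' amplitude, the "1 +" of the amplitude modulation) and zero padded to at
#' least 512 points before the amplitude spectrum is taken.
#'
#' @param series an [EnvelopeSeries-class] with >= 8 samples.
#' @return An [AmplitudeSpectrum-class]; `@resolution` records the padded
#'   bin width.
#' @export
envelopeSpectrum <- function(series) {
  stopifnot(is(series, "EnvelopeSeries"))
  if (length(series@values) < 8) stop("series too short (need >= 8 samples)")
  v <- detrendSeries(series@values, linear = TRUE)
  amplitudeSpectrumCore(v, series@rate, padMin = 512L)
}

#' Spectral peak frequency
#'
#' Frequency of the global amplitude maximum within `searchBand` (default
#' [0.25, 3] Hz: covers the delta band, excludes DC leakage, and includes
#' the 1.71 Hz two-tone beat so injected modulation can be distinguished
#' from beating). Ties break toward the lower frequency.
#'
#' @param spec an [AmplitudeSpectrum-class].
#' @param searchBand frequency interval, Hz.
#' @return Peak frequency, Hz.
#' @export
peakFrequency <- function(spec, searchBand = c(0.25, 3.0)) {
  stopifnot(is(spec, "AmplitudeSpectrum"))
  sel <- spec@freqs >= searchBand[1] & spec@freqs <= searchBand[2]
  if (!any(sel)) stop("searchBand contains no spectrum bins")
  f <- spec@freqs[sel]
  a <- spec@amplitudes[sel]
  f[which.max(a)]   # first maximum = lowest frequency on ties
}
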