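test_that("moving-window layout: 35 windows at 4 Hz for the default spec", {
  t <- timeAxis()
  env <- windowedAmplitude(asNarrowband(sin(2 * pi * FT * t)), windowSpec())
  expect_length(seriesValues(env), 35L)
  expect_equal(env@rate, 4)
  expect_equal(seriesTimes(env)[1], 2.25)
  expect_equal(diff(seriesTimes(env))[1], 0.25)
  expect_error(windowedAmplitude(asNarrowband(sin(2 * pi * FT * t)),
                                 windowSpec(0.5, 0.5, c(2, 2.6))),
               "fewer than 2 windows")
})

test_that("windowed amplitude matches the brute-force windowed-RMS oracle", {
  t <- timeAxis()
  am <- (1 + 0.5 * cos(2 * pi * 1 * t)) * sin(2 * pi * FT * t)

  # unmodulated unit tone: all values 1 +/- 0.05
  flat <- windowedAmplitude(asNarrowband(sin(2 * pi * FT * t)), windowSpec())
  expect_true(all(abs(seriesValues(flat) - 1) < 0.05))

  # independent oracle: direct loop over window sample ranges
  oracle <- function(sig, len, step, lo, hi) {
    starts <- seq(lo, hi - len + 1e-9, by = step)
    vapply(starts, function(s) {
      i <- (round(s * 500) + 1):(round(s * 500) + round(len * 500))
      sqrt(2 * mean(sig[i]^2))
    }, numeric(1))
  }
  got <- seriesValues(windowedAmplitude(asNarrowband(am), windowSpec()))
  expect_equal(got, oracle(am, 0.5, 0.25, 2, 11), tolerance = 1e-9)

  # with windows short against the modulation period, the max/min ratio
  # approaches the true envelope ratio 1.5/0.5 = 3
  fine <- seriesValues(windowedAmplitude(asNarrowband(am), windowSpec(0.1, 0.05)))
  expect_equal(max(fine) / min(fine), 3, tolerance = 0.1 * 3)
})

test_that("Hilbert envelope: identity, AM tracking, and the 1.71 Hz beat", {
  t <- timeAxis()
  env <- hilbertEnvelope(asNarrowband(sin(2 * pi * FT * t)))
  expect_true(all(abs(seriesValues(env) - 1) < 0.01))

  am <- (1 + 0.5 * cos(2 * pi * 1 * t)) * sin(2 * pi * FT * t)
  envAM <- hilbertEnvelope(asNarrowband(am))
  ref <- 1 + 0.5 * cos(2 * pi * seriesTimes(envAM))
  expect_gt(stats::cor(seriesValues(envAM), ref), 0.99)

  # wideband two-tone input beats at |f1 - f2| = 1.71 Hz
  two <- sin(2 * pi * FT * t) + sin(2 * pi * FD * t)
  sp <- envelopeSpectrum(hilbertEnvelope(asNarrowband(two)))
  expect_equal(peakFrequency(sp), FD - FT, tolerance = 0.02)

  expect_error(hilbertEnvelope(asNarrowband(sin(2 * pi * FT * t[1:500]))),
               "10 cycles")
})

test_that("envelope spectrum: detrending, padding, and resolution", {
  mk <- function(v, rate = 4) new("EnvelopeSeries",
                                  times = seq_along(v) / rate, values = v,
                                  rate = rate, source = "target_amplitude")
  spC <- envelopeSpectrum(mk(rep(2.5, 35)))
  expect_lt(max(specAmplitudes(spC)[specFreqs(spC) > 0]), 1e-10)

  tt <- seq(0.25, by = 0.25, length.out = 36)   # 9 s at 4 Hz
  sp1 <- envelopeSpectrum(mk(cos(2 * pi * 1 * tt)))
  expect_lt(abs(peakFrequency(sp1) - 1.0), sp1@resolution + 1e-9)
  expect_gte(length(specFreqs(sp1)), 256L)       # padded to >= 512 points

  # 35-point moving-window series of the two-tone beat peaks at 1.71 Hz
  t <- timeAxis()
  two <- sin(2 * pi * FT * t) + sin(2 * pi * FD * t)
  beat <- windowedAmplitude(asNarrowband(two), windowSpec())
  expect_equal(peakFrequency(envelopeSpectrum(beat), c(0.25, 1.9)),
               FD - FT, tolerance = 0.06)

  expect_error(envelopeSpectrum(mk(1:5)), ">= 8 samples")
})

test_that("peak frequency: argmax, tie-break toward lower frequency, scale invariance", {
  sp <- new("AmplitudeSpectrum", freqs = seq(0, 2, by = 0.1),
            amplitudes = c(rep(0.1, 21)), resolution = 0.1)
  sp@amplitudes[11] <- 1                          # 1.0 Hz bin
  expect_equal(peakFrequency(sp), 1.0)
  sp@amplitudes[c(10, 13)] <- 2                   # equal maxima at 0.9 and 1.2
  expect_equal(peakFrequency(sp), 0.9, tolerance = 1e-9)
  expect_error(peakFrequency(sp, c(3, 4)), "no spectrum bins")

  mk <- function(v) new("EnvelopeSeries", times = seq_along(v) / 4, values = v,
                        rate = 4, source = "target_amplitude")
  v <- 1 + 0.3 * cos(2 * pi * 1 * seq_len(35) / 4) +
    withr::with_seed(1, stats::rnorm(35, 0, 0.05))
  expect_identical(peakFrequency(envelopeSpectrum(mk(v))),
                   peakFrequency(envelopeSpectrum(mk(7.3 * v))))
})

test_that("windowed, fine-windowed and Hilbert envelopes agree on an AM tone", {
  t <- timeAxis()
  am <- (1 + 0.5 * cos(2 * pi * 1 * t + 0.7)) * sin(2 * pi * FT * t)
  nb <- asNarrowband(am)
  pDefault <- peakFrequency(envelopeSpectrum(windowedAmplitude(nb, windowSpec())))
  pFine <- peakFrequency(envelopeSpectrum(windowedAmplitude(nb, windowSpec(0.1, 0.05))))
  pHilb <- peakFrequency(envelopeSpectrum(hilbertEnvelope(nb)))
  expect_lt(abs(pDefault - 1.0), 4 / 35)
  expect_lt(abs(pFine - pDefault), 4 / 35)   # one raw bin of the default series
  expect_lt(abs(pHilb - pDefault), 4 / 35)
})

test_that("recovered modulation frequency error is non-increasing in SNR", {
  par <- paradigmConfig()
  err <- function(snr, s) {
    d <- simulateSubject(par, synthConfig(seed = s, snr = snr))
    nb <- narrowband(averageTrials(d, "all"), FT)
    abs(peakFrequency(envelopeSpectrum(windowedAmplitude(nb))) - 1.0)
  }
  med <- vapply(c(0.25, 0.5, 1, 2, 4), function(snr)
    stats::median(vapply(401:403, function(s) err(snr, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})
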