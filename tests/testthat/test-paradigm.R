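test_that("default schedule reproduces the printed trial design", {
  cfg <- paradigmConfig()
  expect_equal(tagFrequency(cfg, "target"), 60 / 14)
  expect_equal(tagFrequency(cfg, "distractor"), 6)
  sched <- makeSchedule(cfg, nMotionEvents = 1L, seed = 1)
  expect_identical(sched@nTargetCycles, 50L)
  expect_identical(sched@nDistractorCycles, 70L)
  expect_equal(sched@motionEvents$duration, 4 * 14 / 60, tolerance = 1e-12)  # 933 ms
  # off periods: target 8 frames = 133.33 ms, distractor 4 frames = 66.67 ms
  expect_equal(periodSeconds(cfg, "distractor") - cfg@distractorOnFrames / 60,
               0.06667, tolerance = 1e-3)
  expect_equal(periodSeconds(cfg, "target") - cfg@targetOnFrames / 60,
               0.13333, tolerance = 1e-3)
})

test_that("schedule invariants hold and inconsistent durations are rejected", {
  cfg <- paradigmConfig()
  for (s in 1:5) {
    sched <- makeSchedule(cfg, nMotionEvents = 2L, seed = s)
    expect_true(validObject(sched))
    d <- diff(sched@targetCycleOnsets)
    expect_lt(max(abs(d - periodSeconds(cfg, "target"))), 1e-9)
    ev <- sched@motionEvents
    expect_equal(nrow(ev), 2L)
    # inside the motion window, non-overlapping
    expect_true(all(ev$onset >= cfg@motionWindow[1]))
    expect_true(all(ev$onset + ev$duration <= cfg@motionWindow[2]))
    expect_gte(ev$onset[2], ev$onset[1] + ev$duration[1])
  }
  # 11.0 s is not a common multiple of 14/60 and 10/60 s periods
  expect_error(makeSchedule(paradigmConfig(trialDuration = 11.0)), "implies")
})

test_that("subject generation is a pure function of its seed with balanced labels", {
  par <- quickParadigm()
  d1 <- simulateSubject(par, quickSynth(seed = 5L))
  d2 <- simulateSubject(par, quickSynth(seed = 5L))
  d3 <- simulateSubject(par, quickSynth(seed = 6L))
  expect_identical(d1@data, d2@data)
  expect_identical(d1@labels, d2@labels)
  expect_false(identical(d1@data, d3@data))
  expect_equal(unname(table(trialLabels(d1))), rep(6L, 3), ignore_attr = TRUE)
  # full-size default: 28 per category
  expect_equal(unname(table(trialLabels(refSubject()))), rep(28L, 3),
               ignore_attr = TRUE)
})

test_that("noiseless generator contracts: flat envelope at m = 0, 1 Hz peak at m = 0.5", {
  par <- quickParadigm()
  flat <- simulateSubject(par, quickSynth(seed = 2L, modDepth = 0, snr = Inf))
  nb <- narrowband(averageTrials(flat, "all"), FT)
  env <- windowedAmplitude(nb)
  # windowed RMS of an unmodulated 60/14 Hz tone still ripples by
  # sin(2 pi f L)/(2 pi f L) ~ 2% because 0.5 s is not an integer number of
  # half-cycles; the envelope must be flat at that floor, and far flatter
  # than with modulation injected
  cv <- stats::sd(seriesValues(env)) / mean(seriesValues(env))
  expect_lt(cv, 0.03)
  am0 <- simulateSubject(par, quickSynth(seed = 2L, modDepth = 0.5, snr = Inf))
  envM <- windowedAmplitude(narrowband(averageTrials(am0, "all"), FT))
  cvM <- stats::sd(seriesValues(envM)) / mean(seriesValues(envM))
  expect_gt(cvM / cv, 3)

  am <- simulateSubject(par, quickSynth(seed = 2L, modDepth = 0.5, snr = Inf))
  envAM <- windowedAmplitude(narrowband(averageTrials(am, "all"), FT))
  sp <- envelopeSpectrum(envAM)
  expect_lt(abs(peakFrequency(sp) - 1.0), sp@resolution + 1e-9)
})

test_that("square-wave flicker adds harmonics but keeps the fundamental", {
  par <- quickParadigm()
  d <- simulateSubject(par, quickSynth(seed = 3L, snr = Inf,
                                       flickerMode = "square"))
  sp <- ssvepSpectrum(averageTrials(d, "all"), "Oz")
  f <- specFreqs(sp); a <- specAmplitudes(sp)
  line <- function(f0) max(a[abs(f - f0) <= 0.06])
  floorAmp <- stats::median(a[f > 1 & f < 20])
  expect_gt(line(FD), 10 * floorAmp)        # 6 Hz fundamental
  expect_gt(line(2 * FD), 3 * floorAmp)     # 12 Hz harmonic present
})

test_that("cohort generation: behavior model, phase sampler support, ground truth", {
  par <- quickParadigm()
  # deterministic behavior: r(phase, accuracy) = 1 exactly
  co <- simulateCohort(8, par, quickSynth(behaviorNoiseSd = 0),
                       seed = 3L)
  expect_equal(cor(co$truth$relPhase, co$truth$behavior), 1.0, tolerance = 1e-12)
  expect_true(all(co$truth$relPhase >= 0 & co$truth$relPhase <= pi))
  expect_identical(nrow(co$truth), 8L)
  # point-mass sampler: K-S statistic vs uniform is 0.5 at pi/2
  pm <- simulateCohort(6, par, quickSynth(),
                       phaseSampler = function(n) rep(pi / 2, n), seed = 4L)
  expect_equal(ksUniform(pm$truth$relPhase)$statistic, 0.5, tolerance = 1e-12)
  # invalid sampler support is refused
  expect_error(
    simulateCohort(4, par, quickSynth(),
                   phaseSampler = function(n) rep(3 * pi / 2, n), seed = 1L),
    "\\[0, pi\\]")
  # ground truth records the injected phases
  expect_identical(co$truth$relPhase,
                   vapply(co$subjects, function(s) groundTruth(s)$relPhase,
                          numeric(1)))
})

test_that("subject round trip through the on-disk format is lossless", {
  d <- simulateSubject(quickParadigm(3L), quickSynth(seed = 9L))
  dir <- withr::local_tempdir()
  writeSubject(d, dir)
  expect_true(all(file.exists(file.path(dir, c("data.bin", "meta.json")))))
  d2 <- readSubject(dir)
  expect_equal(d2@data, d@data, tolerance = 1e-12)
  expect_identical(as.character(d2@labels), as.character(d@labels))
  expect_equal(d2@behavior$overall, d@behavior$overall, tolerance = 1e-12)
  expect_equal(d2@groundTruth$relPhase, d@groundTruth$relPhase, tolerance = 1e-12)
})
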