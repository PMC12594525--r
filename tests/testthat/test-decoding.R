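test_that("balanced partition: 28 trials into 3 subsets of {10, 9, 9}", {
  parts <- withr::with_seed(1, rhythmtag:::partitionIndices(1:28, 3))
  expect_identical(unname(sort(lengths(parts), decreasing = TRUE)), c(10L, 9L, 9L))
  expect_identical(sort(unname(unlist(parts))), 1:28)
  expect_error(rhythmtag:::partitionIndices(1:2, 3), "cannot split")
})

test_that("subset features: identity on identical trials, pattern recovery, Gram equivalence", {
  # identical trials: all subset feature vectors identical
  s <- sin(2 * pi * FD * timeAxis())
  arr <- array(rep(s, each = 9 * 2), c(9, 2, length(s)))
  ds <- makeDataset(arr, rep("a", 9))
  f <- subsetFeatures(ds, "a", decodingSpec(seed = 1L))
  expect_lt(max(abs(sweep(f, 2, f[1, ]))), 1e-9)

  # noiseless trials of one category: features proportional to the injected
  # distractor gain pattern (modDepth 0 so no AM sidebands enter the band)
  dsn <- simulateSubject(quickParadigm(), quickSynth(seed = 4L, snr = Inf,
                                                     modDepth = 0,
                                                     patternSeparability = 0.05))
  fp <- subsetFeatures(dsn, "pleasant", decodingSpec(seed = 2L))
  w <- dsn@groundTruth$distractorTopography +
    dsn@groundTruth$categoryPatterns[, "pleasant"]
  expect_gt(stats::cor(fp[1, ], w), 0.999)

  # Gram-matrix fast path equals the direct average -> filter -> RMS route
  spec <- decodingSpec(seed = 7L)
  idx <- which(trialLabels(dsn) == "neutral")
  parts <- withr::with_seed(7L, rhythmtag:::partitionIndices(idx, 3))
  nbArr <- rhythmtag:::nbFilterTrials(dsn, 6, 0.5)
  G <- rhythmtag:::trialGram(nbArr, 500, 2, 9)
  fGram <- t(vapply(parts, function(p) rhythmtag:::featuresFromGram(G, p),
                    numeric(3)))
  fDirect <- subsetFeatures(dsn, "neutral", spec)
  expect_equal(fGram, fDirect, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("noiseless distinct patterns decode perfectly; identical distributions at chance", {
  par <- quickParadigm()
  clean <- simulateSubject(par, quickSynth(seed = 5L, snr = Inf,
                                           patternSeparability = 0.05))
  spec <- decodingSpec(nIterations = 5L, seed = 1L)
  expect_equal(accuracy(decodePairwise(clean, "pleasant", "unpleasant", spec)), 1.0)
  tw <- decodeThreeway(clean, spec)
  expect_equal(accuracy(tw), 1.0)
  expect_equal(chanceLevel(tw), 1 / 3)
  expect_equal(accuracy(tw), mean(tw@perIteration))

  # two categories drawn from the same distribution: near chance
  arr <- withr::with_seed(3, array(stats::rnorm(24 * 3 * 2000), c(24, 3, 2000)))
  same <- makeDataset(arr, rep(c("a", "b"), each = 12))
  acc <- accuracy(decodePairwise(same, "a", "b", decodingSpec(nIterations = 20L, seed = 2L)))
  expect_gte(acc, 0.35); expect_lte(acc, 0.65)
})

test_that("windowed decoding returns a 35-point bounded series at chance level 1/3", {
  d <- simulateSubject(quickParadigm(), quickSynth(seed = 6L, snr = 2,
                                                   patternSeparability = 0.15))
  ser <- windowedDecoding(d, decodingSpec(nIterations = 3L, seed = 1L), windowSpec())
  expect_length(seriesValues(ser), 35L)
  expect_true(all(seriesValues(ser) >= 0 & seriesValues(ser) <= 1))
  expect_equal(chanceLevel(ser), 1 / 3)
  expect_equal(seriesTimes(ser)[1], 2.25)
})

test_that("permutation null: p-value formula, chance centering, reproducibility", {
  arr <- withr::with_seed(5, array(stats::rnorm(18 * 3 * 2000), c(18, 3, 2000)))
  ds <- makeDataset(arr, rep(c("a", "b", "c"), each = 6))
  spec <- decodingSpec(nIterations = 4L, seed = 11L)
  pn <- suppressWarnings(permutationNull(ds, spec, "threeway", nPerm = 60L))
  expect_equal(pn$p, (1 + sum(pn$null >= accuracy(pn$observed))) / (1 + 60))
  expect_equal(mean(pn$null), 1 / 3, tolerance = 0.05)
  expect_warning(permutationNull(ds, spec, "threeway", nPerm = 50L), "coarse")
  pn2 <- suppressWarnings(permutationNull(ds, spec, "threeway", nPerm = 60L))
  expect_identical(pn$null, pn2$null)
})

test_that("iteration spread shrinks when trials per category double", {
  spread <- function(nPer, s) {
    d <- simulateSubject(quickParadigm(nPer), quickSynth(seed = s, snr = 0.8,
                                                         patternSeparability = 0.1))
    stats::sd(decodeThreeway(d, decodingSpec(nIterations = 20L, seed = s))@perIteration)
  }
  med <- function(nPer) stats::median(vapply(c(21L, 22L, 23L), function(s)
    spread(nPer, s), numeric(1)))
  expect_lt(med(24L), med(6L))
})

test_that("distractor amplitude and decodability are separate dials", {
  par <- quickParadigm(10L)
  spec <- decodingSpec(nIterations = 10L, seed = 3L)
  res <- vapply(c(0.7, 1.4), function(da) {
    r <- vapply(31:33, function(s) {
      d <- simulateSubject(par, quickSynth(seed = s, distractorAmp = da))
      nb <- narrowband(averageTrials(d, "all"), FD)
      c(wholeTrialAmplitude(nb)$mean, accuracy(decodeThreeway(d, spec)))
    }, numeric(2))
    rowMeans(r)
  }, numeric(2))
  expect_equal(res[1, 2] / res[1, 1], 2, tolerance = 0.3)  # amplitude doubles
  expect_lt(abs(res[2, 2] - res[2, 1]), 0.12)              # accuracy barely moves
})
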